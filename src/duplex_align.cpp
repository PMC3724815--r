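#include <Rcpp.h>
using namespace Rcpp;

// Pairing score under the miRanda-style matrix. 'q' is the miRNA residue,
// 't' the (reversed) target residue; both in {A,C,G,U}.
static inline double pair_score(char q, char t, double gc, double au,
                                double gu, double mm) {
  if ((q == 'G' && t == 'C') || (q == 'C' && t == 'G')) return gc;
  if ((q == 'A' && t == 'U') || (q == 'U' && t == 'A')) return au;
  if ((q == 'G' && t == 'U') || (q == 'U' && t == 'G')) return gu;
  return mm;
}

// Local (Smith-Waterman) alignment with affine gaps (Gotoh) of the miRNA
// (5'->3') against the reversed target (so columns read 3'->5' on the
// target, i.e. antiparallel hybridisation). A gap run of length k costs
// gap_open + (k-1) * gap_extend. Target positions flagged in `mask`
// cannot be used (already claimed by a higher-scoring site).
//
// Returns the best-scoring alignment: score, gapped rows, and 1-based
// inclusive coordinates on the two input strings (target coordinates
// refer to the reversed target string as passed in).
// [[Rcpp::export(name = ".sw_align")]]
List sw_align(std::string mirna, std::string rtarget,
              double match_gc, double match_au, double wobble_gu,
              double mismatch, double gap_open, double gap_extend,
              LogicalVector mask) {
  const int n = mirna.size();     // rows: miRNA
  const int m = rtarget.size();   // cols: reversed target
  const double NEG = -1e9;

  // H: best ending in a paired column; E: gap in miRNA row (consumes
  // target); F: gap in target row (consumes miRNA).
  NumericMatrix H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  IntegerMatrix TH(n + 1, m + 1), TE(n + 1, m + 1), TF(n + 1, m + 1);

  for (int j = 0; j <= m; ++j) { E(0, j) = NEG; F(0, j) = NEG; }
  for (int i = 0; i <= n; ++i) { E(i, 0) = NEG; F(i, 0) = NEG; }

  double best = 0.0;
  int bi = 0, bj = 0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      bool dead = mask[j - 1];
      // E: consume target j via a gap in the miRNA row
      double e_open = H(i, j - 1) + gap_open;
      double e_ext  = E(i, j - 1) + gap_extend;
      if (dead) { e_open = NEG; e_ext = NEG; }
      if (e_open >= e_ext) { E(i, j) = e_open; TE(i, j) = 0; }
      else                 { E(i, j) = e_ext;  TE(i, j) = 1; }
      // F: consume miRNA i via a gap in the target row
      double f_open = H(i - 1, j) + gap_open;
      double f_ext  = F(i - 1, j) + gap_extend;
      if (f_open >= f_ext) { F(i, j) = f_open; TF(i, j) = 0; }
      else                 { F(i, j) = f_ext;  TF(i, j) = 1; }
      // H: paired column, or adopt the best gap state, or restart
      double s = dead ? NEG
                      : pair_score(mirna[i - 1], rtarget[j - 1], match_gc,
                                   match_au, wobble_gu, mismatch);
      double diag = std::max(H(i - 1, j - 1), 0.0) + s;
      double h = diag; int th = H(i - 1, j - 1) > 0.0 ? 1 : 0;
      if (E(i, j) > h) { h = E(i, j); th = 2; }
      if (F(i, j) > h) { h = F(i, j); th = 3; }
      if (h < 0.0) { h = 0.0; th = -1; }
      H(i, j) = h; TH(i, j) = th;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["found"] = false);
  }

  // Traceback from (bi, bj) in state H.
  std::string qrow, trow;
  int i = bi, j = bj, state = 0;  // 0 = H, 1 = E, 2 = F
  while (true) {
    if (state == 0) {
      int th = TH(i, j);
      if (th == 2) { state = 1; continue; }
      if (th == 3) { state = 2; continue; }
      // paired column (th == 0 start, th == 1 continue)
      qrow.push_back(mirna[i - 1]);
      trow.push_back(rtarget[j - 1]);
      --i; --j;
      if (th == 0) break;
    } else if (state == 1) {
      qrow.push_back('-');
      trow.push_back(rtarget[j - 1]);
      int te = TE(i, j);
      --j;
      state = (te == 0) ? 0 : 1;
    } else {
      qrow.push_back(mirna[i - 1]);
      trow.push_back('-');
      int tf = TF(i, j);
      --i;
      state = (tf == 0) ? 0 : 2;
    }
  }
  std::reverse(qrow.begin(), qrow.end());
  std::reverse(trow.begin(), trow.end());

  return List::create(
    _["score"] = best, _["found"] = true,
    _["mirna_row"] = qrow, _["target_row"] = trow,
    _["mirna_start"] = i + 1, _["mirna_end"] = bi,
    _["rtarget_start"] = j + 1, _["rtarget_end"] = bj);
}
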