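test_that("column classification follows the pairing matrix categories", {
  expect_equal(classify_column("G", "C"), "GC_MATCH")
  expect_equal(classify_column("C", "G"), "GC_MATCH")
  expect_equal(classify_column("A", "U"), "AU_MATCH")
  expect_equal(classify_column("G", "U"), "GU_WOBBLE")
  expect_equal(classify_column("U", "G"), "GU_WOBBLE")
  expect_equal(classify_column("A", "C"), "MISMATCH")
  expect_equal(classify_column("-", "A"), "GAP")
  expect_error(classify_column("-", "-"), "both rows")
})

test_that("score recomputation is additive over columns and gap runs", {
  cfg <- align_config()
  a <- fix_alignment("GGGGGGG", "CCCCCCC")
  expect_equal(score_alignment(a, cfg), 35)
  b <- fix_alignment("GGGGGGG", "CCCCCCU")  # 6 GC + 1 GU
  expect_equal(score_alignment(b, cfg), 32)
  expect_equal(score_alignment(fix_alignment("", ""), cfg), 0)
  # affine gap runs: open -8, each extra column -2
  g1 <- fix_alignment("GGG-GGG", "CCCCCCC")
  expect_equal(score_alignment(g1, cfg), 30 - 8)
  g2 <- fix_alignment("GGG--GG", "CCCCCCC")
  expect_equal(score_alignment(g2, cfg), 25 - 10)
})

test_that("the four empirical rules accept/reject constructed fixtures", {
  paired <- rep("GC_MATCH", 22)
  # mismatch in the seed-proximal window -> rule i
  r <- check_empirical_rules(replace(paired, 3, "MISMATCH"))
  expect_false(r$accept)
  expect_true("i" %in% r$violated)
  # all matches -> no central mismatch -> rule iii
  r <- check_empirical_rules(paired)
  expect_false(r$accept)
  expect_equal(r$violated, "iii")
  # single central mismatch -> accepted by all four rules
  r <- check_empirical_rules(replace(paired, 10, "MISMATCH"))
  expect_true(r$accept)
  # five mismatches inside 3-12 -> rule ii
  r <- check_empirical_rules(replace(paired, c(5, 6, 7, 10, 12), "MISMATCH"))
  expect_false(r$accept)
  expect_true("ii" %in% r$violated)
  # two mismatches in the last five -> rule iv
  r <- check_empirical_rules(replace(paired, c(10, 19, 21), "MISMATCH"))
  expect_false(r$accept)
  expect_true("iv" %in% r$violated)
  # gaps count as mismatches for the rules; wobbles count as pairing
  expect_true("i" %in% check_empirical_rules(replace(paired, 2, "GAP"))$violated)
  expect_true(check_empirical_rules(
    replace(replace(paired, 3, "GU_WOBBLE"), 11, "MISMATCH"))$accept)
  # short alignments get the distinct too-short code
  r <- check_empirical_rules(rep("GC_MATCH", 13))
  expect_false(r$accept)
  expect_equal(r$violated, "too_short")
})

test_that("a perfect complementary site is found by the DP but rejected by rule iii", {
  withr::with_seed(21, mirna <- random_rna_string(20))
  site <- rna_complement(mirforest:::str_rev(mirna))
  target <- paste0(random_rna_string(20), site, random_rna_string(20))
  cfg <- align_config(score_threshold = 10, energy_threshold = 100)
  expect_length(align_duplex(mirna, target, cfg), 0L)
  # the DP itself sees the site at full pairing score
  raw <- mirforest:::.sw_align(mirna, mirforest:::str_rev(target),
                               5, 5, 2, -3, -8, -2, rep(FALSE, 60))
  expect_equal(raw$score, score_alignment(
    fix_alignment(mirna, mirforest:::str_rev(site))))
})

test_that("a site with one central mismatch yields one accepted alignment at the right coordinates", {
  withr::with_seed(33, mirna <- random_rna_string(22))
  site_chars <- strsplit(rna_complement(mirforest:::str_rev(mirna)), "")[[1]]
  # break the pairing at miRNA column 11 = site position 12 (antiparallel)
  i <- 22 - 11 + 1
  m11 <- substr(mirna, 11, 11)
  site_chars[i] <- setdiff(c("A", "C"), rna_complement(m11))[1]
  target <- paste0(random_rna_string(12), paste(site_chars, collapse = ""),
                   random_rna_string(10))
  hits <- align_duplex(mirna, target, align_config())
  expect_length(hits, 1L)
  expect_equal(hits[[1]]$target_start, 13L)
  expect_equal(hits[[1]]$target_end, 34L)
  expect_equal(sum(hits[[1]]$categories == "MISMATCH"), 1L)
  # coordinate soundness: ungapped target row == reversed target slice
  ung <- gsub("-", "", hits[[1]]$target_row, fixed = TRUE)
  expect_equal(mirforest:::str_rev(ung),
               substr(target, hits[[1]]$target_start, hits[[1]]$target_end))
  # score additivity: DP-reported score equals recomputation from columns
  expect_equal(hits[[1]]$score, score_alignment(hits[[1]]))
})

test_that("unrelated random sequences rarely clear a high score threshold", {
  cfg <- align_config(score_threshold = 50, energy_threshold = 100)
  withr::with_seed(99, {
    n_hit <- sum(vapply(1:20, function(i) {
      length(align_duplex(random_rna_string(22), random_rna_string(60),
                          cfg)) > 0
    }, TRUE))
  })
  expect_lte(n_hit, 2L)
})

test_that("DP optimum matches the memoised-recursion oracle on small pairs", {
  cfg <- align_config()
  withr::with_seed(7, {
    for (case in 1:60) {
      m <- random_rna_string(sample(4:8, 1))
      t <- random_rna_string(sample(6:12, 1))
      raw <- mirforest:::.sw_align(m, mirforest:::str_rev(t), 5, 5, 2, -3,
                                   cfg$gap_open, cfg$gap_extend,
                                   rep(FALSE, nchar(t)))
      expect_equal(raw$score,
                   oracle_best_local_score(m, mirforest:::str_rev(t), cfg),
                   info = paste(m, t))
    }
  })
})

test_that("alignment input validation and tibble flattening", {
  expect_error(align_duplex("", "ACGU"), "empty")
  expect_error(fix_alignment("AC", "ACG"), "differ in length")
  a <- fix_alignment("GGGG", "CCCC", target_start = 3, target_end = 6)
  tb <- alignment_tbl(a)
  expect_equal(nrow(tb), 1L)
  expect_equal(tb$score, 20)
})
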