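# RNA nearest-neighbour stacking free energies at 37 C, v1.
# step Q1Q2|T1T2: adjacent duplex columns, Q = 5'->3' strand residues,
# T = the paired residues on the antiparallel strand (3'->5').
# Watson-Crick/Watson-Crick steps: Turner 2004 values. Steps involving
# G:U wobble pairs use flat approximations (-1.3 with a WC neighbour,
# -0.5 between two wobbles): adequate for a comparative stability feature.
step	dg_kcal_mol	source
AA|UU	-0.93	turner_wc
AU|UA	-1.10	turner_wc
AG|UC	-2.08	turner_wc
AC|UG	-2.24	turner_wc
AG|UU	-1.30	gu_wc_approx
AU|UG	-1.30	gu_wc_approx
UA|AU	-1.33	turner_wc
UU|AA	-0.93	turner_wc
UG|AC	-2.11	turner_wc
UC|AG	-2.35	turner_wc
UG|AU	-1.30	gu_wc_approx
UU|AG	-1.30	gu_wc_approx
GA|CU	-2.35	turner_wc
GU|CA	-2.24	turner_wc
GG|CC	-3.26	turner_wc
GC|CG	-3.42	turner_wc
GG|CU	-1.30	gu_wc_approx
GU|CG	-1.30	gu_wc_approx
CA|GU	-2.11	turner_wc
CU|GA	-2.08	turner_wc
CG|GC	-2.36	turner_wc
CC|GG	-3.26	turner_wc
CG|GU	-1.30	gu_wc_approx
CU|GG	-1.30	gu_wc_approx
GA|UU	-1.30	gu_wc_approx
GU|UA	-1.30	gu_wc_approx
GG|UC	-1.30	gu_wc_approx
GC|UG	-1.30	gu_wc_approx
GG|UU	-0.50	gu_gu_approx
GU|UG	-0.50	gu_gu_approx
UA|GU	-1.30	gu_wc_approx
UU|GA	-1.30	gu_wc_approx
UG|GC	-1.30	gu_wc_approx
UC|GG	-1.30	gu_wc_approx
UG|GU	-0.50	gu_gu_approx
UU|GG	-0.50	gu_gu_approx
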