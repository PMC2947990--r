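# DERIVED fixture: cell-class composition of the expressed-gene universe
# behind the published stratified expectations. The integer counts were
# reconstructed from the printed expected columns of the two enrichment
# tables (expected_c = panel_total * universe_c / stratum_total); they
# reproduce every printed expectation at its rounding and match the reported
# 48-of-806 postmeiotic X share. They are a reconstruction, not a published
# table.
stratum	cell_class	n_genes
autosomes	somatic	420
autosomes	mitotic	1077
autosomes	meiotic	1144
autosomes	postmeiotic	758
X	somatic	31
X	mitotic	94
X	meiotic	0
X	postmeiotic	48
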