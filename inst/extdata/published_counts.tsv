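quantity	value
n_constituents_mcf7_specific	3872
n_constituents_shared	1124
n_constituents_ishikawa_specific	2138
n_se_mcf7	392
n_se_ishikawa	618
n_se_shared	99
n_shared_se_constituents_mcf7_specific	1293
n_shared_se_constituents_shared	410
n_shared_se_constituents_ishikawa_specific	752
pct_cobind_low_mcf7_specific	47
pct_cobind_low_ishikawa_specific	25
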