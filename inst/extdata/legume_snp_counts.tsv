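germplasm_set	crop	n_genotypes	reads_per_genotype_M	n_snps
tetraploid_alfalfa_mediterranean	alfalfa	154	2.89	10339
tetraploid_alfalfa_po_valley	alfalfa	124	2.75	6690
tetraploid_alfalfa_us	alfalfa	190	2.36	9906
pea_attika_x_isard	pea	105	2.40	2386
pea_kaspa_x_attika	pea	105	1.85	2506
pea_kaspa_x_isard	pea	105	2.30	2750
white_lupin_kiev_x_p27255	white_lupin	191	1.90	2593
white_lupin_world_landrace_pool	white_lupin	288	1.66	6802
chickpea_sbd377_x_bgd112	chickpea	95	1.80	3977
chickpea_icc4958_x_icc1882	chickpea	210	3.37	828
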