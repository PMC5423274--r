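crop	cycle_phenotypic_years	cycle_genomic_years	phen_low	phen_high	gen_low	gen_high
cool_season_grain_legume	2	0.5	180	230	32	36
perennial_forage_legume	5	1	230	280	32	36
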