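# Cool-season grain legume (pea) selection scenario.
# Phenotypic: 1 site, 2 years, 3 reps, 2-year cycle; H = 0.84 from a
# 7-environment trial series. Genomic: 0.5-year cycle, r_A = 0.48.
# Intensities are supplied directly (2.06 for 15/300; 2.39 as the adopted
# value for selecting 15 out of sixfold more genomic candidates).
phenotypic:
  accuracy: 0.84        # H, square root of broad-sense entry-mean heritability
  cycle_years: 2
  k: 15
  candidates: 300
  intensity: 2.06
  cost_per_genotype: 205
genomic:
  accuracy: 0.48
  cycle_years: 0.5
  k: 15
  intensity: 2.39
  cost_per_genotype: 34
s_A: 1
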