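# Perennial forage legume (alfalfa) selection scenario.
# Phenotypic: half-sib progeny test, 1 site, 3 years, 3 reps, 5-year cycle.
# Genomic candidates are derived from equal total evaluation cost
# (midpoint costs 255 vs 34 euro/genotype -> 7.5-fold more candidates).
phenotypic:
  accuracy: 0.46        # h, square root of narrow-sense heritability
  cycle_years: 5
  k: 15
  candidates: 300
  cost_per_genotype: 255
genomic:
  accuracy: 0.32        # r_A, genomic prediction accuracy
  cycle_years: 1
  k: 15
  cost_per_genotype: 34
s_A: 1
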