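---
title: "Designing GBS experiments and comparing selection schemes with gbsdesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing GBS experiments and comparing selection schemes with gbsdesign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbsdesign)
```

## The problem

Genotyping-by-sequencing (GBS) discovers and scores SNP markers by
sequencing short tags adjacent to restriction cut sites in a multiplexed
library. How many usable markers a protocol yields depends on a chain of
choices: the restriction enzyme (how many fragments are cut), the adapter
chemistry (which fragments amplify), the polymerase (how evenly fragments
amplify across sizes and GC contents), the per-genotype read budget
(how deep each tag is covered), and the minimum read depth demanded before
a genotype call is accepted (which depends on ploidy). Downstream, the
markers feed genomic prediction, and a breeding program must decide whether
genomic selection beats phenotypic selection once cycle length and
evaluation cost are taken into account.

`gbsdesign` implements this chain as composable, seeded, testable pieces:
an in-silico digestion engine, a read-sampling engine with amplification
bias, ploidy-aware depth thresholds, a compact RR-BLUP prediction stage,
and the equal-cost selection-gain framework. Synthetic genomes, panels and
traits with controlled statistical structure drive end-to-end tests.

## In-silico digestion and tags

Restriction enzymes are defined as data (`inst/extdata/enzymes.yaml`):
ApeKI (`G^CWGC`), PstI (`CTGCA^G`), MspI (`C^CGG`), plus the toy EcoRI.
Recognition sites may carry IUPAC degenerate codes; only degenerate
palindromes are accepted, so scanning the top strand finds every site, and
overlapping matches are all honoured (`GCAGCAGC` contains two ApeKI sites).
Coordinates are 0-based half-open throughout: a cut at position $k$ falls
between bases $k$ and $k+1$, fragments partition each chromosome exactly,
and the fragment table doubles as a BED-like record.

Amplifiability follows the adapter chemistry: a single-enzyme library
requires an enzyme cut at both fragment ends (chromosome ends never
amplify); the PstI:MspI double digest uses a common adapter so only
fragments cut by a *different* enzyme at each end amplify. Each
amplifiable fragment end contributes one tag, 64 bp read inward from the
cut, reverse-complemented on the right end. Fragments shorter than the tag
length are truncated to the insert (no N padding; adapter read-through is
not modelled) and the duplicate reverse-complementary right-end read is
dropped.

Tag spectra are histograms over fragment size or GC classes. The class
counts follow the conventional presentation (15 size classes, 7 GC
classes); since the exact published bin edges are not fixed anywhere, the
defaults are 100-bp bins to 1400 bp plus an open top class, and 0.10-wide
GC bins between 0.15 and 0.65 with open flanks. The edge at GC 0.35 is
deliberate: over/under-amplification above versus below 35% GC can be read
directly off the observed-minus-expected deviations. Both bin sets are
configurable through `bin_spec()`.

## Amplification bias and read sampling

Relative amplification weight is a product of a log-normal kernel in
fragment length and a logistic ramp in GC fraction, both with strictly
positive baselines. Three presets exist: `uniform` (exactly equal
weights), `kapa` (near-flat, mild preferences), and `neb` (strong
enrichment of 100–500 bp fragments and of GC > 35%). The presets are
calibrated qualitatively — sign and location of the enrichment, not a
parametric fit, which no published source provides — and the tests check
exactly those signs.

Each genotype's read budget is allocated by an independent multinomial
draw over tags (column totals are exact, mirroring the extraction of an
equal number of reads per genotype from a multiplexed pool), and
`downsample()` thins a depth column without replacement via a chain of
univariate hypergeometric draws. Desk-scale budgets of $10^4$–$10^5$ reads
over a few hundred to a few thousand tags stand in for the 1.25–2.5 M
reads over genome-scale tag sets of a real experiment; what matters for
the phenomena studied here is the mean depth per tag (budget / tags),
which the defaults keep in the realistic 5–20 range.

## Depth thresholds across ploidies

A truly heterozygous locus looks homozygous when all $n$ reads sample the
same allele, which happens with probability $f^n + (1-f)^n$ for majority
allele fraction $f$. The worst case is $f = 1/2$ for a diploid and
$f = 3/4$ for an autotetraploid (simplex/triplex heterozygotes). Requiring
this probability below 5% gives minimum depths of 6 (outbred diploid) and
11 (tetraploid); at depth 11 and $f = 3/4$ the residual miscall
probability is 4.22%. Fully homozygous inbred lines have no heterozygotes
to collapse, so the binomial argument does not apply and conventional
depths of 2–3 (4 when residual heterozygosity is expected, as in F6 RILs)
are used instead.

Calling is three-class (both homozygotes plus one pooled heterozygote
class; resolving tetraploid allele dosage would need roughly 48x depth and
is out of scope): both alleles seen with total depth at or above the
heterozygous minimum is HET, a single allele at or above the homozygous
minimum is that homozygote, anything else MISSING. The default rule
(4, 11) is the tetraploid filtering rule. `expected_missing_rate()` gives
the analytic expectation of MISSING under any depth distribution and is
checked against Monte Carlo in the tests. Reads are treated as error-free
draws of the true alleles; sequencing error is deliberately outside the
model, consistent with the binomial threshold argument itself.

## Genomic prediction

Marker matrices are coded 0/1/2 (heterozygote = 1, with tetraploid dose
classes collapsed, matching three-class calling) with `NA` for missing.
The pipeline is: remove loci with minor allele frequency strictly below
2.5% (het counted as one copy of each allele; a locus exactly at the
boundary stays), remove loci whose missing fraction exceeds the chosen
threshold, impute the rest by K-nearest neighbours, and fit RR-BLUP.

KNN imputation (k = 5 by default; no published k exists) measures
genotype distance as root-mean-square code difference over jointly
observed loci, so sparsity does not inflate distances, and replaces a
missing entry by the inverse-distance-weighted mean of the k nearest
informative neighbours, rounded to a valid code. Observed entries are
never altered. A genotype sharing no observed locus with any other is an
error, not a silent guess.

`fit_ridge_predictor()` solves the ridge system on column-centred codes.
The shrinkage $\lambda = \sigma_e^2/\sigma_b^2$ is estimated by restricted
maximum likelihood through a one-dimensional spectral optimisation of the
marker relationship matrix (the standard efficient mixed-model
computation). This was chosen over a method-of-moments variance ratio
because it is exact under the model, needs no fallback grid, and is
deterministic given the data; the primal and dual ridge solutions are
checked against each other in the tests as an internal consistency oracle.
The intercept is the training mean. Predictive ability is the
cross-validated correlation between predicted and observed phenotypes
(10x10 by default; 5-fold with fewer repeats in the desk-scale tests), and
is deliberately *not* divided by the square root of heritability — the
conservative convention that avoids optimistic bias when cross-validating
within a single experiment.

`missing_threshold_sweep()` runs filter-impute-validate across a grid of
missing-data thresholds with a common fold assignment, exposing the
trade-off between more markers and more imputation noise. In sparse
tetraploid simulations (80 outbred genotypes, mean tag depth ~15 under the
(4, 11) rule, heritability 0.6) the 30% threshold beats the 0% threshold
in the majority of seeded runs — the qualitative peak at intermediate
thresholds that motivates sweeping this parameter at all.

## The synthetic-data generator

`simulate_genome()` draws bases i.i.d. with $P(G) = P(C) = \mathrm{GC}/2$,
the simplest model whose GC spectrum is directly controllable; planted
recognition sites are exact (accidental background occurrences are
scrubbed before planting, and the result is re-scanned). Panels draw
segregating loci at a configurable rate with allele frequencies uniform on
[0.025, 0.5] — the lower edge matches the MAF filter boundary so the filter
is genuinely exercised — and outbred allele doses come from
Binomial(ploidy, frequency), a Hardy–Weinberg-like model adopted in the
absence of a published population model. Inbred panels are fully
homozygous. Traits are additive over sampled QTL with Gaussian noise
scaled to a target heritability, and true breeding values are always
retained.

What the generator does *not* emulate matters for interpreting green
tests: there is no linkage or LD (each locus is independent, so imputation
and prediction cannot borrow information along chromosomes the way they do
in real panels), no population structure beyond what
`structured_marker_matrix`-style fixtures build explicitly, no sequencing
error, and no barcode/adapter artefacts. Passing tests therefore
demonstrate the correctness and internal consistency of the pipeline and
the direction of its trade-offs, not calibrated error rates on real data.

## Selection-gain framework

Gain per year is the breeder's equation on a per-year basis,
$\Delta G = i \, a \, \sigma_A r_g / t$, with $a$ the accuracy ($h$, $H$
or $r_A$), $t$ the cycle length and $i$ the selection intensity — the
truncated-normal mean $\varphi(z)/p$ by default, which reproduces the
canonical values 2.06 (p = 5%) and 2.80 (p = 0.667%). A finite-population
order-statistics variant is available but never applied silently. With
defaults $\sigma_A = 1$, $r_g = 1$, gains are in breeding-value standard
deviations per year and ratios are invariant to both.

Equal-cost comparison scales the genomic candidate count by the cost
ratio, $N_G = N_P \cdot c_P / c_G$; `break_even_accuracy()` inverts the
comparison for the genomic accuracy that achieves a chosen advantage, and
the round-trip (break-even accuracy back into the comparison) is exact by
construction and tested. Scenario files under `inst/extdata/` encode an
alfalfa progeny-test scenario (accuracy 0.46, 5-year cycle, 15 of 300,
costs 255 vs 34 per genotype) and a pea scenario (H = 0.84, 2-year cycle
vs 0.5-year genomic cycle, r_A = 0.48) whose genomic intensity 2.39 is a
supplied input rather than a derived value: the truncated-normal value for
15 out of 1800 would be 2.73, and the file keeps the published figure as
data while `selection_intensity()` remains available for the derived path.
One YAML subtlety: the candidate count is spelled `candidates` because a
bare `N:` key is a boolean under YAML 1.1.

## Numerical and design notes

- Everything stochastic takes a seed; identical seeds give identical
  output, including byte-identical TSV artifacts from `gbs_run()`.
- `min_depth_for_error()` scans depths linearly from 1. Note that one read
  always looks homozygous (miscall probability exactly 1), so even
  `alpha = 0.99` yields a minimum depth of 2, not 1.
- Two enzymes cutting the same position keep the first enzyme's label; cuts
  at the very chromosome ends are no-ops.
- Values outside the last spectrum bin fall into the open-ended top class.
- Digestion is checked against a brute-force regex scanner on 1000 random
  sequences; the multinomial and hypergeometric engines against their
  closed-form moments; the analytic missing-rate against Monte Carlo.
- Desk problem sizes (genomes of 50–400 kb, panels of 30–200 genotypes,
  budgets of $10^3$–$10^5$ reads) were chosen once as realistic scaled-down
  study conditions and are stated alongside each test.

## Worked example

```{r example, eval = FALSE}
enz <- load_enzymes()
genome <- simulate_genome(2e5, gc_content = 0.35, seed = 1)
frags <- select_amplifiable(digest(genome, enz$ApeKI), "single")
tags <- extract_tags(genome, frags)

ds <- simulate_gbs_dataset(
  genome, panel_spec(80, ploidy = 4, breeding_system = "outbred"),
  protocol = list(name = "ApeKI", enzymes = list(enz$ApeKI),
                  type = "single"),
  bias = bias_preset("neb"), reads_per_genotype = 10000,
  rule = call_filter_rule(4, 11), seed = 2)
count_shared_polymorphic(ds$calls)

alfalfa <- read_scenario(system.file("extdata", "scenario_alfalfa.yaml",
                                     package = "gbsdesign"))
compare_schemes_equal_cost(alfalfa$phenotypic, alfalfa$genomic)
```
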