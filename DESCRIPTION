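Package: gbsdesign
Title: Genotyping-by-Sequencing Protocol Evaluation and Selection-Gain
    Scenarios for Legume Breeding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for designing
    genotyping-by-sequencing (GBS) experiments and for comparing genomic
    versus phenotypic selection schemes in forage and grain legumes.
    Provides in-silico restriction digestion with degenerate (IUPAC)
    recognition sites, 64-bp tag extraction, fragment size and GC spectrum
    analysis, polymerase amplification-bias models, multinomial read
    allocation and hypergeometric downsampling, binomial read-depth
    thresholds for genotype calling across ploidies, marker filtering,
    K-nearest-neighbour imputation and ridge-regression (RR-BLUP) genomic
    prediction with cross-validation, and a breeder's-equation framework
    for gain per year under equal-cost phenotypic versus genomic selection.
    Synthetic genomes, genotype panels and traits with controlled
    statistical structure are generated for end-to-end pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
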