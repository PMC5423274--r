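# Shared fixtures: toy enzymes, random sequences, and a brute-force
# digestion oracle kept deliberately independent of the package's
# Biostrings-based scanner.

toy_enzyme <- function() restriction_enzyme("toyE", "GAATTC", 1)

gbs_enzymes <- function() load_enzymes()

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# All match start positions (0-based) of an IUPAC pattern, including
# overlapping matches, via a regex lookahead scan.
oracle_match_starts <- function(seq_str, recognition) {
  rx <- paste0("(?=", iupac_to_regex(recognition), ")")
  m <- gregexpr(rx, seq_str, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

oracle_cuts <- function(seq_str, enzyme) {
  starts <- oracle_match_starts(seq_str, enzyme$recognition)
  sort(unique(starts + enzyme$cut_offset))
}

# Quadratic-time digestion oracle: fragments as substrings between cuts.
oracle_fragments <- function(seq_str, enzymes) {
  len <- nchar(seq_str)
  cuts <- sort(unique(unlist(lapply(enzymes, function(e) {
    cz <- oracle_cuts(seq_str, e)
    cz[cz > 0 & cz < len]
  }))))
  bounds <- c(0L, cuts, len)
  vapply(seq_len(length(bounds) - 1L), function(i) {
    substr(seq_str, bounds[i] + 1L, bounds[i + 1L])
  }, character(1))
}

reconstruct_chromosome <- function(genome, fragments, chrom) {
  fr <- fragments[fragments$chrom == chrom, , drop = FALSE]
  fr <- fr[order(fr$start), , drop = FALSE]
  seqs <- vapply(seq_len(nrow(fr)), function(i) {
    as.character(Biostrings::subseq(genome[[chrom]], fr$start[i] + 1L,
                                    fr$end[i]))
  }, character(1))
  paste(seqs, collapse = "")
}

# A small panel with two divergent sub-populations, used for imputation
# head-to-head tests: within-group genotypes are near-copies, so nearest
# neighbours are informative while the column mean is not.
structured_marker_matrix <- function(n_per_group = 12L, n_loci = 60L,
                                     flip_rate = 0.05) {
  centers <- rbind(sample(c(0L, 2L), n_loci, replace = TRUE),
                   sample(c(0L, 2L), n_loci, replace = TRUE))
  rows <- lapply(1:2, function(g) {
    t(vapply(seq_len(n_per_group), function(i) {
      row <- centers[g, ]
      flip <- runif(n_loci) < flip_rate
      row[flip] <- sample(0:2, sum(flip), replace = TRUE)
      row
    }, integer(n_loci)))
  })
  M <- do.call(rbind, rows)
  dimnames(M) <- list(paste0("g", seq_len(nrow(M))),
                      paste0("l", seq_len(n_loci)))
  M
}

# End-to-end simulated GBS dataset at desk scale, shared by the prediction
# and sweep tests.
desk_gbs_dataset <- function(seed, total_length = 3e5, gc = 0.45,
                             n_genotypes = 60L, ploidy = 4L,
                             reads_per_genotype = 6000L, snp_rate = 0.5) {
  genome <- simulate_genome(total_length, gc_content = gc, seed = seed)
  simulate_gbs_dataset(
    genome,
    panel_spec(n_genotypes, ploidy = ploidy, breeding_system = "outbred",
               snp_rate = snp_rate),
    protocol = list(name = "ApeKI", enzymes = list(gbs_enzymes()$ApeKI),
                    type = "single"),
    bias = bias_preset("neb"),
    reads_per_genotype = reads_per_genotype,
    rule = call_filter_rule(4L, 11L),
    seed = seed + 1L
  )
}
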