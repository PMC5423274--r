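#' Simulate a genome with controllable GC content and planted sites
#'
#' Bases are drawn i.i.d. with `P(G) = P(C) = gc_content / 2` except inside
#' planted restriction sites, giving direct control over the GC spectrum.
#' Planted recognition sites are guaranteed to occur exactly the requested
#' number of times as non-overlapping matches: accidental background
#' occurrences of a planted pattern are resampled away before planting, and
#' the realised genome is re-scanned to verify the count.
#'
#' @param total_length Total genome length in bases (>= 1).
#' @param n_chromosomes Number of chromosomes; `total_length` is split as
#'   evenly as possible.
#' @param gc_content Target GC fraction in `[0, 1]`.
#' @param planted_sites Optional list of `list(enzyme =, count =)` entries,
#'   where `enzyme` is a [restriction_enzyme()] or an IUPAC recognition
#'   string. Counts are distributed over chromosomes proportionally to
#'   length.
#' @param seed Optional RNG seed; identical seeds give identical genomes.
#' @return A named `DNAStringSet`.
#' @examples
#' g <- simulate_genome(10000, gc_content = 0.35, seed = 1)
#' @export
simulate_genome <- function(total_length, n_chromosomes = 1L,
                            gc_content = 0.5, planted_sites = NULL,
                            seed = NULL) {
  total_length <- as.integer(total_length)
  stopifnot(total_length >= 1L, n_chromosomes >= 1L,
            gc_content >= 0, gc_content <= 1)
  if (!is.null(seed)) set.seed(seed)

  patterns <- character(0)
  counts <- integer(0)
  if (!is.null(planted_sites)) {
    for (ps in planted_sites) {
      rec <- if (inherits(ps$enzyme, "restriction_enzyme")) {
        ps$enzyme$recognition
      } else {
        toupper(ps$enzyme)
      }
      patterns <- c(patterns, rec)
      counts <- c(counts, as.integer(ps$count))
    }
    if (sum(counts * nchar(patterns)) > total_length) {
      stop("impossible planting: requested sites need ",
           sum(counts * nchar(patterns)), " bases but the genome has only ",
           total_length)
    }
  }

  chrom_len <- rep(total_length %/% n_chromosomes, n_chromosomes)
  chrom_len[1L] <- chrom_len[1L] + total_length %% n_chromosomes
  if (any(chrom_len < 1L)) stop("total_length too small for n_chromosomes")

  # distribute planted counts over chromosomes proportionally to length
  chrom_counts <- matrix(0L, nrow = n_chromosomes, ncol = length(patterns))
  if (length(patterns) > 0L) {
    for (j in seq_along(patterns)) {
      alloc <- if (n_chromosomes == 1L) {
        counts[j]
      } else {
        tabulate(sample.int(n_chromosomes, counts[j], replace = TRUE,
                            prob = chrom_len), nbins = n_chromosomes)
      }
      chrom_counts[, j] <- alloc
    }
  }

  base_prob <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
                 G = gc_content / 2, T = (1 - gc_content) / 2)
  seqs <- character(n_chromosomes)
  for (ci in seq_len(n_chromosomes)) {
    seqs[ci] <- .simulate_chromosome(chrom_len[ci], base_prob, patterns,
                                     chrom_counts[ci, ])
  }
  Biostrings::DNAStringSet(stats::setNames(seqs,
                                           paste0("chr", seq_len(n_chromosomes))))
}

.random_bases <- function(n, base_prob) {
  if (n == 0L) return(character(0))
  sample(names(base_prob), n, replace = TRUE, prob = base_prob)
}

.resolve_iupac <- function(pattern) {
  letters_ <- strsplit(pattern, "")[[1]]
  paste(vapply(letters_, function(l) {
    opts <- strsplit(IUPAC_CODES[[l]], "")[[1]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

.simulate_chromosome <- function(len, base_prob, patterns, counts,
                                 max_attempts = 25L) {
  for (attempt in seq_len(max_attempts)) {
    bases <- .random_bases(len, base_prob)
    ok <- TRUE
    if (length(patterns) > 0L) {
      seq_str <- paste(bases, collapse = "")
      # scrub accidental occurrences of every planted pattern
      for (scrub in 1:100) {
        dna <- Biostrings::DNAString(seq_str)
        hit <- FALSE
        for (pat in patterns) {
          if (len < nchar(pat)) next
          m <- Biostrings::matchPattern(pat, dna, fixed = FALSE)
          if (length(m) > 0L) {
            hit <- TRUE
            for (s in Biostrings::start(m)) {
              k <- nchar(pat)
              substr(seq_str, s, s + k - 1L) <-
                paste(.random_bases(k, base_prob), collapse = "")
            }
          }
        }
        if (!hit) break
      }
      # choose non-overlapping positions and plant concrete instantiations
      occupied <- integer(0)
      placed <- TRUE
      for (j in seq_along(patterns)) {
        k <- nchar(patterns[j])
        for (cnt in seq_len(counts[j])) {
          pos <- NA_integer_
          for (try in 1:500) {
            cand <- sample.int(len - k + 1L, 1L)
            if (!any(abs(cand - occupied) < k + max(nchar(patterns)))) {
              pos <- cand
              break
            }
          }
          if (is.na(pos)) { placed <- FALSE; break }
          occupied <- c(occupied, pos)
          substr(seq_str, pos, pos + k - 1L) <- .resolve_iupac(patterns[j])
        }
        if (!placed) break
      }
      if (!placed) next
      # verify the realised counts (planting may create boundary artefacts)
      dna <- Biostrings::DNAString(seq_str)
      for (j in seq_along(patterns)) {
        m <- Biostrings::matchPattern(patterns[j], dna, fixed = FALSE)
        if (length(m) != counts[j]) { ok <- FALSE; break }
      }
      if (ok) return(seq_str)
    } else {
      return(paste(bases, collapse = ""))
    }
  }
  stop("could not realise the requested planted sites after ", max_attempts,
       " attempts; reduce the site count or enlarge the genome")
}

#' Panel specification for genotype simulation
#'
#' @param n_genotypes Number of genotypes in the panel.
#' @param ploidy 2 or 4.
#' @param breeding_system `"inbred"` (fully homozygous lines) or
#'   `"outbred"` (Hardy-Weinberg-like allele doses).
#' @param snp_rate Per-locus probability that the locus segregates.
#' @param maf_range Allele frequencies of segregating loci are drawn
#'   uniformly on this range (default `[0.025, 0.5]`, so the conventional
#'   2.5% minor-allele-frequency filter boundary is exercised).
#' @return A list of class `panel_spec`.
#' @export
panel_spec <- function(n_genotypes, ploidy = 2L,
                       breeding_system = c("inbred", "outbred"),
                       snp_rate = 0.3, maf_range = c(0.025, 0.5)) {
  breeding_system <- match.arg(breeding_system)
  ploidy <- as.integer(ploidy)
  if (!ploidy %in% c(2L, 4L)) stop("ploidy must be 2 or 4")
  stopifnot(n_genotypes >= 1L, snp_rate >= 0, snp_rate <= 1,
            length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  structure(list(n_genotypes = as.integer(n_genotypes), ploidy = ploidy,
                 breeding_system = breeding_system, snp_rate = snp_rate,
                 maf_range = maf_range),
            class = "panel_spec")
}

#' Simulate true genotypes of a panel at tag loci
#'
#' Each locus segregates with probability `snp_rate`; segregating loci get
#' an alternative-allele frequency drawn uniformly from `maf_range`. Outbred
#' genotypes carry allele doses drawn from `Binomial(ploidy, frequency)`
#' (Hardy-Weinberg-like); inbred genotypes are homozygous, carrying dose 0
#' or `ploidy` with the same allele frequency. SNPs are taken to lie within
#' the tag window, since only tag-window variation is observable in GBS.
#'
#' @param loci Tag table from [extract_tags()], a character vector of locus
#'   identifiers, or a positive integer number of loci.
#' @param spec A [panel_spec()].
#' @param seed Optional RNG seed.
#' @return Object of class `gbs_panel`: list with `doses` (genotype x locus
#'   integer matrix of alternative-allele doses), `ploidy`,
#'   `breeding_system`, `segregating` (logical per locus), `allele_freq`.
#' @export
simulate_genotype_panel <- function(loci, spec, seed = NULL) {
  stopifnot(inherits(spec, "panel_spec"))
  locus_ids <- if (is.data.frame(loci)) {
    loci$tag_id
  } else if (is.character(loci)) {
    loci
  } else if (is.numeric(loci) && length(loci) == 1L && loci >= 1) {
    paste0("locus", seq_len(loci))
  } else {
    stop("loci must be a tag table, a character vector of ids, or a count")
  }
  if (length(locus_ids) == 0L) stop("empty locus list")
  if (!is.null(seed)) set.seed(seed)

  n_loci <- length(locus_ids)
  segregating <- stats::runif(n_loci) < spec$snp_rate
  freq <- numeric(n_loci)
  freq[segregating] <- stats::runif(sum(segregating),
                                    spec$maf_range[1], spec$maf_range[2])
  doses <- matrix(0L, nrow = spec$n_genotypes, ncol = n_loci,
                  dimnames = list(paste0("g", seq_len(spec$n_genotypes)),
                                  locus_ids))
  if (any(segregating)) {
    seg_idx <- which(segregating)
    if (spec$breeding_system == "inbred") {
      carrier <- stats::rbinom(spec$n_genotypes * length(seg_idx), 1L,
                               rep(freq[seg_idx], each = spec$n_genotypes))
      doses[, seg_idx] <- as.integer(carrier) * spec$ploidy
    } else {
      doses[, seg_idx] <- stats::rbinom(
        spec$n_genotypes * length(seg_idx), spec$ploidy,
        rep(freq[seg_idx], each = spec$n_genotypes))
    }
  }
  structure(list(doses = doses, ploidy = spec$ploidy,
                 breeding_system = spec$breeding_system,
                 segregating = segregating, allele_freq = freq,
                 loci = locus_ids),
            class = "gbs_panel")
}

#' @export
print.gbs_panel <- function(x, ...) {
  cat("<gbs_panel> ", nrow(x$doses), " ", x$breeding_system,
      " genotypes (ploidy ", x$ploidy, ") x ", ncol(x$doses), " loci; ",
      sum(x$segregating), " segregating\n", sep = "")
  invisible(x)
}

#' Simulate an additive trait with a target heritability
#'
#' A set of QTL is sampled among loci with realised genetic variance; the
#' true breeding value of a genotype is the sum of its allele doses times
#' standard-normal effects at those QTL. Gaussian noise is added with
#' variance scaled so that the expected narrow-sense heritability of the
#' phenotype equals `h2`.
#'
#' @param panel A [simulate_genotype_panel()] result.
#' @param n_qtl Number of QTL (must not exceed the variable loci).
#' @param h2 Heritability in `[0, 1]`; `h2 = 1` gives noise-free phenotypes,
#'   `h2 = 0` phenotypes independent of the genotypes.
#' @param seed Optional RNG seed.
#' @return List of class `gbs_trait`: `phenotype`, `breeding_value`, `qtl`
#'   (locus indices), `effects`, `h2`.
#' @export
simulate_trait <- function(panel, n_qtl, h2, seed = NULL) {
  stopifnot(inherits(panel, "gbs_panel"), n_qtl >= 1L)
  if (h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  variable <- which(apply(panel$doses, 2L, stats::var) > 0)
  if (length(variable) < n_qtl) {
    stop("n_qtl (", n_qtl, ") exceeds the ", length(variable),
         " variable loci in the panel")
  }
  qtl <- sort(sample(variable, n_qtl))
  effects <- stats::rnorm(n_qtl)
  g <- as.numeric(panel$doses[, qtl, drop = FALSE] %*% effects)
  var_g <- stats::var(g)
  n <- length(g)
  if (h2 == 0) {
    phen <- stats::rnorm(n, sd = max(sqrt(var_g), 1))
  } else {
    noise_sd <- sqrt(var_g * (1 - h2) / h2)
    phen <- g + stats::rnorm(n, sd = noise_sd)
  }
  structure(list(phenotype = stats::setNames(phen, rownames(panel$doses)),
                 breeding_value = stats::setNames(g, rownames(panel$doses)),
                 qtl = qtl, effects = effects, h2 = h2),
            class = "gbs_trait")
}

#' Simulate a complete GBS dataset end to end
#'
#' Composes digestion, tag extraction, biased multinomial read allocation
#' and depth-threshold genotype calling into a marker matrix with
#' depth-driven missingness. True genotypes are retained so calling error
#' rates remain computable.
#'
#' @param genome See [as_genome()].
#' @param panel A [simulate_genotype_panel()] result whose loci match this
#'   genome's tags, or a [panel_spec()] (the panel is then simulated at the
#'   tag loci).
#' @param protocol List with `enzymes` (list of [restriction_enzyme()]) and
#'   `type` (see [select_amplifiable()]); optional `name` used in error
#'   messages.
#' @param bias A [bias_model()] (default uniform).
#' @param reads_per_genotype Per-genotype read budget.
#' @param rule A [call_filter_rule()].
#' @param tag_length Tag length (default 64).
#' @param seed Optional RNG seed; identical seeds give identical datasets.
#' @return Object of class `gbs_dataset`: list with `calls` (genotype x
#'   locus marker matrix coded 0/1/2 with `NA` for missing), `truth` (same
#'   shape, from the true doses), `depth` (tag x genotype read counts),
#'   `tags`, `panel`, `rule`.
#' @export
simulate_gbs_dataset <- function(genome, panel, protocol,
                                 bias = bias_preset("uniform"),
                                 reads_per_genotype = 20000L,
                                 rule = call_filter_rule(),
                                 tag_length = 64L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genome <- as_genome(genome)
  proto_name <- if (!is.null(protocol$name)) protocol$name else protocol$type
  frags <- digest(genome, protocol$enzymes)
  amp <- select_amplifiable(frags, protocol$type)
  if (nrow(amp) == 0L) {
    stop("protocol '", proto_name, "' yields zero amplifiable fragments")
  }
  tags <- extract_tags(genome, amp, tag_length = tag_length)
  if (inherits(panel, "panel_spec")) {
    panel <- simulate_genotype_panel(tags, panel)
  }
  stopifnot(inherits(panel, "gbs_panel"))
  if (ncol(panel$doses) != nrow(tags)) {
    stop("panel has ", ncol(panel$doses), " loci but the protocol yields ",
         nrow(tags), " tags")
  }
  n_geno <- nrow(panel$doses)
  w <- amplification_weights(tags, bias)
  depth <- sample_read_depths(w, reads_per_genotype, n_geno,
                              tag_ids = tags$tag_id)
  # alternative-allele reads ~ Binomial(depth, dose / ploidy), per entry
  depth_gl <- t(depth)  # genotype x locus
  p_alt <- panel$doses / panel$ploidy
  alt <- matrix(stats::rbinom(length(depth_gl), as.vector(depth_gl),
                              as.vector(p_alt)),
                nrow = n_geno, dimnames = dimnames(depth_gl))
  ref <- depth_gl - alt
  calls <- matrix(call_to_code(call_genotype(as.vector(ref), as.vector(alt),
                                             rule)),
                  nrow = n_geno, dimnames = dimnames(depth_gl))
  truth <- matrix(0L, nrow = n_geno, ncol = ncol(depth_gl),
                  dimnames = dimnames(depth_gl))
  truth[panel$doses > 0L & panel$doses < panel$ploidy] <- 1L
  truth[panel$doses == panel$ploidy] <- 2L
  structure(list(calls = calls, truth = truth, depth = depth, tags = tags,
                 panel = panel, rule = rule,
                 reads_per_genotype = as.integer(reads_per_genotype)),
            class = "gbs_dataset")
}

#' @export
print.gbs_dataset <- function(x, ...) {
  cat("<gbs_dataset> ", nrow(x$calls), " genotypes x ", ncol(x$calls),
      " tag loci; ", x$reads_per_genotype, " reads/genotype; ",
      sprintf("%.1f%% missing calls\n", 100 * mean(is.na(x$calls))), sep = "")
  invisible(x)
}
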