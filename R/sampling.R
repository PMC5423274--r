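#' Allocate a per-genotype read budget across tags
#'
#' Each genotype's `total_reads` reads are drawn as an independent
#' multinomial sample over tags with the given amplification weights,
#' mirroring the random extraction of an equal number of reads from every
#' genotype in a multiplexed library. Column sums are therefore exactly
#' `total_reads`.
#'
#' @param weights Normalised per-tag amplification weights
#'   ([amplification_weights()]).
#' @param total_reads Reads per genotype (>= 0).
#' @param n_genotypes Number of genotypes (columns).
#' @param tag_ids Optional row names.
#' @return Integer matrix of read depths, tags in rows, genotypes in columns.
#' @export
sample_read_depths <- function(weights, total_reads, n_genotypes,
                               tag_ids = NULL) {
  stopifnot(length(weights) >= 1L, all(weights >= 0), n_genotypes >= 1L)
  total_reads <- as.integer(total_reads)
  if (is.na(total_reads) || total_reads < 0L) {
    stop("total_reads must be a non-negative integer")
  }
  if (total_reads == 0L) {
    depths <- matrix(0L, nrow = length(weights), ncol = n_genotypes)
  } else {
    depths <- stats::rmultinom(n_genotypes, size = total_reads, prob = weights)
    storage.mode(depths) <- "integer"
  }
  rownames(depths) <- tag_ids
  colnames(depths) <- paste0("g", seq_len(n_genotypes))
  depths
}

#' Downsample a depth column without replacement
#'
#' Thins a per-tag read-depth vector to a smaller total by sampling reads
#' without replacement (multivariate hypergeometric), the in-silico analogue
#' of extracting a fixed number of reads from a FASTQ file. Implemented as a
#' chain of univariate hypergeometric draws, so it is exact and O(number of
#' tags).
#'
#' @param depths Non-negative integer vector of read depths.
#' @param target_total New total; must not exceed `sum(depths)`.
#' @return Integer vector with `sum` exactly `target_total`; the expectation
#'   of each entry is scaled by `target_total / sum(depths)`.
#' @export
downsample <- function(depths, target_total) {
  stopifnot(all(depths >= 0))
  depths <- as.integer(depths)
  target_total <- as.integer(target_total)
  total <- sum(depths)
  if (is.na(target_total) || target_total < 0L) {
    stop("target_total must be a non-negative integer")
  }
  if (target_total > total) {
    stop("target_total (", target_total, ") exceeds available reads (",
         total, ")")
  }
  if (target_total == total) return(depths)
  out <- integer(length(depths))
  remaining_pool <- total
  remaining_draw <- target_total
  for (i in seq_along(depths)) {
    if (remaining_draw == 0L) break
    k <- stats::rhyper(1L, m = depths[i], n = remaining_pool - depths[i],
                       k = remaining_draw)
    out[i] <- k
    remaining_pool <- remaining_pool - depths[i]
    remaining_draw <- remaining_draw - k
  }
  names(out) <- names(depths)
  out
}

#' Count tags reaching a minimum read depth
#'
#' @param depths Read-depth vector (one genotype) or matrix.
#' @param min_depth Minimum depth threshold (>= 1).
#' @return For a vector, the number of tags with depth `>= min_depth`; for a
#'   matrix, a per-genotype (per-column) count vector.
#' @export
tags_at_depth <- function(depths, min_depth) {
  stopifnot(min_depth >= 1)
  if (is.matrix(depths)) return(colSums(depths >= min_depth))
  sum(depths >= min_depth)
}

#' Compare GBS protocols by tag yield at depth thresholds
#'
#' For each protocol (enzyme set + amplifiability rule + bias model), the
#' genome is digested once, then for each replicate and read budget a
#' per-genotype read sample is drawn and the number of tags reaching each
#' minimum-depth threshold is recorded. This is the engine behind
#' equal-read-budget protocol comparisons: protocols producing fewer
#' amplifiable fragments concentrate the same budget into higher per-tag
#' depth.
#'
#' @param genome See [as_genome()].
#' @param protocols Named list; each element a list with `enzymes` (list of
#'   [restriction_enzyme()]), `type` (see [select_amplifiable()]) and
#'   optionally `bias` (a [bias_model()], default uniform).
#' @param budgets Integer vector of per-genotype read budgets.
#' @param thresholds Integer vector of minimum read depths.
#' @param reps Replicate draws per combination (default 20).
#' @param tag_length Tag length (default 64).
#' @param seed Optional RNG seed for reproducibility.
#' @return Long-format data frame: `protocol`, `budget`, `threshold`, `rep`,
#'   `n_tags` (amplifiable tags in the protocol) and `tags_at_depth`.
#' @export
run_protocol_comparison <- function(genome, protocols, budgets,
                                    thresholds = c(2L, 6L, 11L),
                                    reps = 20L, tag_length = 64L,
                                    seed = NULL) {
  if (length(protocols) == 0L) stop("empty protocol list")
  if (is.null(names(protocols)) || any(!nzchar(names(protocols)))) {
    stop("protocols must be a named list")
  }
  if (!is.null(seed)) set.seed(seed)
  genome <- as_genome(genome)
  rows <- list()
  for (pname in names(protocols)) {
    proto <- protocols[[pname]]
    frags <- digest(genome, proto$enzymes)
    amp <- select_amplifiable(frags, proto$type)
    if (nrow(amp) == 0L) {
      stop("protocol '", pname, "' yields zero amplifiable fragments")
    }
    tags <- extract_tags(genome, amp, tag_length = tag_length)
    bias <- if (is.null(proto$bias)) bias_preset("uniform") else proto$bias
    w <- amplification_weights(tags, bias)
    for (budget in budgets) {
      for (r in seq_len(reps)) {
        depths <- sample_read_depths(w, budget, 1L)[, 1L]
        for (th in thresholds) {
          rows[[length(rows) + 1L]] <- data.frame(
            protocol = pname, budget = budget, threshold = th, rep = r,
            n_tags = nrow(tags), tags_at_depth = tags_at_depth(depths, th),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
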