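#' Ploidy model for read-depth genotype calling
#'
#' Describes the heterozygote allele-dose classes a calling pipeline must
#' distinguish from homozygotes. A diploid heterozygote carries allele-dose
#' fraction 1/2; an autotetraploid heterozygote carries 1/4, 2/4 or 3/4
#' (simplex, duplex, triplex). Calling pools all heterozygote classes into a
#' single HET class; the worst case for mistaking a heterozygote for a
#' homozygote is the most skewed class, with majority allele fraction
#' `max(f, 1 - f)` (3/4 for a tetraploid, 1/2 for a diploid).
#'
#' @param ploidy 2 or 4.
#' @return Object of class `ploidy_model` with fields `ploidy`,
#'   `het_doses` (allele-dose fractions) and `worst_fraction`.
#' @examples
#' ploidy_model(4)$worst_fraction  # 0.75
#' @export
ploidy_model <- function(ploidy) {
  ploidy <- as.integer(ploidy)
  if (!ploidy %in% c(2L, 4L)) stop("ploidy must be 2 or 4")
  het_doses <- seq_len(ploidy - 1L) / ploidy
  structure(list(ploidy = ploidy, het_doses = het_doses,
                 worst_fraction = max(pmax(het_doses, 1 - het_doses))),
            class = "ploidy_model")
}

#' Probability of miscalling a heterozygote as a homozygote
#'
#' At a truly heterozygous locus where one allele is sampled with
#' probability `f` per read, the probability that all `n` independent reads
#' show the same allele (so the locus looks homozygous) is
#' `f^n + (1 - f)^n`. For a triplex/simplex tetraploid heterozygote
#' (`f = 3/4`) at `n = 11` reads this is 4.22%.
#'
#' @param n Read depth (>= 1); vectorised.
#' @param f Majority allele fraction, in (0, 1).
#' @return Miscall probability, strictly decreasing in `n`.
#' @examples
#' miscall_probability(11, 0.75)  # 0.0422
#' @export
miscall_probability <- function(n, f) {
  if (any(f <= 0) || any(f >= 1)) stop("f must lie strictly in (0, 1)")
  if (any(n < 1)) stop("n must be >= 1")
  f^n + (1 - f)^n
}

#' Minimum read depth for a bounded heterozygote miscall rate
#'
#' Smallest depth `n` such that the probability of all reads showing one
#' allele at the worst-case heterozygous dose class falls below `alpha`.
#' With `alpha = 0.05` this gives 6 reads for an outbred diploid and 11 for
#' an outbred autotetraploid. Fully homozygous inbred lines have no
#' heterozygotes to collapse, so the binomial model does not apply; a
#' conventional depth of 2--3 (4 with residual heterozygosity) is used for
#' them instead.
#'
#' @param model A [ploidy_model()] (or ploidy 2/4, coerced).
#' @param alpha Type-I error bound in (0, 1) (default 0.05).
#' @return Minimum integer read depth.
#' @examples
#' min_depth_for_error(ploidy_model(2))  # 6
#' min_depth_for_error(ploidy_model(4))  # 11
#' @export
min_depth_for_error <- function(model, alpha = 0.05) {
  if (!inherits(model, "ploidy_model")) model <- ploidy_model(model)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  f <- model$worst_fraction
  n <- 1L
  while (miscall_probability(n, f) >= alpha) n <- n + 1L
  n
}

#' Minimum-depth rule for genotype calls
#'
#' The default (4 reads for heterozygous calls, 11 for homozygous calls)
#' is the filtering rule for autotetraploid panels: heterozygous loci seen
#' in fewer than 4 reads and homozygous loci seen in fewer than 11 reads
#' are set to missing, bounding the heterozygote-as-homozygote miscall rate
#' at 4.22%.
#'
#' @param min_depth_het,min_depth_hom Minimum total depths (>= 1).
#' @return Object of class `call_filter_rule`.
#' @export
call_filter_rule <- function(min_depth_het = 4L, min_depth_hom = 11L) {
  min_depth_het <- as.integer(min_depth_het)
  min_depth_hom <- as.integer(min_depth_hom)
  stopifnot(min_depth_het >= 1L, min_depth_hom >= 1L)
  structure(list(min_depth_het = min_depth_het,
                 min_depth_hom = min_depth_hom),
            class = "call_filter_rule")
}

#' Call a genotype from allele read counts
#'
#' Three-class calling: both alleles observed with sufficient total depth is
#' HET (tetraploid dose classes are pooled); a single allele observed with
#' depth at or above the homozygous minimum is the corresponding homozygote;
#' anything else is MISSING. A HET call is never produced from reads of a
#' single allele.
#'
#' @param a,b Read counts for the reference and alternative allele
#'   (vectorised, non-negative).
#' @param rule A [call_filter_rule()].
#' @return Character vector in `{"HOM_REF", "HOM_ALT", "HET", "MISSING"}`.
#' @examples
#' call_genotype(11, 0)  # HOM_REF
#' call_genotype(3, 1)   # HET (total 4 >= 4)
#' call_genotype(5, 0)   # MISSING (5 < 11)
#' @export
call_genotype <- function(a, b, rule = call_filter_rule()) {
  stopifnot(inherits(rule, "call_filter_rule"), all(a >= 0), all(b >= 0))
  n <- a + b
  out <- rep("MISSING", length(n))
  out[a > 0 & b > 0 & n >= rule$min_depth_het] <- "HET"
  out[a > 0 & b == 0 & a >= rule$min_depth_hom] <- "HOM_REF"
  out[b > 0 & a == 0 & b >= rule$min_depth_hom] <- "HOM_ALT"
  out
}

#' Numeric marker code of a genotype call
#'
#' Maps `HOM_REF`/`HET`/`HOM_ALT`/`MISSING` to `0`/`1`/`2`/`NA`, the coding
#' used by marker matrices (tetraploid heterozygote dose classes collapse to
#' the single code 1).
#'
#' @param call Character vector of calls.
#' @return Integer vector with `NA` for missing.
#' @export
call_to_code <- function(call) {
  code <- c(HOM_REF = 0L, HET = 1L, HOM_ALT = 2L, MISSING = NA_integer_)
  unname(code[call])
}

#' Expected missing-call rate under a depth distribution
#'
#' Analytic expectation of a MISSING call under a minimum-depth rule, by
#' total probability over read depth and allele-sampling outcomes. At a
#' truly homozygous locus all reads show one allele, so the call is missing
#' exactly when depth is below the homozygous minimum. At a truly
#' heterozygous locus with majority allele fraction `f`, all `n` reads show
#' one allele with probability `f^n + (1 - f)^n`, in which case the locus
#' looks homozygous and needs the homozygous minimum; otherwise both alleles
#' are seen and the heterozygous minimum applies.
#'
#' @param depth_probs Named numeric vector: `depth_probs[d]` is the
#'   probability of observing the depth given by `names(depth_probs)[d]`
#'   (non-negative integers); probabilities must sum to 1.
#' @param het_fraction Fraction of truly heterozygous loci, in `[0, 1]`.
#' @param rule A [call_filter_rule()].
#' @param het_doses Allele-dose fractions of the heterozygote classes,
#'   weighted equally (default diploid: `0.5`).
#' @return Expected probability of a MISSING call.
#' @export
expected_missing_rate <- function(depth_probs, het_fraction,
                                  rule = call_filter_rule(),
                                  het_doses = 0.5) {
  stopifnot(all(depth_probs >= 0), abs(sum(depth_probs) - 1) < 1e-8,
            het_fraction >= 0, het_fraction <= 1,
            all(het_doses > 0), all(het_doses < 1))
  depths <- as.integer(names(depth_probs))
  stopifnot(!any(is.na(depths)), all(depths >= 0))
  miss_hom <- as.numeric(depths < rule$min_depth_hom)
  miss_het_by_dose <- vapply(het_doses, function(f) {
    p_one_allele <- ifelse(depths == 0L, 1, f^depths + (1 - f)^depths)
    ifelse(depths == 0L, 1,
           (depths < rule$min_depth_het) * (1 - p_one_allele) +
           (depths < rule$min_depth_hom) * p_one_allele)
  }, numeric(length(depths)))
  miss_het <- rowMeans(matrix(miss_het_by_dose, nrow = length(depths)))
  sum(depth_probs * ((1 - het_fraction) * miss_hom + het_fraction * miss_het))
}
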