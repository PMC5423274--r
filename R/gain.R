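#' Standardized selection differential (selection intensity)
#'
#' For an infinitely large candidate population, the mean of the selected
#' upper fraction `p` of a standard normal distribution is
#' `i = phi(z) / p`, where `z` is the `(1 - p)` quantile and `phi` the
#' standard normal density. Selecting 15 of 300 candidates (p = 5%) gives
#' i = 2.06; 15 of 2250 (p = 0.667%) gives i = 2.80. An optional
#' finite-population value averages the expected top-`k` order statistics
#' (Blom approximation) and is never applied silently.
#'
#' @param p Selected fraction in (0, 1]; vectorised. `p = 1` returns 0.
#' @param method `"infinite"` (default, truncated-normal mean) or
#'   `"finite"` (requires `N`; uses `k = round(p * N)` order statistics).
#' @param N Candidate population size for `method = "finite"`.
#' @return Selection intensity, strictly decreasing in `p`.
#' @examples
#' selection_intensity(15 / 300)   # 2.06
#' selection_intensity(15 / 2250)  # 2.80
#' @export
selection_intensity <- function(p, method = c("infinite", "finite"),
                                N = NULL) {
  method <- match.arg(method)
  if (any(p <= 0) || any(p > 1)) stop("selected fraction p must lie in (0, 1]")
  if (method == "infinite") {
    i <- ifelse(p == 1, 0, stats::dnorm(stats::qnorm(1 - p)) / p)
    return(as.numeric(i))
  }
  if (is.null(N)) stop("method = 'finite' requires the candidate count N")
  vapply(p, function(pp) {
    k <- max(1L, round(pp * N))
    ranks <- N - seq_len(k) + 1L
    mean(stats::qnorm((ranks - 0.375) / (N + 0.25)))
  }, numeric(1))
}

#' Broad-sense heritability on an entry-mean basis
#'
#' `H2 = s_g^2 / (s_g^2 + s_ge^2 / e + s_e^2 / (e r))` for genotype,
#' genotype-by-environment and pooled error variance components estimated
#' over `e` environments and `r` replications. Non-decreasing in both `e`
#' and `r`, bounded in `[0, 1]`.
#'
#' @param s_g2,s_ge2,s_e2 Variance components (>= 0, not all zero).
#' @param e,r Numbers of test environments and replications (>= 1).
#' @return Broad-sense heritability in `[0, 1]`.
#' @examples
#' broad_sense_heritability(1, 1, 1, e = 1, r = 1)  # 1/3
#' @export
broad_sense_heritability <- function(s_g2, s_ge2, s_e2, e = 1, r = 1) {
  stopifnot(s_g2 >= 0, s_ge2 >= 0, s_e2 >= 0, e >= 1, r >= 1)
  denom <- s_g2 + s_ge2 / e + s_e2 / (e * r)
  if (denom == 0) stop("all variance components are zero")
  s_g2 / denom
}

#' Describe a selection scheme
#'
#' Bundles the quantities of the gain-per-year formulas
#' `dG_P = i_P h s_A r_gP / t_P` (phenotypic) and
#' `dG_G = i_G r_A s_A r_gG / t_G` (genomic): the accuracy (square root of
#' heritability for phenotypic selection, genomic accuracy `r_A` for
#' genomic selection), the cycle length in years, the selected count `k`
#' out of `N` candidates (or a directly supplied intensity), the genetic
#' correlation between selection and target conditions, and optionally the
#' evaluation cost per genotype for equal-cost comparisons.
#'
#' @param mode `"phenotypic"` or `"genomic"`.
#' @param accuracy Accuracy in `[0, 1]` (`h`, `H`, or `r_A`).
#' @param cycle_years Cycle length in years (> 0).
#' @param k,N Selected count and candidate count (used when `intensity` is
#'   not given).
#' @param intensity Optional selection intensity overriding `k`/`N` (e.g. a
#'   published value).
#' @param genetic_correlation Genetic correlation with the target
#'   conditions, in `[-1, 1]` (default 1).
#' @param cost_per_genotype Optional evaluation cost per candidate.
#' @return Object of class `selection_scheme`.
#' @export
selection_scheme <- function(mode = c("phenotypic", "genomic"), accuracy,
                             cycle_years, k = NULL, N = NULL,
                             intensity = NULL, genetic_correlation = 1,
                             cost_per_genotype = NULL) {
  mode <- match.arg(mode)
  stopifnot(accuracy >= 0, accuracy <= 1, cycle_years > 0,
            genetic_correlation >= -1, genetic_correlation <= 1)
  if (is.null(intensity)) {
    if (is.null(k)) {
      stop("supply either an intensity or the selected count k (with N, ",
           "or with costs so N can be derived at comparison time)")
    }
    stopifnot(k >= 1)
    if (!is.null(N)) stopifnot(k <= N)
  }
  structure(list(mode = mode, accuracy = accuracy,
                 cycle_years = cycle_years, k = k, N = N,
                 intensity = intensity,
                 genetic_correlation = genetic_correlation,
                 cost_per_genotype = cost_per_genotype),
            class = "selection_scheme")
}

scheme_intensity <- function(scheme) {
  if (!is.null(scheme$intensity)) return(scheme$intensity)
  if (is.null(scheme$N)) {
    stop("scheme has no candidate count N and no direct intensity; ",
         "derive N first (see compare_schemes_equal_cost)")
  }
  selection_intensity(scheme$k / scheme$N)
}

#' @export
print.selection_scheme <- function(x, ...) {
  cat("<selection_scheme> ", x$mode, ": accuracy ", x$accuracy,
      ", cycle ", x$cycle_years, " yr, i = ",
      format(scheme_intensity(x), digits = 3), "\n", sep = "")
  invisible(x)
}

#' Predicted genetic gain per year of a selection scheme
#'
#' `dG = i x accuracy x s_A x r_g / t`, the breeder's equation on a
#' per-year basis. With the defaults `s_A = 1` and `r_g = 1`, gains are in
#' units of breeding-value standard deviations per year.
#'
#' @param scheme A [selection_scheme()].
#' @param s_A Standard deviation of breeding values (default 1).
#' @return Predicted gain per year.
#' @examples
#' ph <- selection_scheme("phenotypic", accuracy = 0.46, cycle_years = 5,
#'                        k = 15, N = 300)
#' gain_per_year(ph)  # 0.189
#' @export
gain_per_year <- function(scheme, s_A = 1) {
  stopifnot(inherits(scheme, "selection_scheme"), s_A > 0)
  scheme_intensity(scheme) * scheme$accuracy * s_A *
    scheme$genetic_correlation / scheme$cycle_years
}

#' Compare phenotypic and genomic selection at equal cost
#'
#' Computes gain per year for both schemes and their ratio. When the
#' genomic scheme's candidate count is not given but both costs are, the
#' genomic count is scaled to equal total evaluation cost:
#' `N_G = N_P x cost_P / cost_G`, which raises the genomic selection
#' intensity at the same budget. Published intensities supplied via
#' `intensity` override the truncated-normal computation.
#'
#' @param phenotypic,genomic [selection_scheme()] objects.
#' @param s_A Standard deviation of breeding values (default 1; the ratio
#'   is invariant to it).
#' @return Object of class `scheme_comparison`: list with `gain_phenotypic`,
#'   `gain_genomic`, `ratio`, `intensity_phenotypic`, `intensity_genomic`,
#'   `break_even_accuracy` (genomic accuracy at which the gains would be
#'   equal) and the input schemes.
#' @export
compare_schemes_equal_cost <- function(phenotypic, genomic, s_A = 1) {
  stopifnot(inherits(phenotypic, "selection_scheme"),
            inherits(genomic, "selection_scheme"))
  if (is.null(genomic$intensity) && is.null(genomic$N)) {
    if (is.null(phenotypic$cost_per_genotype) ||
        is.null(genomic$cost_per_genotype) || is.null(phenotypic$N)) {
      stop("genomic candidates must be given directly or derivable from ",
           "costs (both cost_per_genotype values and the phenotypic N)")
    }
    genomic$N <- phenotypic$N * phenotypic$cost_per_genotype /
      genomic$cost_per_genotype
    if (genomic$N < genomic$k) {
      stop("equal-cost genomic candidate count (", round(genomic$N, 1),
           ") is below the selected count k = ", genomic$k)
    }
  }
  g_p <- gain_per_year(phenotypic, s_A)
  g_g <- gain_per_year(genomic, s_A)
  structure(list(
    gain_phenotypic = g_p,
    gain_genomic = g_g,
    ratio = if (g_p > 0) g_g / g_p else NA_real_,
    intensity_phenotypic = scheme_intensity(phenotypic),
    intensity_genomic = scheme_intensity(genomic),
    break_even_accuracy = break_even_accuracy(phenotypic, genomic,
                                              advantage_factor = 1),
    phenotypic = phenotypic, genomic = genomic, s_A = s_A
  ), class = "scheme_comparison")
}

#' @export
print.scheme_comparison <- function(x, ...) {
  cat("<scheme_comparison>\n")
  cat(sprintf("  phenotypic gain/yr: %.3f (i = %.2f)\n",
              x$gain_phenotypic, x$intensity_phenotypic))
  cat(sprintf("  genomic gain/yr:    %.3f (i = %.2f)\n",
              x$gain_genomic, x$intensity_genomic))
  cat(sprintf("  genomic : phenotypic ratio: %.2f\n", x$ratio))
  cat(sprintf("  break-even genomic accuracy: %.3f\n",
              x$break_even_accuracy))
  invisible(x)
}

#' Genomic accuracy needed for a given advantage over phenotypic selection
#'
#' Solves `dG_G = advantage_factor x dG_P` for the genomic accuracy:
#' `r_A = advantage_factor x accuracy_P x i_P x t_G / (i_G x t_P)` (genetic
#' correlations assumed equal on both sides).
#'
#' @param phenotypic,genomic [selection_scheme()] objects (the genomic
#'   scheme's accuracy is ignored).
#' @param advantage_factor Desired gain ratio genomic / phenotypic
#'   (default 1, the break-even point).
#' @return The required genomic accuracy `r_A`.
#' @export
break_even_accuracy <- function(phenotypic, genomic, advantage_factor = 1) {
  stopifnot(inherits(phenotypic, "selection_scheme"),
            inherits(genomic, "selection_scheme"), advantage_factor >= 0)
  i_p <- scheme_intensity(phenotypic)
  i_g <- scheme_intensity(genomic)
  if (i_g == 0) stop("genomic selection intensity is zero")
  advantage_factor * phenotypic$accuracy * i_p * genomic$cycle_years /
    (i_g * phenotypic$cycle_years)
}

#' Working population size for independent multi-trait selection
#'
#' Selecting `k` genotypes that simultaneously pass independent truncation
#' at rate `per_trait_rate` on each of `n_traits` traits requires
#' `k x (1 / per_trait_rate)^n_traits` candidates (rounded up). Ten
#' genotypes selected for 4 traits at a 20% rate each require 6,250
#' individuals.
#'
#' @param k Number of selected genotypes.
#' @param n_traits Number of independently selected traits (>= 0).
#' @param per_trait_rate Selection rate per trait in (0, 1].
#' @return Required candidate count (integer).
#' @examples
#' multi_trait_population_size(10, 4, 0.20)  # 6250
#' @export
multi_trait_population_size <- function(k, n_traits, per_trait_rate) {
  stopifnot(k >= 1, n_traits >= 0)
  if (per_trait_rate <= 0 || per_trait_rate > 1) {
    stop("per_trait_rate must lie in (0, 1]")
  }
  as.integer(ceiling(k * (1 / per_trait_rate)^n_traits))
}

#' Phenotypic-to-genomic cost ratios from cost ranges
#'
#' Given per-genotype evaluation cost ranges for phenotypic and genomic
#' selection, returns the extreme and midpoint cost ratios: the minimum
#' ratio pairs the cheapest phenotypic with the dearest genomic cost, the
#' maximum the reverse, and the midpoint ratio uses the arithmetic means of
#' the two ranges.
#'
#' @param phen_low,phen_high Phenotypic cost range per genotype.
#' @param gen_low,gen_high Genomic cost range per genotype (> 0).
#' @return Named list: `min`, `mid`, `max` ratios.
#' @examples
#' cost_ratio_summary(230, 280, 32, 36)$mid  # 7.5 (forage legume)
#' @export
cost_ratio_summary <- function(phen_low, phen_high, gen_low, gen_high) {
  stopifnot(phen_low <= phen_high, gen_low <= gen_high)
  if (gen_low <= 0) stop("genomic cost must be positive")
  list(min = phen_low / gen_high,
       mid = mean(c(phen_low, phen_high)) / mean(c(gen_low, gen_high)),
       max = phen_high / gen_low)
}

#' Read a selection-comparison scenario from YAML
#'
#' The scenario file holds two blocks, `phenotypic` and `genomic`, each with
#' the [selection_scheme()] fields (`accuracy`, `cycle_years`, `k`,
#' `candidates`, `intensity`, `genetic_correlation`, `cost_per_genotype`),
#' plus an optional top-level `s_A`. Packaged examples:
#' `system.file("extdata", "scenario_alfalfa.yaml", package = "gbsdesign")`
#' and `scenario_pea.yaml`.
#'
#' @param path Path to the YAML scenario file.
#' @return List with `phenotypic` and `genomic` [selection_scheme()]s and
#'   `s_A`.
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  build <- function(block, mode) {
    selection_scheme(
      mode = mode,
      accuracy = block$accuracy,
      cycle_years = block$cycle_years,
      # the candidate count is named 'candidates' in YAML (a bare 'N' key
      # would be read as a boolean under YAML 1.1)
      k = block$k,
      N = if (!is.null(block$candidates)) block$candidates else block[["N"]],
      intensity = block$intensity,
      genetic_correlation = if (is.null(block$genetic_correlation)) 1
                            else block$genetic_correlation,
      cost_per_genotype = block$cost_per_genotype
    )
  }
  if (is.null(cfg$phenotypic) || is.null(cfg$genomic)) {
    stop("scenario file must contain 'phenotypic' and 'genomic' blocks: ",
         path)
  }
  list(phenotypic = build(cfg$phenotypic, "phenotypic"),
       genomic = build(cfg$genomic, "genomic"),
       s_A = if (is.null(cfg$s_A)) 1 else cfg$s_A)
}
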