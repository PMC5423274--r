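#' Run a pipeline stage from a configuration
#'
#' Single entry point behind the command-line wrapper
#' (`inst/scripts/gbsdesign.R`). Each subcommand reads its parameters from a
#' YAML configuration (path or list), writes TSV artifacts into `out_dir`,
#' and records a `manifest.yaml` with the subcommand, full configuration,
#' seed and package version, so every artifact is reproducible from its
#' manifest alone.
#'
#' Subcommands:
#' \describe{
#'   \item{`simulate`}{synthetic genome + panel + end-to-end GBS dataset;
#'     writes `genome.fasta`, `calls.tsv`, `truth.tsv`, `depth.tsv`.}
#'   \item{`digest`}{in-silico digestion of a FASTA; writes
#'     `fragments.tsv` (BED-like: chrom, start, end, enzymes, length, GC).}
#'   \item{`sample`}{protocol comparison by tag yield at depth thresholds;
#'     writes `protocol_comparison.tsv`.}
#'   \item{`thresholds`}{minimum-depth table across ploidies and error
#'     rates; writes `depth_thresholds.tsv`.}
#'   \item{`predict`}{marker filtering, imputation and cross-validated
#'     predictive ability, optionally over a missing-threshold sweep;
#'     writes `prediction.tsv`.}
#'   \item{`gain`}{equal-cost phenotypic vs genomic comparison from a
#'     scenario file; writes `gain_comparison.tsv`.}
#' }
#'
#' @param subcommand One of the stage names above.
#' @param config YAML file path or an equivalent nested list.
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed controlling all randomness of the stage.
#' @return (Invisibly) a character vector of the files written.
#' @export
gbs_run <- function(subcommand = c("simulate", "digest", "sample",
                                   "thresholds", "predict", "gain"),
                    config, out_dir, seed = 1L) {
  subcommand <- match.arg(subcommand)
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config_path <- config
    config <- yaml::read_yaml(config)
  } else {
    config_path <- NA_character_
  }
  stopifnot(is.list(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)

  files <- switch(subcommand,
    simulate = .run_simulate(config, out_dir),
    digest = .run_digest(config, out_dir),
    sample = .run_sample(config, out_dir),
    thresholds = .run_thresholds(config, out_dir),
    predict = .run_predict(config, out_dir),
    gain = .run_gain(config, out_dir)
  )
  manifest <- list(subcommand = subcommand, seed = seed,
                   config = config, config_path = config_path,
                   package = "gbsdesign",
                   version = as.character(utils::packageVersion("gbsdesign")))
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  invisible(c(files, manifest_path))
}

.cfg <- function(config, name, default = NULL, required = FALSE) {
  val <- config[[name]]
  if (is.null(val)) {
    if (required) stop("missing required config field: ", name)
    return(default)
  }
  val
}

.resolve_enzymes <- function(names_or_defs) {
  defaults <- load_enzymes()
  lapply(names_or_defs, function(e) {
    if (is.character(e)) {
      if (!e %in% names(defaults)) stop("unknown enzyme: ", e)
      defaults[[e]]
    } else {
      restriction_enzyme(e$name, e$recognition, e$cut_offset)
    }
  })
}

.run_simulate <- function(config, out_dir) {
  gcfg <- .cfg(config, "genome", required = TRUE)
  genome <- simulate_genome(
    total_length = .cfg(gcfg, "total_length", required = TRUE),
    n_chromosomes = .cfg(gcfg, "n_chromosomes", 1L),
    gc_content = .cfg(gcfg, "gc_content", 0.5)
  )
  pcfg <- .cfg(config, "panel", required = TRUE)
  spec <- panel_spec(
    n_genotypes = .cfg(pcfg, "n_genotypes", required = TRUE),
    ploidy = .cfg(pcfg, "ploidy", 2L),
    breeding_system = .cfg(pcfg, "breeding_system", "inbred"),
    snp_rate = .cfg(pcfg, "snp_rate", 0.3)
  )
  prcfg <- .cfg(config, "protocol", required = TRUE)
  protocol <- list(name = .cfg(prcfg, "name", "protocol"),
                   enzymes = .resolve_enzymes(.cfg(prcfg, "enzymes",
                                                   required = TRUE)),
                   type = .cfg(prcfg, "type", "single"))
  rcfg <- .cfg(config, "rule", list())
  rule <- call_filter_rule(.cfg(rcfg, "min_depth_het", 4L),
                           .cfg(rcfg, "min_depth_hom", 11L))
  ds <- simulate_gbs_dataset(
    genome, spec, protocol,
    bias = bias_preset(.cfg(config, "bias", "uniform")),
    reads_per_genotype = .cfg(config, "reads_per_genotype", 20000L),
    rule = rule,
    tag_length = .cfg(config, "tag_length", 64L)
  )
  paths <- c(
    write_genome_fasta(genome, file.path(out_dir, "genome.fasta")),
    write_marker_matrix(ds$calls, file.path(out_dir, "calls.tsv")),
    write_marker_matrix(ds$truth, file.path(out_dir, "truth.tsv")),
    write_tsv_table(ds$depth, file.path(out_dir, "depth.tsv"),
                    row_names = "tag")
  )
  paths
}

.run_digest <- function(config, out_dir) {
  fasta <- .cfg(config, "fasta", required = TRUE)
  if (!file.exists(fasta)) stop("input FASTA not found: ", fasta)
  genome <- read_genome_fasta(fasta)
  enzymes <- .resolve_enzymes(.cfg(config, "enzymes", required = TRUE))
  frags <- digest(genome, enzymes)
  protocol <- .cfg(config, "protocol")
  if (!is.null(protocol)) frags <- select_amplifiable(frags, protocol)
  write_tsv_table(frags, file.path(out_dir, "fragments.tsv"))
}

.run_sample <- function(config, out_dir) {
  fasta <- .cfg(config, "fasta")
  genome <- if (!is.null(fasta)) {
    read_genome_fasta(fasta)
  } else {
    gcfg <- .cfg(config, "genome", required = TRUE)
    simulate_genome(.cfg(gcfg, "total_length", required = TRUE),
                    .cfg(gcfg, "n_chromosomes", 1L),
                    .cfg(gcfg, "gc_content", 0.5))
  }
  pconfigs <- .cfg(config, "protocols", required = TRUE)
  protocols <- lapply(pconfigs, function(p) {
    list(enzymes = .resolve_enzymes(p$enzymes),
         type = .cfg(p, "type", "single"),
         bias = bias_preset(.cfg(p, "bias", "uniform")))
  })
  res <- run_protocol_comparison(
    genome, protocols,
    budgets = .cfg(config, "budgets", required = TRUE),
    thresholds = .cfg(config, "thresholds", c(2L, 6L, 11L)),
    reps = .cfg(config, "reps", 20L),
    tag_length = .cfg(config, "tag_length", 64L)
  )
  write_tsv_table(res, file.path(out_dir, "protocol_comparison.tsv"))
}

.run_thresholds <- function(config, out_dir) {
  alphas <- .cfg(config, "alphas", 0.05)
  ploidies <- .cfg(config, "ploidies", c(2L, 4L))
  grid <- expand.grid(ploidy = ploidies, alpha = alphas)
  grid$min_depth <- mapply(function(pl, a) {
    min_depth_for_error(ploidy_model(pl), a)
  }, grid$ploidy, grid$alpha)
  grid$worst_fraction <- vapply(grid$ploidy,
                                function(pl) ploidy_model(pl)$worst_fraction,
                                numeric(1))
  grid$miscall_at_depth <- miscall_probability(grid$min_depth,
                                               grid$worst_fraction)
  write_tsv_table(grid, file.path(out_dir, "depth_thresholds.tsv"))
}

.run_predict <- function(config, out_dir) {
  calls <- read_marker_matrix(.cfg(config, "markers", required = TRUE))
  y <- read_phenotypes(.cfg(config, "phenotypes", required = TRUE))
  y <- y[rownames(calls)]
  thresholds <- .cfg(config, "missing_thresholds", 0.3)
  res <- missing_threshold_sweep(
    calls, y, thresholds = thresholds,
    min_maf = .cfg(config, "min_maf", 0.025),
    k = .cfg(config, "knn_k", 5L),
    n_folds = .cfg(config, "n_folds", 10L),
    n_reps = .cfg(config, "n_reps", 10L),
    seed = sample.int(2^30, 1L)
  )
  write_tsv_table(res, file.path(out_dir, "prediction.tsv"))
}

.run_gain <- function(config, out_dir) {
  scn <- if (!is.null(config$scenario)) {
    read_scenario(config$scenario)
  } else {
    tmp <- tempfile(fileext = ".yaml")
    on.exit(unlink(tmp))
    yaml::write_yaml(config, tmp)
    read_scenario(tmp)
  }
  cmp <- compare_schemes_equal_cost(scn$phenotypic, scn$genomic,
                                    s_A = scn$s_A)
  report <- data.frame(
    quantity = c("gain_phenotypic_per_year", "gain_genomic_per_year",
                 "ratio_genomic_phenotypic", "intensity_phenotypic",
                 "intensity_genomic", "break_even_accuracy"),
    value = c(cmp$gain_phenotypic, cmp$gain_genomic, cmp$ratio,
              cmp$intensity_phenotypic, cmp$intensity_genomic,
              cmp$break_even_accuracy)
  )
  write_tsv_table(report, file.path(out_dir, "gain_comparison.tsv"))
}
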