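locus_maf <- function(marker_matrix) {
  apply(marker_matrix, 2L, function(col) {
    obs <- col[!is.na(col)]
    if (length(obs) == 0L) return(NA_real_)
    f <- sum(obs) / (2 * length(obs))  # het carries one copy of each allele
    min(f, 1 - f)
  })
}

#' Filter markers by minor allele frequency
#'
#' MAF is computed over non-missing calls with a heterozygote contributing
#' one copy of each allele. Loci with MAF strictly below `min_maf` are
#' removed (a locus at exactly the boundary is retained); monomorphic loci
#' (MAF 0) are always removed.
#'
#' @param marker_matrix Genotype x locus matrix coded 0/1/2 with `NA`
#'   missing.
#' @param min_maf Minimum minor allele frequency (default 0.025).
#' @return The filtered matrix; a warning is emitted if no locus survives.
#' @export
maf_filter <- function(marker_matrix, min_maf = 0.025) {
  maf <- locus_maf(marker_matrix)
  keep <- !is.na(maf) & maf >= min_maf
  if (!any(keep)) warning("MAF filter removed every locus")
  marker_matrix[, keep, drop = FALSE]
}

#' Filter markers by missing-call rate
#'
#' @param marker_matrix Genotype x locus matrix with `NA` missing.
#' @param max_missing Maximum tolerated missing fraction per locus in
#'   `[0, 1]`; loci with a strictly greater missing fraction are removed.
#' @return The filtered matrix.
#' @export
missing_rate_filter <- function(marker_matrix, max_missing) {
  stopifnot(max_missing >= 0, max_missing <= 1)
  miss <- colMeans(is.na(marker_matrix))
  marker_matrix[, miss <= max_missing, drop = FALSE]
}

#' K-nearest-neighbour imputation of missing marker calls
#'
#' Genotype-to-genotype distances are root-mean-square code differences over
#' jointly observed loci (so sparsity does not inflate distances). Each
#' missing entry is replaced by the inverse-distance-weighted mean code of
#' the `k` nearest genotypes observed at that locus, rounded to the nearest
#' valid code. Observed entries are never altered.
#'
#' @param marker_matrix Genotype x locus matrix coded 0/1/2 with `NA`.
#' @param k Number of neighbours (default 5).
#' @return A complete matrix of the same shape.
#' @export
knn_impute <- function(marker_matrix, k = 5L) {
  stopifnot(k >= 1L)
  M <- marker_matrix
  n <- nrow(M)
  if (!anyNA(M)) return(M)
  fully_missing <- colSums(!is.na(M)) == 0L
  if (any(fully_missing)) {
    stop("locus with no observed call cannot be imputed: ",
         paste(utils::head(colnames(M)[fully_missing], 3L), collapse = ", "))
  }
  obs <- !is.na(M)
  shared <- obs %*% t(obs)  # jointly observed locus counts
  M0 <- M
  M0[!obs] <- 0
  # sum of squared differences over shared loci, via the expansion
  # sum((x - y)^2 * obs_x * obs_y)
  sq <- M0^2
  ssd <- pmax((sq %*% t(obs)) + (obs %*% t(sq)) - 2 * (M0 %*% t(M0)), 0)
  d <- sqrt(ssd / pmax(shared, 1L))
  d[shared == 0L] <- Inf
  diag(d) <- Inf
  disconnected <- apply(is.finite(d), 1L, sum) == 0L
  if (any(disconnected)) {
    stop("genotype shares no observed locus with any other genotype: ",
         paste(utils::head(rownames(M)[disconnected], 3L), collapse = ", "))
  }
  codes <- sort(unique(as.vector(M[obs])))
  for (i in seq_len(n)) {
    miss_loci <- which(!obs[i, ])
    if (length(miss_loci) == 0L) next
    ord <- order(d[i, ])
    for (l in miss_loci) {
      donors <- ord[obs[ord, l] & is.finite(d[i, ord])]
      if (length(donors) == 0L) {
        stop("no informative neighbour for genotype ", rownames(M)[i],
             " at locus ", colnames(M)[l])
      }
      nb <- donors[seq_len(min(k, length(donors)))]
      wts <- 1 / (d[i, nb] + 1e-6)
      est <- sum(wts * M[nb, l]) / sum(wts)
      M[i, l] <- codes[which.min(abs(codes - est))]
    }
  }
  M
}

#' Fit a ridge-regression (RR-BLUP) marker-effect model
#'
#' Solves the ridge system `b = (Xc'Xc + lambda I)^{-1} Xc' (y - mean(y))`
#' on column-centred marker codes. When `shrinkage` is `NULL` the ridge
#' parameter `lambda = sigma_e^2 / sigma_b^2` is estimated by restricted
#' maximum likelihood through a one-dimensional spectral optimisation of the
#' marker relationship matrix (the standard efficient mixed-model
#' computation), which is deterministic given the data. The intercept is
#' the training mean.
#'
#' @param X Complete genotype x marker matrix (no missing values).
#' @param y Phenotype vector, length `nrow(X)`.
#' @param shrinkage Optional fixed ridge parameter; `Inf` shrinks all
#'   effects to zero so predictions equal the training mean.
#' @return Object of class `ridge_blup` with fields `mu`, `effects`,
#'   `centers`, `shrinkage`, `sigma2_b`, `sigma2_e`.
#' @export
fit_ridge_predictor <- function(X, y, shrinkage = NULL) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), nrow(X) >= 2L)
  if (anyNA(X)) stop("X contains missing values; impute first")
  if (stats::sd(y) == 0) stop("phenotype has zero variance")
  n <- nrow(X)
  p <- ncol(X)
  centers <- colMeans(X)
  Xc <- sweep(X, 2L, centers)
  mu <- mean(y)
  yc <- y - mu

  if (!is.null(shrinkage) && is.infinite(shrinkage)) {
    return(structure(list(mu = mu, effects = rep(0, p), centers = centers,
                          shrinkage = Inf, sigma2_b = 0, sigma2_e = var(y)),
                     class = "ridge_blup"))
  }

  if (is.null(shrinkage)) {
    # REML for y = mu + Xc b + e, b ~ N(0, s2b I): spectral decomposition of
    # Xc Xc' restricted to the space orthogonal to the intercept
    Q2 <- qr.Q(qr(matrix(1, n, 1)), complete = TRUE)[, -1L, drop = FALSE]
    K <- tcrossprod(Xc)
    ev <- eigen(crossprod(Q2, K %*% Q2), symmetric = TRUE)
    xi <- pmax(ev$values, 0)
    eta <- as.numeric(crossprod(ev$vectors, crossprod(Q2, y)))
    reml <- function(log_delta) {
      delta <- exp(log_delta)
      denom <- xi + delta
      rss <- sum(eta^2 / denom)
      -0.5 * ((n - 1) * log(rss) + sum(log(denom)))
    }
    scale_ref <- max(mean(xi), 1e-8)
    opt <- stats::optimize(reml, interval = log(scale_ref) + c(-15, 15),
                           maximum = TRUE, tol = 1e-8)
    shrinkage <- exp(opt$maximum)
    sigma2_b <- sum(eta^2 / (xi + shrinkage)) / (n - 1)
    sigma2_e <- shrinkage * sigma2_b
    effects <- as.numeric(crossprod(Xc, Q2 %*% (ev$vectors %*%
      (eta / (xi + shrinkage)))))
  } else {
    stopifnot(shrinkage >= 0)
    if (p <= n) {
      effects <- as.numeric(solve(crossprod(Xc) + shrinkage * diag(p),
                                  crossprod(Xc, yc)))
    } else {
      K <- tcrossprod(Xc)
      effects <- as.numeric(crossprod(Xc, solve(K + shrinkage * diag(n), yc)))
    }
    sigma2_b <- NA_real_
    sigma2_e <- NA_real_
  }
  structure(list(mu = mu, effects = effects, centers = centers,
                 shrinkage = shrinkage, sigma2_b = sigma2_b,
                 sigma2_e = sigma2_e),
            class = "ridge_blup")
}

#' @export
predict.ridge_blup <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  stopifnot(ncol(newdata) == length(object$effects))
  as.numeric(object$mu +
               sweep(newdata, 2L, object$centers) %*% object$effects)
}

#' @export
print.ridge_blup <- function(x, ...) {
  cat("<ridge_blup> ", length(x$effects), " marker effects; shrinkage ",
      format(x$shrinkage, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Cross-validated predictive ability
#'
#' Genotypes are partitioned into folds; for each fold the ridge model is
#' trained on the remaining genotypes and the Pearson correlation between
#' predicted and observed phenotypes of the held-out fold is recorded.
#' Predictive ability is the mean of these correlations over folds and
#' repeats. No correction by heritability is applied, so the estimate is a
#' deliberately conservative proxy for prediction accuracy.
#'
#' @param X Complete genotype x marker matrix.
#' @param y Phenotypes.
#' @param n_folds,n_reps Fold count per repeat and number of repeated random
#'   partitions (default 10 x 10).
#' @param seed Optional RNG seed; identical seeds give identical fold
#'   assignments and results.
#' @return Object of class `cv_result`: list with `ability` (mean), `sd`,
#'   `folds` (per-fold data frame), `n_folds`, `n_reps`, `seed`.
#' @export
cross_validate <- function(X, y, n_folds = 10L, n_reps = 10L, seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n, n >= n_folds, n_folds >= 2L, n_reps >= 1L)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (rep_i in seq_len(n_reps)) {
    fold_of <- sample(rep(seq_len(n_folds), length.out = n))
    for (f in seq_len(n_folds)) {
      test <- fold_of == f
      if (sum(test) < 2L || stats::sd(y[test]) == 0) {
        warning("fold ", f, " of rep ", rep_i,
                " skipped: constant or tiny held-out phenotype")
        next
      }
      fit <- fit_ridge_predictor(X[!test, , drop = FALSE], y[!test])
      pred <- predict(fit, X[test, , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        rep = rep_i, fold = f, n_test = sum(test),
        ability = stats::cor(pred, y[test]))
    }
  }
  folds <- do.call(rbind, rows)
  structure(list(ability = mean(folds$ability), sd = stats::sd(folds$ability),
                 folds = folds, n_folds = n_folds, n_reps = n_reps,
                 seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> predictive ability %.3f (sd %.3f) over %d x %d CV\n",
              x$ability, x$sd, x$n_folds, x$n_reps))
  invisible(x)
}

#' Predictive ability across missing-data thresholds
#'
#' For each missing-rate threshold the marker matrix is filtered
#' ([missing_rate_filter()] then [maf_filter()]), imputed
#' ([knn_impute()]) and cross-validated ([cross_validate()]). Relaxing the
#' threshold admits more markers but also more imputation noise; inspecting
#' the resulting curve locates the trade-off (empirically a peak of
#' predictive ability at intermediate thresholds).
#'
#' @param calls Genotype x locus marker matrix with `NA` for missing.
#' @param y Phenotypes.
#' @param thresholds Missing-rate thresholds to sweep (fractions in
#'   `[0, 1]`).
#' @param min_maf,k,n_folds,n_reps See the component functions.
#' @param seed RNG seed for the fold assignments (one per threshold, drawn
#'   from this seed).
#' @return Data frame with `threshold`, `n_markers`, `ability` (`NA` when no
#'   marker survives).
#' @export
missing_threshold_sweep <- function(calls, y, thresholds = c(0, 0.1, 0.2,
                                                             0.3, 0.4, 0.5),
                                    min_maf = 0.025, k = 5L, n_folds = 5L,
                                    n_reps = 2L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  # one shared fold seed: thresholds are compared on common fold assignments
  fold_seed <- sample.int(2^30, 1L)
  rows <- lapply(seq_along(thresholds), function(i) {
    th <- thresholds[i]
    M <- missing_rate_filter(calls, th)
    M <- suppressWarnings(maf_filter(M, min_maf))
    if (ncol(M) == 0L) {
      return(data.frame(threshold = th, n_markers = 0L, ability = NA_real_))
    }
    M <- knn_impute(M, k = k)
    cv <- cross_validate(M, y, n_folds = n_folds, n_reps = n_reps,
                         seed = fold_seed)
    data.frame(threshold = th, n_markers = ncol(M), ability = cv$ability)
  })
  do.call(rbind, rows)
}

#' Count polymorphic loci shared by all genotypes
#'
#' A locus counts when it is called (non-missing) in every genotype of the
#' panel and segregates among them -- the standard yardstick for comparing
#' GBS protocols by exploitable marker yield.
#'
#' @param calls Genotype x locus marker matrix with `NA` for missing.
#' @return Integer count.
#' @export
count_shared_polymorphic <- function(calls) {
  complete <- colSums(is.na(calls)) == 0L
  poly <- apply(calls, 2L, function(col) {
    obs <- col[!is.na(col)]
    length(unique(obs)) > 1L
  })
  sum(complete & poly)
}
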