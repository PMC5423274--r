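test_that("MAF filtering uses the strict below-threshold rule", {
  # 40 genotypes, a single heterozygous carrier: MAF = 1/80 = 1.25%
  M <- matrix(0L, nrow = 40, ncol = 3,
              dimnames = list(paste0("g", 1:40), c("l1", "l2", "l3")))
  M[1, 1] <- 1L                      # MAF 0.0125 -> removed
  M[1:2, 2] <- 1L                    # MAF 2/80 = 0.025 -> retained (boundary)
  # l3 monomorphic -> removed
  out <- maf_filter(M, 0.025)
  expect_equal(colnames(out), "l2")

  expect_warning(maf_filter(M[, 3, drop = FALSE]), "every locus")

  # het counts one copy of each allele: 2 hets == 1 hom alt
  M2 <- cbind(l1 = c(1L, 1L, rep(0L, 18)), l2 = c(2L, rep(0L, 19)))
  expect_equal(ncol(maf_filter(M2, 0.05)), 2L)
})

test_that("missing-rate filter matches a brute-force recount", {
  set.seed(1)
  M <- matrix(sample(c(0L, 1L, 2L, NA), 600, replace = TRUE,
                     prob = c(0.4, 0.2, 0.2, 0.2)), nrow = 20,
              dimnames = list(NULL, paste0("l", 1:30)))
  expect_equal(ncol(missing_rate_filter(M, 1)), 30L)     # identity
  complete_only <- missing_rate_filter(M, 0)
  expect_true(all(colSums(is.na(complete_only)) == 0L))
  for (th in c(0.1, 0.25, 0.5)) {
    kept <- colnames(missing_rate_filter(M, th))
    manual <- colnames(M)[colMeans(is.na(M)) <= th]
    expect_identical(kept, manual)
  }
})

test_that("maf and missing filters commute on the surviving set", {
  set.seed(2)
  M <- matrix(sample(c(0L, 1L, 2L, NA), 2000, replace = TRUE,
                     prob = c(0.5, 0.15, 0.15, 0.2)), nrow = 40,
              dimnames = list(NULL, paste0("l", 1:50)))
  a <- suppressWarnings(maf_filter(missing_rate_filter(M, 0.3), 0.05))
  b <- suppressWarnings(missing_rate_filter(maf_filter(M, 0.05), 0.3))
  expect_identical(colnames(a), colnames(b))
  # idempotence
  expect_identical(suppressWarnings(maf_filter(a, 0.05)), a)
  expect_identical(missing_rate_filter(a, 0.3), a)
})

test_that("KNN imputation preserves observed entries and uses neighbours", {
  M <- structured_marker_matrix()
  expect_identical(knn_impute(M), M)  # no missing -> identity

  # a genotype identical to its group except one masked entry is restored
  M2 <- M
  M2[1, 5] <- NA
  imp <- knn_impute(M2, k = 5)
  expect_equal(imp[1, 5], M[1, 5])
  expect_identical(imp[-1, ], M2[-1, ])
  expect_true(all(imp %in% 0:2))

  # disconnected genotype errors by name
  M3 <- M
  M3[1, ] <- NA
  M3[1, 1] <- 0L
  M3[-1, 1] <- NA
  M3[2, 2] <- M3[2, 2]  # others observed elsewhere
  expect_error(knn_impute(M3), "g1")
})

test_that("KNN beats column-mean imputation on structured panels", {
  set.seed(3)
  wins <- 0L
  for (s in 1:10) {
    M <- structured_marker_matrix(n_per_group = 12L, n_loci = 60L)
    mask <- matrix(runif(length(M)) < 0.1, nrow = nrow(M))
    # keep every locus observed somewhere
    mask[1, colSums(!mask) == 0] <- FALSE
    Mm <- M
    Mm[mask] <- NA
    imp_knn <- knn_impute(Mm, k = 5)
    col_means <- colMeans(Mm, na.rm = TRUE)
    imp_mean <- Mm
    for (j in seq_len(ncol(Mm))) {
      miss <- is.na(Mm[, j])
      imp_mean[miss, j] <- round(col_means[j])
    }
    err_knn <- mean(imp_knn[mask] != M[mask])
    err_mean <- mean(imp_mean[mask] != M[mask])
    wins <- wins + (err_knn < err_mean)
  }
  expect_gte(wins, 8L)
})

test_that("ridge predictor limits and primal-dual equivalence", {
  set.seed(4)
  n <- 60; p <- 20
  X <- matrix(sample(0:2, n * p, replace = TRUE), nrow = n)
  y <- as.numeric(X %*% rnorm(p)) + rnorm(n, sd = 0.5)

  # infinite shrinkage: predictions collapse to the training mean
  fit_inf <- fit_ridge_predictor(X, y, shrinkage = Inf)
  expect_equal(predict(fit_inf, X), rep(mean(y), n))

  # single perfectly predictive marker, vanishing shrinkage
  x1 <- X[, 1, drop = FALSE]
  y1 <- 2.5 * x1[, 1] + 1
  fit1 <- fit_ridge_predictor(x1, y1 + rnorm(n, sd = 1e-8),
                              shrinkage = 1e-10)
  expect_gt(cor(predict(fit1, x1), y1), 0.9999)

  # dual (n x n) and primal (p x p) ridge solutions coincide
  lam <- 3.7
  fit_primal <- fit_ridge_predictor(X, y, shrinkage = lam)
  Xc <- sweep(X, 2, colMeans(X))
  b_dual <- crossprod(Xc, solve(tcrossprod(Xc) + lam * diag(n), y - mean(y)))
  expect_equal(fit_primal$effects, as.numeric(b_dual), tolerance = 1e-8)

  # REML fit is deterministic and shrinks towards zero under pure noise
  fit_a <- fit_ridge_predictor(X, y)
  fit_b <- fit_ridge_predictor(X, y)
  expect_identical(fit_a$effects, fit_b$effects)
  expect_error(fit_ridge_predictor(X, rep(1, n)), "zero variance")
  expect_error(fit_ridge_predictor(matrix(c(NA, 1:5), 3), 1:3), "missing")
})

test_that("held-out predictive ability recovers a noise-free additive trait", {
  set.seed(5)
  n <- 200; p <- 50
  X <- matrix(sample(0:2, n * p, replace = TRUE, prob = c(0.4, 0.3, 0.3)),
              nrow = n)
  beta <- rnorm(p)
  y <- as.numeric(X %*% beta)
  train <- 1:150
  fit <- fit_ridge_predictor(X[train, ], y[train])
  expect_gt(cor(predict(fit, X[-train, ]), y[-train]), 0.95)
})

test_that("cross-validation is seed-reproducible with a null under permutation", {
  set.seed(6)
  n <- 80; p <- 30
  X <- matrix(sample(0:2, n * p, replace = TRUE), nrow = n)
  y <- as.numeric(X %*% rnorm(p)) + rnorm(n)

  cv1 <- cross_validate(X, y, n_folds = 5, n_reps = 2, seed = 7)
  cv2 <- cross_validate(X, y, n_folds = 5, n_reps = 2, seed = 7)
  expect_identical(cv1$folds, cv2$folds)
  expect_gt(cv1$ability, 0.5)
  expect_true(all(cv1$folds$ability >= -1 & cv1$folds$ability <= 1))

  y_perm <- sample(y)
  cv_null <- cross_validate(X, y_perm, n_folds = 5, n_reps = 4, seed = 8)
  expect_lt(abs(cv_null$ability), 3 * cv_null$sd)
})

test_that("predictive ability rises with heritability", {
  spec <- panel_spec(150, ploidy = 2, breeding_system = "outbred",
                     snp_rate = 0.8, maf_range = c(0.1, 0.5))
  ability <- sapply(c(0.2, 0.5, 0.8), function(h2) {
    mean(vapply(1:10, function(s) {
      panel <- simulate_genotype_panel(80L, spec, seed = 1000 * h2 + s)
      tr <- simulate_trait(panel, n_qtl = 20, h2 = h2, seed = 2000 * h2 + s)
      cv <- cross_validate(panel$doses, tr$phenotype, n_folds = 5,
                           n_reps = 1, seed = s)
      cv$ability
    }, numeric(1)))
  })
  expect_true(all(diff(ability) > 0))
})

test_that("shared polymorphic locus counting matches a brute-force recount", {
  M <- rbind(c(0L, 0L, 1L, NA), c(0L, 1L, 1L, 0L), c(0L, 2L, 1L, 0L))
  # l1 monomorphic complete: no; l2 polymorphic complete: yes;
  # l3 monomorphic: no; l4 has a missing call: no
  expect_equal(count_shared_polymorphic(M), 1L)
  set.seed(9)
  M2 <- matrix(sample(c(0L, 1L, 2L, NA), 900, replace = TRUE,
                      prob = c(0.5, 0.2, 0.2, 0.1)), nrow = 30)
  manual <- sum(vapply(seq_len(ncol(M2)), function(j) {
    col <- M2[, j]
    !anyNA(col) && length(unique(col)) > 1L
  }, logical(1)))
  expect_equal(count_shared_polymorphic(M2), manual)
})

test_that("missing-threshold sweep relaxation admits markers monotonically", {
  ds <- desk_gbs_dataset(seed = 50, total_length = 1.2e5, n_genotypes = 30L,
                         reads_per_genotype = 3000L)
  panel <- ds$panel
  tr <- simulate_trait(panel, n_qtl = 20, h2 = 0.6, seed = 51)
  sweep_res <- missing_threshold_sweep(ds$calls, tr$phenotype,
                                       thresholds = c(0, 0.3, 0.8),
                                       n_folds = 5, n_reps = 1, seed = 52)
  expect_equal(nrow(sweep_res), 3L)
  expect_true(all(diff(sweep_res$n_markers) >= 0))

  # a complete matrix gives threshold-independent ability
  Mc <- knn_impute(suppressWarnings(maf_filter(
    missing_rate_filter(ds$calls, 0.4))))
  sweep_c <- missing_threshold_sweep(Mc, tr$phenotype,
                                     thresholds = c(0, 0.5),
                                     n_folds = 5, n_reps = 1, seed = 53)
  expect_equal(sweep_c$ability[1], sweep_c$ability[2], tolerance = 1e-9)
})
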