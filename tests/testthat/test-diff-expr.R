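# counts with controllable per-gene mean and residual SD on the log2 scale
lognormal_counts <- function(n_genes, n_samples, mu, sd, seed = 1) {
  withr::with_seed(seed, {
    E <- matrix(rnorm(n_genes * n_samples, mean = mu, sd = sd),
                n_genes, n_samples)
    m <- pmax(round(2^E), 0)
    dimnames(m) <- list(sprintf("G%04d", seq_len(n_genes)),
                        sprintf("S%03d", seq_len(n_samples)))
    m
  })
}

de_covariates <- function(n, seed = 2) {
  withr::with_seed(seed, tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    condition = rep(c("healthy", "disease"), length.out = n),
    sex = sample(c("male", "female"), n, replace = TRUE),
    age = runif(n, 20, 70),
    rin = rnorm(n, 7.5, 0.8),
    ischemic_time = rnorm(n, 500, 150),
    genotype_1 = rnorm(n), genotype_2 = rnorm(n), genotype_3 = rnorm(n)
  ))
}

test_that("log-CPM follows its defining arithmetic", {
  expect_equal(log_cpm(matrix(0), lib_sizes = 1e6)[1, 1],
               log2(0.5 * 1e6 / (1e6 + 1)), tolerance = 1e-12)
  expect_equal(log_cpm(matrix(0), lib_sizes = 1e6)[1, 1], -1.0000014,
               tolerance = 1e-6)
  big <- 1e9
  expect_equal(log_cpm(matrix(big), lib_sizes = big)[1, 1], log2(1e6),
               tolerance = 1e-6)
  # scale invariance for counts >> 1
  cnt <- matrix(c(1e5, 2e5, 5e5), 3, 1)
  v1 <- log_cpm(cnt, lib_sizes = 8e5)
  v2 <- log_cpm(2 * cnt, lib_sizes = 16e5)
  expect_lt(max(abs(v1 - v2)), 1e-5)
  expect_error(log_cpm(matrix(1), lib_sizes = 0), "positive")
  expect_error(log_cpm(matrix(-1), lib_sizes = 10), "non-negative")
})

test_that("voom weights are flat for homoskedastic data", {
  withr::with_seed(11, mu <- runif(300, 5, 10))
  cnt <- lognormal_counts(300, 40, mu = mu, sd = 0.7, seed = 12)
  X <- de_design(de_covariates(40))
  v <- voom_weights(cnt, X)
  cv <- sd(v$weights) / mean(v$weights)
  expect_lt(cv, 0.2)
})

test_that("voom weights track an engineered mean-variance trend", {
  withr::with_seed(13, mu <- runif(400, 4, 12))
  sds <- 1.2 - 0.1 * (mu - 4)            # SD decreasing with mean
  withr::with_seed(14, {
    E <- matrix(rnorm(400 * 50, mean = mu, sd = sds), 400, 50)
  })
  cnt <- pmax(round(2^E), 0)
  dimnames(cnt) <- list(sprintf("G%04d", 1:400), sprintf("S%03d", 1:50))
  X <- de_design(de_covariates(50))
  v <- voom_weights(cnt, X)
  rho <- cor(rowMeans(v$log_cpm), rowMeans(v$weights), method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("degenerate counts cannot produce non-finite weights", {
  cnt <- matrix(50, 20, 12,
                dimnames = list(paste0("G", 1:20), sprintf("S%03d", 1:12)))
  X <- de_design(de_covariates(12))
  v <- voom_weights(cnt, X)
  expect_true(all(is.finite(v$weights) & v$weights > 0))

  small <- cnt[1:5, ]
  expect_warning(v5 <- voom_weights(small, X), "unit weights")
  expect_true(all(v5$weights == 1))
})

test_that("weighted least squares matches its oracle and the OLS limit", {
  X <- de_design(de_covariates(12))[, 1:3]
  withr::with_seed(15, {
    E <- matrix(rnorm(8 * 12), 8, 12,
                dimnames = list(paste0("G", 1:8), sprintf("S%03d", 1:12)))
    W <- matrix(runif(8 * 12, 0.2, 5), 8, 12)
  })
  wf <- weighted_fit(E, W, X)
  for (i in 1:8) {
    o <- oracle_wls(X, E[i, ], W[i, ])
    expect_lt(max(abs(wf$coefficients[i, ] - o$coefficients)), 1e-8)
    expect_lt(max(abs(wf$stdev_unscaled[i, ] * sqrt(wf$sigma2[i]) - o$se)),
              1e-8)
  }

  # unit weights reduce exactly to ordinary least squares
  wf1 <- weighted_fit(E, NULL, X)
  ols <- agewise:::ols_matrix_fit(E, X)
  expect_lt(max(abs(wf1$coefficients - ols$coefficients)), 1e-10)
  expect_lt(max(abs(wf1$sigma2 - ols$sigma2)), 1e-10)

  # a near-infinite weight forces interpolation of that sample
  W2 <- matrix(1, 1, 12)
  W2[1, 3] <- 1e8
  wf2 <- weighted_fit(E[1, , drop = FALSE], W2, X)
  fitted3 <- drop(X[3, ] %*% wf2$coefficients[1, ])
  expect_lt(abs(fitted3 - E[1, 3]), 1e-4)

  expect_error(weighted_fit(E, -W, X), "positive")
  expect_error(weighted_fit(E, W, cbind(X, X[, 3])), "rank deficient")
})

test_that("moderation has the stated no-shrinkage and fixed-point limits", {
  X <- de_design(de_covariates(16))
  cnt <- lognormal_counts(50, 16, mu = 8, sd = 0.6, seed = 16)
  v <- voom_weights(cnt, X)
  wf <- weighted_fit(v$log_cpm, v$weights, X)

  # d0 = 0: moderated t equals the ordinary t exactly
  tab0 <- ebayes_moderate(wf, prior_df = 0)
  t_ord <- wf$coefficients[, "condition"] /
    (wf$stdev_unscaled[, "condition"] * sqrt(wf$sigma2))
  expect_equal(tab0$t_mod, unname(t_ord), tolerance = 1e-12)
  expect_equal(attr(tab0, "df_total"), wf$df_residual)

  # all s2 equal: posterior variances equal them for any prior df
  wf_eq <- wf
  wf_eq$sigma2 <- rep(0.25, 50)
  tab_eq <- ebayes_moderate(wf_eq, prior_df = 4)
  t_eq <- wf_eq$coefficients[, "condition"] /
    (wf_eq$stdev_unscaled[, "condition"] * sqrt(0.25))
  expect_equal(tab_eq$t_mod, unname(t_eq), tolerance = 1e-10)
})

test_that("moment matching recovers planted prior df and variance", {
  d0 <- 4
  s02 <- 1
  d <- 10
  withr::with_seed(17, s2 <- s02 * rf(5000, d, d0))
  mm <- agewise:::moment_match_fdist(s2, d)
  expect_lt(abs(mm$df_prior - d0) / d0, 0.5)
  expect_lt(abs(mm$s2_prior - s02) / s02, 0.2)
})

test_that("moderated statistics agree with the limma reference", {
  skip_if_not_installed("limma")
  sim <- simulate_dataset(small_config(seed = 18))
  a <- assign_cohorts(sim$donors, sim$samples, "adipose_subcutaneous")
  cov <- dplyr::mutate(a, condition = ifelse(tissue_disease, "disease",
                                             "healthy"))
  fit <- fit_de(sim$counts[, cov$sample_id], cov)

  X <- fit$design
  lv <- limma::voom(sim$counts[, cov$sample_id], design = X)
  lf <- limma::eBayes(limma::lmFit(lv, X))
  lt <- lf$t[, "condition"]
  expect_equal(unname(fit$table$logFC),
               unname(lf$coefficients[, "condition"]), tolerance = 1e-6)
  expect_gt(cor(fit$table$t_mod, lt), 0.999)
  expect_lt(abs(attr(fit$table, "df_prior") - lf$df.prior) /
              lf$df.prior, 0.2)
})

test_that("DEG calls use a strict threshold and recover planted effects", {
  empty <- tibble::tibble(gene_id = character(0), logFC = numeric(0),
                          fdr = numeric(0))
  expect_identical(call_degs(empty), list(up = character(0),
                                          down = character(0)))
  tab <- tibble::tibble(gene_id = c("a", "b", "c"),
                        logFC = c(2, -2, 1), fdr = c(0.05, 0.04, 0.01))
  degs <- call_degs(tab)
  expect_false("a" %in% c(degs$up, degs$down))  # fdr exactly 0.05: excluded
  expect_identical(degs$down, "b")
  expect_identical(degs$up, "c")

  sim <- simulate_dataset(small_config(seed = 19))
  a <- assign_cohorts(sim$donors, sim$samples, "adipose_subcutaneous")
  cov <- dplyr::mutate(a, condition = ifelse(tissue_disease, "disease",
                                             "healthy"))
  fit <- fit_de(sim$counts[, cov$sample_id], cov)
  truth <- sim$truth
  strong <- truth$gene_id[truth$gene_class == "disease_driven"]
  tabm <- fit$table[match(strong, fit$table$gene_id), ]
  # direction fidelity for truly affected genes
  agree <- sign(tabm$logFC) ==
    sign(truth$d_disease[match(strong, truth$gene_id)])
  expect_gt(mean(agree), 0.95)
  expect_gt(mean(tabm$is_deg), 0.8)
})

test_that("with no disease effect the realized DEG FDR stays controlled", {
  fdrs <- vapply(1:20, function(s) {
    cfg <- simulation_config(
      n_donors = 100, n_null = 300, n_core_aging = 0, n_disease_driven = 0,
      n_healthy_specific = 0, n_disease_de_only = 0, n_sex_interaction = 0,
      seed = 100 + s
    )
    sim <- simulate_dataset(cfg)
    a <- assign_cohorts(sim$donors, sim$samples, "adipose_subcutaneous")
    cov <- dplyr::mutate(a, condition = ifelse(tissue_disease, "disease",
                                               "healthy"))
    fit <- suppressMessages(fit_de(sim$counts[, cov$sample_id], cov))
    mean(fit$table$is_deg)  # every call is a false discovery
  }, 0)
  expect_lte(mean(fdrs), 0.10)
})
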