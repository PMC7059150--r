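#' Log-transform and filter a TPM-scale expression matrix
#'
#' Applies `log2(tpm + 1)` and keeps genes whose TPM exceeds `min_value` in
#' at least `min_fraction` of samples — a conventional low-expression filter
#' for bulk RNA-seq before per-gene regression.
#'
#' @param tpm Non-negative numeric matrix, genes x samples.
#' @param min_value,min_fraction Filter rule: keep genes with
#'   `tpm > min_value` in `>= min_fraction` of samples.
#' @return Filtered log2 matrix; attribute `filter_summary` records counts.
#' @export
preprocess_expression <- function(tpm, min_value = 0.1, min_fraction = 0.2) {
  if (any(tpm < 0)) abort("TPM matrix must be non-negative.")
  frac <- rowMeans(tpm > min_value)
  keep <- frac >= min_fraction
  if (!any(keep)) abort("All genes removed by the expression filter.")
  if (any(!keep)) {
    inform(paste0(sum(!keep), " of ", length(keep),
                  " genes removed by the expression filter (> ", min_value,
                  " in >= ", 100 * min_fraction, "% of samples)."))
  }
  out <- log2(tpm[keep, , drop = FALSE] + 1)
  attr(out, "filter_summary") <- c(n_input = length(keep), n_kept = sum(keep))
  out
}

#' Top principal components of a log-expression matrix
#'
#' Sample scores of the top `n_pcs` principal components of the
#' gene-centred log-expression matrix, used as unobserved-covariate proxies
#' in the age regression. Deterministic up to sign; signs are fixed by
#' making each component's largest-magnitude gene loading positive.
#'
#' @param log_expr Numeric matrix, genes x samples.
#' @param n_pcs Number of components; `n_pcs <= 0` returns NULL (no PC
#'   adjustment).
#' @return samples x n_pcs score matrix with columns PC1..PCn.
#' @export
compute_expression_pcs <- function(log_expr, n_pcs = 5) {
  if (n_pcs <= 0) return(NULL)
  if (n_pcs >= ncol(log_expr)) {
    abort("n_pcs must be smaller than the number of samples.")
  }
  pr <- stats::prcomp(t(log_expr), center = TRUE, scale. = FALSE)
  k <- min(n_pcs, ncol(pr$x))
  scores <- pr$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(pr$rotation[, j]))
    if (pr$rotation[i, j] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}

# Shared-design OLS across all genes at once. Y is genes x samples, X is
# samples x p. Returns coefficient / SE matrices plus residual variance.
ols_matrix_fit <- function(Y, X) {
  n <- ncol(Y)
  p <- ncol(X)
  if (n <= p) abort("More covariates than samples.")
  qrx <- qr(X)
  if (qrx$rank < p) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):p]]
    abort(paste0("Design matrix is rank deficient; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  xtx_inv <- chol2inv(chol(crossprod(X)))
  B <- qr.coef(qrx, t(Y))                       # p x genes
  res <- t(Y) - X %*% B                          # samples x genes
  df <- n - p
  s2 <- colSums(res^2) / df
  se <- sqrt(outer(diag(xtx_inv), s2))           # p x genes
  dimnames(B) <- dimnames(se) <- list(colnames(X), rownames(Y))
  list(coefficients = t(B), se = t(se), sigma2 = s2, df_residual = df)
}

# Assemble the age-regression design matrix from a per-sample covariate
# tibble (age, sex, genotype_*, rin, pmi) and optional PC scores.
aging_design <- function(covariates, pcs = NULL) {
  needed <- c("age", "sex", "rin", "pmi")
  missing <- setdiff(needed, names(covariates))
  if (length(missing) > 0) {
    abort(paste0("Covariate table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  geno <- as.matrix(covariates[grepl("^genotype_", names(covariates))])
  X <- cbind(
    `(Intercept)` = 1,
    age = covariates$age,
    sex_male = as.numeric(covariates$sex == "male"),
    geno,
    pcs,
    rin = covariates$rin,
    pmi = covariates$pmi
  )
  if (anyNA(X)) abort("Design matrix contains missing values.")
  X
}

#' Per-gene age-association regression
#'
#' Fits, for every gene, ordinary least squares of log2 expression on age,
#' sex, genotype-derived covariates, the top expression principal
#' components, RIN and PMI, then tests the age coefficient with a two-sided
#' t-test and controls FDR by Benjamini-Hochberg across genes. Genes with
#' `fdr <= fdr_cutoff` are called aging genes.
#'
#' @param log_expr Numeric matrix, genes x samples (e.g. from
#'   [preprocess_expression()]), columns named by sample id.
#' @param covariates Tibble with one row per column of `log_expr` (matched
#'   by `sample_id`): age (years), sex, genotype_* columns, rin, pmi.
#' @param n_pcs Number of expression PCs computed on this cohort and added
#'   as covariates.
#' @param fdr_cutoff Aging-gene FDR threshold (inclusive).
#' @return An object of class `aging_fit`; see [tidy.aging_fit()] for the
#'   per-gene table (gene_id, gamma, se, t, p, fdr, direction,
#'   is_aging_gene).
#' @export
fit_age_regression <- function(log_expr, covariates, n_pcs = 5,
                               fdr_cutoff = 0.01) {
  stopifnot(!is.null(colnames(log_expr)), "sample_id" %in% names(covariates))
  covariates <- covariates[match(colnames(log_expr), covariates$sample_id), ]
  if (anyNA(covariates$sample_id)) {
    abort("Every expression column needs a covariate row.")
  }
  pcs <- compute_expression_pcs(log_expr, n_pcs)
  X <- aging_design(covariates, pcs)
  fit <- ols_matrix_fit(log_expr, X)

  zero_var <- apply(log_expr, 1, function(y) stats::var(y) == 0)
  structure(
    list(
      coefficients = fit$coefficients,
      se = fit$se,
      sigma2 = fit$sigma2,
      df_residual = fit$df_residual,
      zero_variance = zero_var,
      design = X,
      fdr_cutoff = fdr_cutoff,
      n_samples = ncol(log_expr)
    ),
    class = "aging_fit"
  )
}

# Two-sided t-test + BH for one named coefficient of an aging_fit.
coef_table <- function(fit, name) {
  est <- unname(fit$coefficients[, name])
  se <- unname(fit$se[, name])
  t <- est / se
  p <- 2 * stats::pt(abs(t), df = fit$df_residual, lower.tail = FALSE)
  flag <- unname(fit$zero_variance) | !is.finite(t)
  t[flag] <- 0
  p[flag] <- 1
  tibble(
    gene_id = rownames(fit$coefficients),
    estimate = est, se = se, t = t, p = p,
    fdr = bh_fdr(p),
    direction = sign(est),
    zero_variance = unname(fit$zero_variance)
  )
}

#' Test any fitted coefficient across genes
#'
#' Two-sided per-gene t-test with BH-FDR for a named design coefficient,
#' e.g. `"sex_male"` to screen for sex-dimorphic expression, or `"age"` to
#' reproduce the aging-gene results.
#'
#' @param fit An `aging_fit`.
#' @param name Coefficient name; unknown names raise an error listing the
#'   available ones.
#' @return Tibble: gene_id, estimate, se, t, p, fdr, direction.
#' @export
test_covariate <- function(fit, name) {
  stopifnot(inherits(fit, "aging_fit"))
  if (!name %in% colnames(fit$coefficients)) {
    abort(paste0("Unknown coefficient '", name, "'. Available: ",
                 paste(colnames(fit$coefficients), collapse = ", ")))
  }
  coef_table(fit, name) |> select(-"zero_variance")
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment mapped back to input order (delegates to
#' [stats::p.adjust()]).
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @return q-values of the same length; empty input yields empty output.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  stats::p.adjust(p, method = "BH")
}
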