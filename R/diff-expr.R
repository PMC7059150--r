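#' Log counts-per-million
#'
#' `log2((count + 0.5) / (libsize + 1) * 1e6)`, the offset-stabilised
#' log-CPM used before precision-weighted linear modelling.
#'
#' @param counts Non-negative matrix, genes x samples.
#' @param lib_sizes Per-sample library sizes; defaults to column sums.
#' @return Numeric matrix of the same shape.
#' @export
log_cpm <- function(counts, lib_sizes = colSums(counts)) {
  if (any(counts < 0)) abort("Counts must be non-negative.")
  if (any(lib_sizes <= 0)) abort("Library sizes must be positive.")
  sweep(log2(counts + 0.5), 2, log2(lib_sizes + 1), "-") + log2(1e6)
}

# Design matrix for the disease-vs-healthy contrast:
# condition + sex + age + RIN + ischemic time + genotype covariates.
de_design <- function(covariates) {
  needed <- c("condition", "sex", "age", "rin", "ischemic_time")
  missing <- setdiff(needed, names(covariates))
  if (length(missing) > 0) {
    abort(paste0("DE covariate table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  cond <- covariates$condition
  if (is.character(cond) || is.factor(cond)) {
    cond <- as.numeric(as.character(cond) == "disease")
  }
  if (length(unique(cond)) < 2) abort("Both condition levels must be present.")
  geno <- as.matrix(covariates[grepl("^genotype_", names(covariates))])
  cbind(
    `(Intercept)` = 1,
    condition = cond,
    sex_male = as.numeric(covariates$sex == "male"),
    age = covariates$age,
    rin = covariates$rin,
    ischemic_time = covariates$ischemic_time,
    geno
  )
}

#' Precision weights from the mean-variance trend
#'
#' Re-implementation of the voom procedure: fit per-gene OLS of log-CPM on
#' the design, lowess-smooth the square-root residual standard deviations
#' against average log2 count (span 0.5), then read the predicted
#' square-root SD off the trend at each observation's fitted log2 count and
#' set its weight to the predicted value to the power -4 (an
#' inverse-variance weight). Predictions are floored at a small positive
#' constant so degenerate trends cannot produce non-finite weights.
#'
#' @param counts Count matrix, genes x samples.
#' @param design Numeric design matrix, samples x p.
#' @param lib_sizes Library sizes; defaults to column sums.
#' @param span Lowess span for the trend.
#' @param sd_floor Floor for the predicted square-root SD.
#' @return List of class `voom_fit`: `log_cpm` (matrix), `weights`
#'   (genes x samples), `trend` (tibble x = mean log2 count, y = sqrt SD),
#'   `design`.
#' @export
voom_weights <- function(counts, design, lib_sizes = colSums(counts),
                         span = 0.5, sd_floor = 0.01) {
  E <- log_cpm(counts, lib_sizes)
  if (nrow(E) < 10) {
    warn("Fewer than 10 genes: mean-variance trend not fitted, unit weights used.")
    return(structure(
      list(log_cpm = E, weights = matrix(1, nrow(E), ncol(E),
                                         dimnames = dimnames(E)),
           trend = tibble(x = numeric(0), y = numeric(0)), design = design),
      class = "voom_fit"
    ))
  }
  fit <- ols_matrix_fit(E, design)
  sx <- rowMeans(E) + mean(log2(lib_sizes + 1)) - log2(1e6)
  sy <- sqrt(sqrt(fit$sigma2))
  lo <- stats::lowess(sx, sy, f = span)
  predict_sqrt_sd <- if (length(unique(lo$x)) < 2) {
    # flat trend (e.g. all genes at one abundance): constant prediction
    function(z) rep(mean(lo$y), length(z))
  } else {
    stats::approxfun(lo$x, lo$y, rule = 2, ties = mean)
  }

  fitted_E <- design %*% t(fit$coefficients)          # samples x genes
  fitted_logcount <- t(fitted_E) +
    matrix(log2(lib_sizes + 1) - log2(1e6), nrow(E), ncol(E), byrow = TRUE)
  pred <- pmax(predict_sqrt_sd(fitted_logcount), sd_floor)
  w <- matrix(pred^-4, nrow(E), ncol(E), dimnames = dimnames(E))

  structure(
    list(log_cpm = E, weights = w,
         trend = tibble(x = lo$x, y = lo$y), design = design),
    class = "voom_fit"
  )
}

#' Per-gene weighted least squares
#'
#' @param E Response matrix (log-CPM), genes x samples.
#' @param weights Positive weight matrix of the same shape (or NULL for
#'   unit weights, which reduces the fit to ordinary least squares).
#' @param design Design matrix, samples x p.
#' @return List: `coefficients` (genes x p), `stdev_unscaled` (genes x p,
#'   sqrt of the diagonal of the weighted inverse Gram matrix), `sigma2`
#'   (weighted residual variance), `df_residual`.
#' @export
weighted_fit <- function(E, weights, design) {
  n <- ncol(E)
  p <- ncol(design)
  if (n <= p) abort("More covariates than samples.")
  qrx <- qr(design)
  if (qrx$rank < p) {
    bad <- colnames(design)[qrx$pivot[(qrx$rank + 1):p]]
    abort(paste0("Design matrix is rank deficient; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  if (is.null(weights)) {
    weights <- matrix(1, nrow(E), n)
  }
  if (any(weights <= 0) || any(!is.finite(weights))) {
    abort("Weights must be positive and finite.")
  }
  g <- nrow(E)
  coefs <- matrix(NA_real_, g, p, dimnames = list(rownames(E), colnames(design)))
  sdu <- coefs
  s2 <- numeric(g)
  df <- n - p
  for (i in seq_len(g)) {
    sw <- sqrt(weights[i, ])
    Xw <- design * sw
    yw <- E[i, ] * sw
    f <- stats::lm.fit(Xw, yw)
    coefs[i, ] <- f$coefficients
    s2[i] <- sum(f$residuals^2) / df
    R <- qr.R(f$qr)
    sdu[i, ] <- sqrt(diag(chol2inv(R))[order(f$qr$pivot)])
  }
  list(coefficients = coefs, stdev_unscaled = sdu, sigma2 = s2,
       df_residual = df)
}

# Newton inversion of the trigamma function (solves trigamma(y) = x).
trigamma_inverse <- function(x) {
  out <- x
  hi <- x > 1e7
  lo <- x < 1e-6
  out[hi] <- 1 / sqrt(x[hi])
  out[lo] <- 1 / x[lo]
  mid <- !hi & !lo
  y <- 0.5 + 1 / x[mid]
  for (i in seq_len(50)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x[mid]) / psigamma(y, 2)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  out[mid] <- y
  out
}

# Moment-match the marginal distribution of log residual variances to a
# scaled F, yielding the prior df and prior variance of the shrinkage model.
moment_match_fdist <- function(s2, df) {
  ok <- s2 > 0 & is.finite(s2)
  if (sum(ok) < 2) return(list(df_prior = Inf, s2_prior = stats::median(s2)))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- mean((e - emean)^2) * n / (n - 1) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    df_prior <- 2 * trigamma_inverse(evar)
    if (!is.finite(df_prior) || df_prior <= 0) {
      warn("Prior-df estimation failed to bracket; using full shrinkage.")
      df_prior <- Inf
    }
  } else {
    df_prior <- Inf
  }
  s2_prior <- if (is.finite(df_prior)) {
    exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  } else if (is.finite(evar) && evar > 0) {
    exp(emean)
  } else {
    # no excess spread in log s^2: the prior is the (geometric) mean itself,
    # making equal variances a fixed point of the shrinkage
    exp(mean(z))
  }
  list(df_prior = df_prior, s2_prior = s2_prior)
}

#' Empirical-Bayes moderated t-statistics
#'
#' Shrinks per-gene residual variances toward a pooled prior estimated by
#' moment-matching the log residual variances to their implied log-F
#' distribution (digamma/trigamma inversion), then forms moderated
#' t-statistics with `df_residual + df_prior` degrees of freedom and
#' BH-adjusted p-values for the chosen coefficient.
#'
#' @param fit Output of [weighted_fit()].
#' @param coef Name of the tested coefficient (default "condition").
#' @param fdr_cutoff Significance threshold on FDR (strict `<`).
#' @param prior_df Override the estimated prior df: `0` disables shrinkage
#'   (ordinary t-tests), `Inf` forces full shrinkage, `NULL` estimates it.
#' @return Tibble of class `deg_table`: gene_id, logFC, t_mod, p, fdr,
#'   direction, is_deg; attributes `df_prior`, `s2_prior`, `df_total`.
#' @export
ebayes_moderate <- function(fit, coef = "condition", fdr_cutoff = 0.05,
                            prior_df = NULL) {
  if (!coef %in% colnames(fit$coefficients)) {
    abort(paste0("Unknown coefficient '", coef, "'. Available: ",
                 paste(colnames(fit$coefficients), collapse = ", ")))
  }
  s2 <- fit$sigma2
  df <- fit$df_residual
  if (is.null(prior_df)) {
    if (length(s2) < 10 || df <= 0) {
      abort("Need at least 10 genes with residual df > 0.")
    }
    mm <- moment_match_fdist(s2, df)
  } else if (prior_df == 0) {
    mm <- list(df_prior = 0, s2_prior = mean(s2))
  } else {
    mm <- list(df_prior = prior_df,
               s2_prior = moment_match_fdist(s2, df)$s2_prior)
  }
  d0 <- mm$df_prior
  s2_post <- if (is.infinite(d0)) {
    rep(mm$s2_prior, length(s2))
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * mm$s2_prior + df * s2) / (d0 + df)
  }
  est <- unname(fit$coefficients[, coef])
  sdu <- unname(fit$stdev_unscaled[, coef])
  t_mod <- est / (sdu * sqrt(s2_post))
  df_total <- df + d0
  p <- 2 * stats::pt(abs(t_mod), df = df_total, lower.tail = FALSE)
  bad <- !is.finite(t_mod)
  t_mod[bad] <- 0
  p[bad] <- 1
  out <- tibble(
    gene_id = rownames(fit$coefficients) %||% as.character(seq_along(est)),
    logFC = est, t_mod = t_mod, p = p, fdr = bh_fdr(p),
    direction = sign(est)
  ) |>
    mutate(is_deg = .data$fdr < fdr_cutoff)
  attr(out, "df_prior") <- d0
  attr(out, "s2_prior") <- mm$s2_prior
  attr(out, "df_total") <- df_total
  class(out) <- c("deg_table", class(out))
  out
}

#' Disease-vs-healthy differential expression
#'
#' Full precision-weighted pipeline on raw counts: log-CPM transform, voom
#' mean-variance weights, per-gene weighted least squares on
#' `condition + sex + age + RIN + ischemic time + genotype covariates`, and
#' empirical-Bayes moderated t on the condition coefficient. Genes with all
#' zero counts are dropped first.
#'
#' @param counts Count matrix, genes x samples.
#' @param covariates Tibble with sample_id, condition ("disease"/"healthy"
#'   or 0/1), sex, age, rin, ischemic_time, genotype_* columns.
#' @param fdr_cutoff DEG threshold (strict `<`).
#' @param prior_df Passed to [ebayes_moderate()].
#' @return Object of class `de_fit` with elements `table` (the `deg_table`),
#'   `voom`, `wfit`, `design`.
#' @export
fit_de <- function(counts, covariates, fdr_cutoff = 0.05, prior_df = NULL) {
  stopifnot(!is.null(colnames(counts)), "sample_id" %in% names(covariates))
  covariates <- covariates[match(colnames(counts), covariates$sample_id), ]
  if (anyNA(covariates$sample_id)) {
    abort("Every count column needs a covariate row.")
  }
  nonzero <- rowSums(counts) > 0
  if (any(!nonzero)) {
    inform(paste0(sum(!nonzero), " all-zero gene(s) dropped before DE."))
  }
  counts <- counts[nonzero, , drop = FALSE]
  X <- de_design(covariates)
  vw <- voom_weights(counts, X)
  wf <- weighted_fit(vw$log_cpm, vw$weights, X)
  tab <- ebayes_moderate(wf, coef = "condition", fdr_cutoff = fdr_cutoff,
                         prior_df = prior_df)
  structure(list(table = tab, voom = vw, wfit = wf, design = X,
                 fdr_cutoff = fdr_cutoff),
            class = "de_fit")
}

#' Call significant DEGs by direction
#'
#' @param table A `deg_table` (or any tibble with gene_id, logFC, fdr).
#' @param threshold FDR threshold, strict `<`.
#' @return List with character vectors `up` (logFC > 0) and `down`
#'   (logFC < 0).
#' @export
call_degs <- function(table, threshold = 0.05) {
  sig <- table$fdr < threshold
  list(
    up = table$gene_id[sig & table$logFC > 0],
    down = table$gene_id[sig & table$logFC < 0]
  )
}
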