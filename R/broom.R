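#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-gene aging table from a fitted age regression
#'
#' @param x An `aging_fit`.
#' @param ... Unused.
#' @return Tibble: gene_id, gamma (log2 units/year), se, t, p, fdr,
#'   direction, is_aging_gene, zero_variance.
#' @export
tidy.aging_fit <- function(x, ...) {
  coef_table(x, "age") |>
    rename(gamma = "estimate") |>
    mutate(is_aging_gene = .data$fdr <= x$fdr_cutoff)
}

#' One-row summary of an age regression
#'
#' @param x An `aging_fit`.
#' @param ... Unused.
#' @export
glance.aging_fit <- function(x, ...) {
  tab <- tidy(x)
  tibble(
    n_genes = nrow(tab),
    n_samples = x$n_samples,
    df_residual = x$df_residual,
    n_aging_genes = sum(tab$is_aging_gene),
    n_up = sum(tab$is_aging_gene & tab$direction > 0),
    n_down = sum(tab$is_aging_gene & tab$direction < 0),
    fdr_cutoff = x$fdr_cutoff
  )
}

#' @export
print.aging_fit <- function(x, ...) {
  g <- glance(x)
  cat("<aging_fit> ", g$n_genes, " genes x ", g$n_samples, " samples; ",
      g$n_aging_genes, " aging genes at FDR <= ", g$fdr_cutoff,
      " (", g$n_up, " up, ", g$n_down, " down)\n", sep = "")
  invisible(x)
}

#' Per-gene DEG table from a differential-expression fit
#'
#' @param x A `de_fit`.
#' @param ... Unused.
#' @export
tidy.de_fit <- function(x, ...) x$table

#' One-row summary of a differential-expression fit
#'
#' @param x A `de_fit`.
#' @param ... Unused.
#' @export
glance.de_fit <- function(x, ...) {
  tibble(
    n_genes = nrow(x$table),
    n_deg = sum(x$table$is_deg),
    n_up = sum(x$table$is_deg & x$table$direction > 0),
    n_down = sum(x$table$is_deg & x$table$direction < 0),
    df_prior = attr(x$table, "df_prior"),
    s2_prior = attr(x$table, "s2_prior"),
    fdr_cutoff = x$fdr_cutoff
  )
}

#' @export
print.de_fit <- function(x, ...) {
  g <- glance(x)
  cat("<de_fit> ", g$n_genes, " genes; ", g$n_deg, " DEGs at FDR < ",
      g$fdr_cutoff, " (", g$n_up, " up, ", g$n_down, " down); prior df = ",
      signif(g$df_prior, 3), "\n", sep = "")
  invisible(x)
}

#' Gene-level membership of a signature partition
#'
#' @param x A `signature_partition`.
#' @param ... Unused.
#' @export
tidy.signature_partition <- function(x, ...) x$membership

#' Set sizes of a signature partition
#'
#' @param x A `signature_partition`.
#' @param ... Unused.
#' @export
glance.signature_partition <- function(x, ...) {
  tibble(
    n_background = length(x$background),
    n_common_sig = length(x$common_sig),
    n_healthy_sig = length(x$healthy_sig),
    n_cag = length(x$cag),
    n_csag = length(x$csag),
    n_hsag = length(x$hsag)
  )
}

#' @export
print.signature_partition <- function(x, ...) {
  g <- glance(x)
  cat("<signature_partition> background ", g$n_background, "; CAG ",
      g$n_cag, ", CSAG ", g$n_csag, ", HSAG ", g$n_hsag, "\n", sep = "")
  invisible(x)
}

#' Per-gene direction comparison
#'
#' @param x A `concordance_summary`.
#' @param ... Unused.
#' @export
tidy.concordance_summary <- function(x, ...) x$genes

#' Concordance totals and binomial test
#'
#' @param x A `concordance_summary`.
#' @param ... Unused.
#' @export
glance.concordance_summary <- function(x, ...) {
  tibble(
    n_shared = x$n_consistent + x$n_inconsistent,
    n_consistent = x$n_consistent,
    n_inconsistent = x$n_inconsistent,
    fraction_consistent = x$fraction,
    p_binomial = x$p_binomial
  )
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat("<concordance_summary> ", x$n_consistent, "/",
      x$n_consistent + x$n_inconsistent,
      " concordant (fraction ", signif(x$fraction, 3),
      ", binomial p = ", signif(x$p_binomial, 3), ")\n", sep = "")
  invisible(x)
}
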