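#' @import ggplot2
NULL

#' Volcano plot of an age regression
#'
#' Age coefficient against -log10 p, aging genes highlighted.
#'
#' @param object An `aging_fit`.
#' @param ... Unused.
#' @export
autoplot.aging_fit <- function(object, ...) {
  tab <- tidy(object)
  ggplot(tab, aes(x = .data$gamma, y = -log10(pmax(.data$p, 1e-300)),
                  colour = .data$is_aging_gene)) +
    geom_point(size = 0.6, alpha = 0.6) +
    scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                        name = paste0("FDR ≤ ", object$fdr_cutoff)) +
    labs(x = "age coefficient (log2 units / year)",
         y = expression(-log[10]~p),
         title = "Age-association regression") +
    theme_minimal()
}

#' Volcano plot of a differential-expression fit
#'
#' @param object A `de_fit`.
#' @param ... Unused.
#' @export
autoplot.de_fit <- function(object, ...) {
  tab <- object$table
  ggplot(tab, aes(x = .data$logFC, y = -log10(pmax(.data$p, 1e-300)),
                  colour = .data$is_deg)) +
    geom_point(size = 0.6, alpha = 0.6) +
    scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "steelblue"),
                        name = paste0("FDR < ", object$fdr_cutoff)) +
    labs(x = "log2 fold change (disease - healthy)",
         y = expression(-log[10]~p),
         title = "Disease vs healthy differential expression") +
    theme_minimal()
}

#' Mean-variance trend of a voom fit
#'
#' Square-root residual SD against average log2 count, with the fitted
#' lowess trend that the precision weights are read from.
#'
#' @param object A `voom_fit`.
#' @param ... Unused.
#' @export
autoplot.voom_fit <- function(object, ...) {
  ggplot(object$trend, aes(x = .data$x, y = .data$y)) +
    geom_line(colour = "firebrick") +
    labs(x = "average log2 count", y = expression(sqrt("residual SD")),
         title = "Mean-variance trend") +
    theme_minimal()
}

#' Set sizes of a signature partition
#'
#' @param object A `signature_partition`.
#' @param ... Unused.
#' @export
autoplot.signature_partition <- function(object, ...) {
  counts <- object$membership |>
    count(.data$set, direction = ifelse(.data$direction > 0, "up", "down"))
  ggplot(counts, aes(x = .data$set, y = .data$n, fill = .data$direction)) +
    geom_col(position = "dodge") +
    scale_fill_manual(values = c(up = "firebrick", down = "steelblue")) +
    labs(x = NULL, y = "genes", title = "Aging-gene partition") +
    theme_minimal()
}

#' Direction-concordance bar chart
#'
#' @param object A `concordance_summary`.
#' @param ... Unused.
#' @export
autoplot.concordance_summary <- function(object, ...) {
  dat <- tibble(
    outcome = c("consistent", "inconsistent"),
    n = c(object$n_consistent, object$n_inconsistent)
  )
  ggplot(dat, aes(x = .data$outcome, y = .data$n, fill = .data$outcome)) +
    geom_col(show.legend = FALSE) +
    scale_fill_manual(values = c(consistent = "steelblue",
                                 inconsistent = "firebrick")) +
    labs(x = NULL, y = "genes",
         title = "Aging vs disease direction concordance") +
    theme_minimal()
}
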