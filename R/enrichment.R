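#' Load and filter a disease-gene catalog
#'
#' The catalog arrives pre-merged from its sources (GWAS catalog and OMIM)
#' as a long table with columns `term`, `gene`, optional `p` (GWAS
#' association p-value) and `source`. Two numeric filters are applied:
#' GWAS-sourced associations must reach genome-wide significance
#' (`p < gwas_p_threshold`, strict), and terms must retain at least
#' `min_genes` distinct genes. OMIM-sourced rows are kept unconditionally;
#' duplicated (term, gene) pairs collapse to a single membership.
#'
#' @param x Path to a TSV file or a data frame with the columns above.
#' @param gwas_p_threshold Genome-wide significance threshold.
#' @param min_genes Minimum genes per retained term.
#' @return Tibble of class `disease_catalog` with columns term, gene,
#'   source.
#' @export
load_disease_catalog <- function(x, gwas_p_threshold = 5e-8, min_genes = 5) {
  tab <- if (is.character(x)) {
    as_tibble(utils::read.delim(x, stringsAsFactors = FALSE))
  } else {
    as_tibble(x)
  }
  needed <- c("term", "gene")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0) {
    abort(paste0("Catalog lacks required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!"source" %in% names(tab)) tab$source <- "merged"
  if (!"p" %in% names(tab)) tab$p <- NA_real_

  out <- tab |>
    filter(.data$source != "gwas" | is.na(.data$p) |
             .data$p < gwas_p_threshold) |>
    distinct(.data$term, .data$gene, .keep_all = TRUE) |>
    group_by(.data$term) |>
    filter(n() >= min_genes) |>
    ungroup() |>
    select("term", "gene", "source")
  class(out) <- c("disease_catalog", class(out))
  out
}

#' Disease-gene enrichment of the aging-gene partition
#'
#' Tests each catalog term for hypergeometric over-representation in each of
#' the CAG / CSAG / HSAG sets, splitting up- and down-regulated aging genes
#' and correcting by BH-FDR within each set-by-direction column. Catalog
#' genes outside the background are dropped; terms left with no background
#' genes are skipped. An empty set yields p = 1 for its whole column.
#'
#' @param partition A [partition_signatures()] object.
#' @param catalog A [load_disease_catalog()] tibble.
#' @param background Gene universe; defaults to the partition background.
#' @param top_k Terms flagged per set-by-direction column by smallest p.
#' @return Long tibble: term, set, direction, N, K, n, k, p, fdr, top.
#' @export
disease_enrichment <- function(partition, catalog,
                               background = partition$background,
                               top_k = 5) {
  stopifnot(inherits(partition, "signature_partition"))
  background <- unique(background)
  terms <- split(catalog$gene, catalog$term)
  terms <- map(terms, ~ intersect(unique(.x), background))
  skipped <- names(terms)[lengths(terms) == 0]
  if (length(skipped) > 0) {
    inform(paste0(length(skipped),
                  " catalog term(s) had no genes in the background; skipped."))
  }
  terms <- terms[lengths(terms) > 0]

  mem <- partition$membership
  rows <- list()
  for (set in c("CAG", "CSAG", "HSAG")) {
    for (dirn in c("up", "down")) {
      sgn <- if (dirn == "up") 1 else -1
      genes <- mem$gene_id[mem$set == set & mem$direction == sgn]
      for (term in names(terms)) {
        ot <- if (length(genes) == 0) {
          tibble(N = length(background), K = 0L,
                 n = length(terms[[term]]), k = 0L, p = 1)
        } else {
          overlap_test(genes, terms[[term]], background)
        }
        rows[[length(rows) + 1]] <- bind_cols(
          tibble(term = term, set = set, direction = dirn), ot
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble(term = character(0), set = character(0),
                  direction = character(0), N = integer(0), K = integer(0),
                  n = integer(0), k = integer(0), p = numeric(0),
                  fdr = numeric(0), top = logical(0)))
  }
  list_rbind(rows) |>
    group_by(.data$set, .data$direction) |>
    mutate(
      fdr = bh_fdr(.data$p),
      top = rank(.data$p, ties.method = "first") <= top_k
    ) |>
    ungroup()
}

#' Overlap of the partition with a curated aging-gene list
#'
#' Hypergeometric overlap of each of CAG, CSAG and HSAG with a candidate
#' human aging-gene list (e.g. GenAge), flagging enrichments at p < 0.01.
#'
#' @param partition A [partition_signatures()] object.
#' @param aging_list Character vector of candidate aging genes.
#' @param background Gene universe; defaults to the partition background.
#' @param p_flag Flagging threshold.
#' @return Tibble: set, N, K, n, k, p, enriched.
#' @export
genage_overlap <- function(partition, aging_list,
                           background = partition$background,
                           p_flag = 0.01) {
  stopifnot(inherits(partition, "signature_partition"))
  background <- unique(background)
  mapped <- intersect(unique(aging_list), background)
  sets <- list(CAG = partition$cag, CSAG = partition$csag,
               HSAG = partition$hsag)
  imap(sets, function(genes, nm) {
    bind_cols(tibble(set = nm), overlap_test(genes, mapped, background))
  }) |>
    list_rbind() |>
    mutate(enriched = .data$p < p_flag)
}
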