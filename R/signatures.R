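#' Partition aging genes into core / common-specific / healthy-specific sets
#'
#' Given per-gene aging tables from the common and the healthy cohorts
#' (tidied [fit_age_regression()] output), restricts both to the shared
#' tested-gene universe and splits the significant genes into core aging
#' genes (CAG, significant in both cohorts), common-specific aging genes
#' (CSAG, common only) and healthy-specific aging genes (HSAG, healthy
#' only). Age-trend directions are taken from the cohort that defines
#' membership (common for CAG/CSAG, healthy for HSAG).
#'
#' @param common_table,healthy_table Tibbles with gene_id, direction and
#'   is_aging_gene (see [tidy.aging_fit()]).
#' @return Object of class `signature_partition`: gene-set character
#'   vectors `cag`, `csag`, `hsag`, the input signatures `common_sig` /
#'   `healthy_sig`, the `background` universe, and a `membership` tibble
#'   (gene_id, set, direction).
#' @export
partition_signatures <- function(common_table, healthy_table) {
  background <- intersect(common_table$gene_id, healthy_table$gene_id)
  n_only <- length(union(common_table$gene_id, healthy_table$gene_id)) -
    length(background)
  if (n_only > 0) {
    inform(paste0(n_only, " gene(s) tested in only one analysis excluded ",
                  "from the shared background."))
  }
  ct <- common_table |> filter(.data$gene_id %in% background)
  ht <- healthy_table |> filter(.data$gene_id %in% background)
  common_sig <- ct$gene_id[ct$is_aging_gene]
  healthy_sig <- ht$gene_id[ht$is_aging_gene]
  cag <- intersect(common_sig, healthy_sig)
  csag <- setdiff(common_sig, healthy_sig)
  hsag <- setdiff(healthy_sig, common_sig)

  dir_common <- stats::setNames(ct$direction, ct$gene_id)
  dir_healthy <- stats::setNames(ht$direction, ht$gene_id)
  membership <- bind_rows(
    tibble(gene_id = cag, set = "CAG", direction = unname(dir_common[cag])),
    tibble(gene_id = csag, set = "CSAG", direction = unname(dir_common[csag])),
    tibble(gene_id = hsag, set = "HSAG", direction = unname(dir_healthy[hsag]))
  )
  structure(
    list(cag = cag, csag = csag, hsag = hsag,
         common_sig = common_sig, healthy_sig = healthy_sig,
         background = background, membership = membership),
    class = "signature_partition"
  )
}

#' Hypergeometric overlap (enrichment) test
#'
#' Upper-tail hypergeometric probability of observing at least the realised
#' overlap between two gene sets drawn from a finite background:
#' `P(X >= k)` with `N = |background|`, `K = |set_a|`, `n = |set_b|`,
#' `k = |intersection|`. Symmetric in its two sets.
#'
#' @param set_a,set_b Character vectors, subsets of `background`.
#' @param background Character vector, the tested-gene universe.
#' @return One-row tibble: N, K, n, k, p.
#' @export
overlap_test <- function(set_a, set_b, background) {
  background <- unique(background)
  if (length(background) == 0) abort("Background universe is empty.")
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (!all(set_a %in% background) || !all(set_b %in% background)) {
    abort("Both sets must be subsets of the background.")
  }
  N <- length(background)
  K <- length(set_a)
  n <- length(set_b)
  k <- length(intersect(set_a, set_b))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  tibble(N = N, K = K, n = n, k = k, p = p)
}

#' Direction concordance between aging and disease regulation
#'
#' For genes shared between an aging-gene table and a DEG table, compares
#' the sign of the age coefficient with the sign of the disease log-fold
#' change. Genes with a zero coefficient on either side are excluded; by
#' default only genes significant in both analyses are compared. Reports an
#' exact binomial test of the consistent fraction against 0.5.
#'
#' @param aging_table Tidy aging table (gene_id, gamma or estimate,
#'   direction, is_aging_gene).
#' @param deg_table A `deg_table` (gene_id, logFC, direction, is_deg).
#' @param significant_only Restrict to genes significant in both tables.
#' @return Object of class `concordance_summary`: `genes` tibble (gene_id,
#'   aging_direction, disease_direction, consistent), counts
#'   `n_consistent` / `n_inconsistent`, `fraction`, and `p_binomial`.
#' @export
direction_concordance <- function(aging_table, deg_table,
                                  significant_only = TRUE) {
  shared <- aging_table |>
    select(gene_id = "gene_id", aging_direction = "direction",
           aging_sig = any_of("is_aging_gene")) |>
    inner_join(
      deg_table |>
        select(gene_id = "gene_id", disease_direction = "direction",
               de_sig = any_of("is_deg")),
      by = "gene_id"
    )
  if (significant_only) {
    if (!all(c("aging_sig", "de_sig") %in% names(shared))) {
      abort("Significance columns required when significant_only = TRUE.")
    }
    shared <- shared |> filter(.data$aging_sig, .data$de_sig)
  }
  shared <- shared |>
    filter(.data$aging_direction != 0, .data$disease_direction != 0) |>
    mutate(consistent = .data$aging_direction == .data$disease_direction) |>
    select("gene_id", "aging_direction", "disease_direction", "consistent")
  n_c <- sum(shared$consistent)
  n_i <- nrow(shared) - n_c
  p <- if (nrow(shared) > 0) {
    stats::binom.test(n_c, nrow(shared), p = 0.5)$p.value
  } else {
    NA_real_
  }
  structure(
    list(genes = shared, n_consistent = n_c, n_inconsistent = n_i,
         fraction = if (nrow(shared) > 0) n_c / nrow(shared) else NA_real_,
         p_binomial = p),
    class = "concordance_summary"
  )
}

#' Read a GMT gene-set file
#'
#' Tab-separated lines: set name, description, then one gene per field.
#'
#' @param path File path.
#' @return Named list of character gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      abort(paste0("Malformed GMT line ", i, ": expected name, description ",
                   "and at least one gene."))
    }
    sets[[fields[1]]] <- unique(fields[-(1:2)])
  }
  sets
}

#' Compare own gene sets against external signature collections
#'
#' Hypergeometric overlap of each own set against each external set
#' (e.g. aging-gene lists from independent studies supplied as GMT), with
#' BH-FDR across all comparisons. External genes outside the background are
#' dropped (fraction recorded); external sets entirely outside the
#' background are skipped with a warning.
#'
#' @param own_sets Named list of character vectors (subsets of background).
#' @param external_sets Named list of character vectors, e.g. [read_gmt()]
#'   output.
#' @param background Tested-gene universe.
#' @return Tibble: own_set, external_set, unmapped_fraction, N, K, n, k, p,
#'   fdr.
#' @export
compare_external <- function(own_sets, external_sets, background) {
  background <- unique(background)
  rows <- list()
  for (ext_name in names(external_sets)) {
    ext <- unique(external_sets[[ext_name]])
    mapped <- intersect(ext, background)
    if (length(mapped) == 0) {
      warn(paste0("External set '", ext_name,
                  "' is disjoint from the background; skipped."))
      next
    }
    unmapped <- 1 - length(mapped) / length(ext)
    for (own_name in names(own_sets)) {
      ot <- overlap_test(own_sets[[own_name]], mapped, background)
      rows[[length(rows) + 1]] <- bind_cols(
        tibble(own_set = own_name, external_set = ext_name,
               unmapped_fraction = unmapped),
        ot
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble(own_set = character(0), external_set = character(0),
                  unmapped_fraction = numeric(0), N = integer(0),
                  K = integer(0), n = integer(0), k = integer(0),
                  p = numeric(0), fdr = numeric(0)))
  }
  list_rbind(rows) |> mutate(fdr = bh_fdr(.data$p))
}
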