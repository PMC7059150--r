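#' Pipeline configuration
#'
#' Collects every threshold and input the end-to-end run needs. With
#' `simulate = TRUE` (the default) the expression and metadata come from the
#' synthetic generator; otherwise `expression`, `donors` and `samples` must
#' be file paths (TPM/GCT + TSV) or in-memory objects.
#'
#' @param tissue Tissue analysed; must be a key of `map`.
#' @param map Tissue-disease map.
#' @param simulate Generate data via [simulate_dataset()].
#' @param simulation A [simulation_config()] (used when `simulate = TRUE`).
#' @param expression,counts,donors,samples Inputs for real-data runs: TPM
#'   matrix (or GCT/TSV path), count matrix, donor and sample tables.
#' @param aging_fdr Aging-gene FDR cutoff (inclusive).
#' @param deg_fdr DEG FDR cutoff (strict).
#' @param n_pcs Expression PCs in the aging design.
#' @param filter_min_value,filter_min_fraction Expression filter rule.
#' @param catalog Optional disease-gene catalog (path or tibble).
#' @param external_gmt Optional GMT path (external aging signatures).
#' @param genage Optional character vector or one-column file of candidate
#'   aging genes.
#' @param top_k Top terms flagged per enrichment column.
#' @param seed Root seed for every stochastic stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(tissue = "adipose_subcutaneous",
                            map = default_tissue_map(),
                            simulate = TRUE,
                            simulation = simulation_config(tissue = tissue,
                                                           seed = seed),
                            expression = NULL, counts = NULL,
                            donors = NULL, samples = NULL,
                            aging_fdr = 0.01, deg_fdr = 0.05, n_pcs = 5,
                            filter_min_value = 0.1,
                            filter_min_fraction = 0.2,
                            catalog = NULL, external_gmt = NULL,
                            genage = NULL, top_k = 5, seed = 1L) {
  stopifnot(aging_fdr > 0, aging_fdr < 1, deg_fdr > 0, deg_fdr < 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; a `simulation`
#' block is passed through [simulation_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulation)) {
    raw$simulation <- do.call(simulation_config, raw$simulation)
  }
  do.call(pipeline_config, raw)
}

cohort_covariates <- function(assignment, sample_ids) {
  assignment |>
    filter(.data$sample_id %in% sample_ids) |>
    select("sample_id", "age", "sex", "rin", "pmi", "ischemic_time",
           starts_with("genotype_"))
}

run_aging_stage <- function(tpm, assignment, sample_ids, config) {
  sub <- tpm[, colnames(tpm) %in% sample_ids, drop = FALSE]
  le <- preprocess_expression(sub, config$filter_min_value,
                              config$filter_min_fraction)
  fit_age_regression(le, cohort_covariates(assignment, colnames(sub)),
                     n_pcs = config$n_pcs, fdr_cutoff = config$aging_fdr)
}

#' Run the whole healthy-vs-common aging pipeline
#'
#' Orchestrates, in order: cohort assignment, tissue eligibility gate,
#' age regression in the healthy, common and unhealthy cohorts, disease-vs-
#' healthy differential expression, the CAG/CSAG/HSAG partition, direction
#' concordance, and (when a catalog or gene lists are supplied) overlap
#' enrichment. One root seed governs all stochastic stages through derived
#' substreams. A run manifest captures the config hash, seed and per-stage
#' row counts so two runs with identical inputs are verifiably identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every stage's table is
#'   written as TSV/JSON before the next stage starts.
#' @return List with `assignment`, `eligibility`, `aging` (per-cohort
#'   fits), `de`, `partition`, `concordance`, `enrichment` (or NULL),
#'   `genage` (or NULL), `external` (or NULL), `truth` (simulation only)
#'   and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(x, name) {
    if (!is.null(out_dir)) write_tsv(x, file.path(out_dir, name))
    invisible(x)
  }

  if (isTRUE(config$simulate)) {
    sim <- simulate_dataset(config$simulation)
    donors <- sim$donors
    samples <- sim$samples
    tpm <- sim$tpm
    counts <- sim$counts
    truth <- sim$truth
  } else {
    donors <- if (is.character(config$donors)) {
      read_tsv_tbl(config$donors)
    } else {
      as_tibble(config$donors)
    }
    samples <- if (is.character(config$samples)) {
      read_tsv_tbl(config$samples)
    } else {
      as_tibble(config$samples)
    }
    tpm <- if (is.character(config$expression)) {
      read_expression(config$expression)
    } else {
      config$expression
    }
    counts <- if (is.character(config$counts)) {
      read_expression(config$counts, counts = TRUE)
    } else {
      config$counts
    }
    truth <- NULL
  }

  assignment <- assign_cohorts(donors, samples, config$tissue, config$map)
  emit(assignment, "cohorts.tsv")
  eligibility <- check_tissue_eligibility(assignment)
  emit(eligibility, "eligibility.tsv")
  if (!eligibility$analysis_eligible) {
    abort(paste0("Tissue '", config$tissue, "' is not analysis-eligible (",
                 eligibility$n_samples, " samples; need > 80)."))
  }
  if (!eligibility$healthy_vs_disease_eligible) {
    abort(paste0("Tissue '", config$tissue, "' fails the disease-fraction ",
                 "rule (", round(100 * eligibility$disease_fraction, 1),
                 "% disease samples; need > 20%)."))
  }

  unhealthy <- build_unhealthy_cohort(assignment)
  cohorts <- list(
    tissue_healthy = assignment$sample_id[assignment$tissue_healthy],
    common = assignment$sample_id[assignment$common],
    unhealthy = unhealthy$sample_id
  )
  aging <- imap(cohorts, function(ids, nm) {
    fit <- run_aging_stage(tpm, assignment, ids, config)
    emit(tidy(fit), paste0("aging_", nm, ".tsv"))
    fit
  })

  de_ids <- assignment$sample_id[assignment$common]
  de_cov <- assignment |>
    filter(.data$sample_id %in% de_ids) |>
    mutate(condition = ifelse(.data$tissue_disease, "disease", "healthy")) |>
    select("sample_id", "condition", "sex", "age", "rin", "ischemic_time",
           starts_with("genotype_"))
  de <- fit_de(counts[, de_cov$sample_id, drop = FALSE], de_cov,
               fdr_cutoff = config$deg_fdr)
  emit(de$table, "degs.tsv")

  part <- partition_signatures(tidy(aging$common), tidy(aging$tissue_healthy))
  emit(part$membership, "partition.tsv")
  conc <- direction_concordance(tidy(aging$tissue_healthy), de$table)
  if (!is.null(out_dir)) {
    jsonlite::write_json(glance(conc), file.path(out_dir, "concordance.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  enr <- NULL
  if (!is.null(config$catalog)) {
    catalog <- load_disease_catalog(config$catalog)
    enr <- disease_enrichment(part, catalog, top_k = config$top_k)
    emit(enr, "enrichment.tsv")
  }
  ga <- NULL
  if (!is.null(config$genage)) {
    lst <- if (is.character(config$genage) && length(config$genage) == 1 &&
                 file.exists(config$genage)) {
      readLines(config$genage)
    } else {
      config$genage
    }
    ga <- genage_overlap(part, lst)
    emit(ga, "genage.tsv")
  }
  ext <- NULL
  if (!is.null(config$external_gmt)) {
    ext <- compare_external(
      list(CAG = part$cag, CSAG = part$csag, HSAG = part$hsag),
      read_gmt(config$external_gmt), part$background
    )
    emit(ext, "external_overlap.tsv")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("agewise")),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "map")]),
    tissue = config$tissue,
    stages = list(
      n_donors = nrow(donors),
      n_samples_retained = sum(assignment$common),
      n_healthy = sum(assignment$tissue_healthy),
      n_disease = sum(assignment$tissue_disease),
      n_unhealthy = nrow(unhealthy),
      n_genes_tested = map(aging, ~ nrow(.x$coefficients)),
      n_aging_genes = map(aging, ~ sum(tidy(.x)$is_aging_gene)),
      n_degs = sum(de$table$is_deg),
      partition = list(cag = length(part$cag), csag = length(part$csag),
                       hsag = length(part$hsag)),
      enrichment_skipped = is.null(enr)
    )
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(assignment = assignment, eligibility = eligibility,
       unhealthy = unhealthy, aging = aging, de = de, partition = part,
       concordance = conc, enrichment = enr, genage = ga, external = ext,
       truth = truth, manifest = manifest)
}
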