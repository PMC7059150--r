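#' Built-in tissue-to-disease relevance map
#'
#' Rules for the tissues whose healthy-cohort definitions are fully stated:
#' subcutaneous adipose (healthy = no type-2 diabetes and BMI below 30),
#' tibial artery (healthy = no ischemic heart disease, heart attack or acute
#' coronary syndrome) and lung (healthy = no chronic respiratory disease,
#' asthma or pneumonia). Each entry lists the tissue-relevant disease codes
#' and, where applicable, a BMI ceiling that is part of the healthy predicate.
#'
#' @return Named list: tissue -> list(codes = character, bmi_max = numeric or
#'   NULL).
#' @export
default_tissue_map <- function() {
  list(
    adipose_subcutaneous = list(codes = c("T2D"), bmi_max = 30),
    artery_tibial = list(
      codes = c("ischemic_heart_disease", "heart_attack",
                "acute_coronary_syndrome"),
      bmi_max = NULL
    ),
    lung = list(
      codes = c("chronic_respiratory_disease", "asthma", "pneumonia"),
      bmi_max = NULL
    )
  )
}

has_any_code <- function(code_string, codes) {
  any(split_codes(code_string) %in% codes)
}

#' Assign samples to healthy / common / disease cohorts
#'
#' Implements the tissue-level cohort definitions: a donor is *disease-free*
#' if they carry no disease annotation at all; *tissue-level healthy* if they
#' carry none of the tissue-relevant codes and pass any tissue-specific
#' predicate (for adipose: BMI < 30); *tissue-level disease* otherwise. The
#' *common* cohort is every retained sample. Donors with multiple samples in
#' the tissue keep only their highest-RIN sample; donors with missing BMI
#' where a BMI predicate applies are excluded with a recorded reason.
#'
#' @param donors Tibble with donor_id, age, sex, bmi, disease_codes
#'   (`;`-separated string), pmi.
#' @param samples Tibble with sample_id, donor_id, tissue, rin,
#'   ischemic_time; all rows must belong to `tissue`.
#' @param tissue Tissue name, must be a key of `map`.
#' @param map Tissue-disease map, see [default_tissue_map()].
#' @return Tibble with one row per input sample: ids, age, sex, bmi,
#'   disease_codes and logical columns disease_free, tissue_healthy,
#'   tissue_disease, common, excluded plus exclusion_reason. Tissue and map
#'   are attached as attributes for downstream steps.
#' @export
assign_cohorts <- function(donors, samples, tissue, map = default_tissue_map()) {
  if (!tissue %in% names(map)) {
    abort(paste0("Tissue '", tissue, "' is missing from the tissue-disease map."))
  }
  if (!all(samples$tissue == tissue)) {
    abort("All samples must belong to the stated tissue.")
  }
  rule <- map[[tissue]]
  if (length(rule$codes) < 1) abort("Tissue rule must list at least one code.")

  dat <- samples |>
    inner_join(donors, by = "donor_id") |>
    group_by(.data$donor_id) |>
    arrange(desc(.data$rin), .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$sample_id)
  if (nrow(dat) < nrow(samples)) {
    inform(paste0(nrow(samples) - nrow(dat),
                  " duplicate donor sample(s) dropped (kept highest RIN)."))
  }

  n_missing_codes <- sum(is.na(dat$disease_codes))
  if (n_missing_codes > 0) {
    warn(paste0(n_missing_codes, " donor(s) have missing disease annotations; ",
                "treated as not annotated."))
  }

  relevant <- map_lgl(dat$disease_codes,
                      ~ has_any_code(.x %||% "", rule$codes))
  excluded <- rep(FALSE, nrow(dat))
  reason <- rep(NA_character_, nrow(dat))
  if (!is.null(rule$bmi_max)) {
    miss_bmi <- is.na(dat$bmi)
    excluded[miss_bmi] <- TRUE
    reason[miss_bmi] <- "missing BMI where a BMI predicate applies"
    if (any(miss_bmi)) {
      warn(paste0(sum(miss_bmi), " sample(s) excluded: missing BMI."))
    }
  }
  passes_pred <- if (is.null(rule$bmi_max)) {
    rep(TRUE, nrow(dat))
  } else {
    !is.na(dat$bmi) & dat$bmi < rule$bmi_max
  }

  out <- dat |>
    mutate(
      disease_free = map_lgl(.data$disease_codes,
                             ~ length(split_codes(.x %||% "")) == 0),
      tissue_healthy = !excluded & !relevant & passes_pred,
      tissue_disease = !excluded & !.data$tissue_healthy,
      common = !excluded,
      disease_free = .data$disease_free & .data$tissue_healthy,
      excluded = excluded,
      exclusion_reason = reason
    ) |>
    select("sample_id", "donor_id", "age", "sex", "bmi", "disease_codes",
           "rin", "ischemic_time", "pmi", starts_with("genotype_"),
           "disease_free", "tissue_healthy", "tissue_disease", "common",
           "excluded", "exclusion_reason")
  attr(out, "tissue") <- tissue
  attr(out, "map") <- map
  out
}

full_disease_predicate <- function(assignment, rule) {
  relevant <- map_lgl(assignment$disease_codes,
                      ~ has_any_code(.x %||% "", rule$codes))
  if (is.null(rule$bmi_max)) {
    relevant
  } else {
    relevant & !is.na(assignment$bmi) & assignment$bmi >= rule$bmi_max
  }
}

#' Build the "unhealthy" aging cohort
#'
#' Pools tissue-level healthy donors aged in `young_range` with donors
#' meeting the full disease predicate (for adipose: type-2 diabetes AND
#' BMI >= 30) aged in `old_range`. Young donors who meet the disease
#' predicate are excluded, since their disease is not age-associated. Age
#' intervals are half-open on the right for the young arm and closed for the
#' old arm, so a donor aged exactly 40 falls in the old arm.
#'
#' @param assignment Output of [assign_cohorts()].
#' @param young_range,old_range Length-2 numeric age windows in years.
#' @return Tibble of retained samples with an `arm` column
#'   (`young_healthy` / `old_unhealthy`); attribute `excluded_young_disease`
#'   holds the sample ids dropped by the young-disease exclusion.
#' @export
build_unhealthy_cohort <- function(assignment,
                                   young_range = c(20, 40),
                                   old_range = c(40, 70)) {
  tissue <- attr(assignment, "tissue")
  rule <- attr(assignment, "map")[[tissue]]
  pred <- full_disease_predicate(assignment, rule)
  young <- assignment$age >= young_range[1] & assignment$age < young_range[2]
  old <- assignment$age >= old_range[1] & assignment$age <= old_range[2]

  keep_young <- assignment$tissue_healthy & young
  keep_old <- pred & old & !assignment$excluded
  dropped <- assignment$sample_id[pred & young]

  out <- assignment |>
    filter(keep_young | keep_old) |>
    mutate(arm = ifelse(.data$sample_id %in% assignment$sample_id[keep_young],
                        "young_healthy", "old_unhealthy")) |>
    select("sample_id", "donor_id", "age", "arm")
  if (nrow(out) == 0) warn("Unhealthy cohort is empty.")
  attr(out, "excluded_young_disease") <- dropped
  out
}

#' Tissue eligibility for the aging and healthy-vs-disease analyses
#'
#' A tissue enters the aging analysis only with more than `min_samples`
#' retained samples (read strictly: 81 qualifies, 80 does not), and enters
#' the healthy-vs-disease comparison only when strictly more than
#' `min_disease_frac` of retained samples come from disease donors.
#'
#' @param assignment Output of [assign_cohorts()].
#' @param min_samples Sample-count threshold (strict).
#' @param min_disease_frac Disease-fraction threshold (strict).
#' @return One-row tibble: n_samples, n_disease, disease_fraction,
#'   analysis_eligible, healthy_vs_disease_eligible.
#' @export
check_tissue_eligibility <- function(assignment, min_samples = 80,
                                     min_disease_frac = 0.2) {
  n <- sum(assignment$common)
  nd <- sum(assignment$tissue_disease)
  frac <- if (n > 0) nd / n else 0
  tibble(
    n_samples = n,
    n_disease = nd,
    disease_fraction = frac,
    analysis_eligible = n > min_samples,
    healthy_vs_disease_eligible = n > 0 && frac > min_disease_frac
  )
}
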