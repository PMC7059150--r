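#' Simulation configuration for a GTEx-like single-tissue cohort
#'
#' Builds the parameter list consumed by [simulate_cohort()] and
#' [simulate_expression()]. The defaults describe one tissue sampled from 500
#' post-mortem donors aged 20-70 whose probability of carrying the
#' tissue-relevant disease rises with age on the logit scale, so that genes
#' responding only to disease acquire a spurious marginal age association --
#' the confounding structure that motivates stratifying a "healthy" cohort.
#'
#' Expression is negative-binomial on counts: gene `g` in sample `i` has
#' log2 mean `b_g + gamma_g * (age - 45) * mask_g + d_g * disease +
#' delta_g * male + small RIN/PMI loadings`, scaled by a lognormal
#' library-size factor. `mask_g` is 1 everywhere for core-aging genes and
#' `1 - disease` for healthy-specific genes, whose age trend exists only in
#' donors free of the tissue-relevant disease.
#'
#' @param n_donors Number of donors (one sample each).
#' @param age_range Length-2 numeric, uniform age range in years.
#' @param disease_logit_intercept,disease_logit_slope Logistic model for
#'   P(tissue-relevant disease | age); slope is per year of age.
#' @param irrelevant_disease_prob Age-independent probability of carrying a
#'   disease code irrelevant to the tissue (keeps "disease-free" a strict
#'   subset of "tissue-level healthy").
#' @param sex_prob Probability a donor is male.
#' @param bmi_mean,bmi_age_slope,bmi_sd BMI model (kg/m^2): mean at age 40,
#'   linear trend per year, residual SD.
#' @param rin_mean,rin_sd RNA integrity number distribution (clamped to 1-10).
#' @param pmi_mean,pmi_sd Post-mortem interval, minutes.
#' @param ischemic_mean,ischemic_sd Sample ischemic time, minutes.
#' @param n_genotype_covariates Number of standard-normal donor-level
#'   genotype-derived covariate columns.
#' @param lib_size_log_mean,lib_size_log_sd Log-normal library-size factor.
#' @param nb_dispersion Negative-binomial dispersion (1/size); variance is
#'   `mu + dispersion * mu^2`.
#' @param n_null,n_core_aging,n_disease_driven,n_healthy_specific,n_disease_de_only,n_sex_interaction
#'   Genes per generative class.
#' @param gamma_age Age effect magnitude, log2 units per year (signs are
#'   randomised per gene).
#' @param d_disease Disease effect magnitude (log2) for disease_driven genes.
#' @param d_disease_weak Disease effect (log2) for disease_de_only genes;
#'   sized to be detectable by the direct disease contrast but too small for
#'   the disease-to-age confounding it induces to register as age association.
#' @param delta_sex Sex effect magnitude (log2) for sex_interaction genes.
#' @param core_d_disease Optional disease effect planted on core-aging genes
#'   with the same sign as their age effect (default 0 = off); used to study
#'   direction concordance between aging and disease regulation.
#' @param n_latent_factors,latent_loading_sd Unobserved per-sample nuisance
#'   factors (standard-normal scores) loading on every gene with
#'   `N(0, latent_loading_sd^2)` log2 loadings. They emulate the technical
#'   and cell-composition variance that dominates the leading expression
#'   principal components of real bulk tissue, which is what the PC
#'   covariates of the age regression are there to absorb.
#' @param base_log2_range Uniform range of baseline log2 expression.
#' @param rin_loading_sd,pmi_loading_sd SD of per-gene nuisance loadings on
#'   centred RIN / PMI.
#' @param tissue Tissue label stamped on samples.
#' @param seed Root integer seed; per-stage substreams are derived from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_donors = 500,
                              age_range = c(20, 70),
                              disease_logit_intercept = -4.7,
                              disease_logit_slope = 0.08,
                              irrelevant_disease_prob = 0.15,
                              sex_prob = 0.5,
                              bmi_mean = 26,
                              bmi_age_slope = 0.05,
                              bmi_sd = 4,
                              rin_mean = 7.5,
                              rin_sd = 0.8,
                              pmi_mean = 600,
                              pmi_sd = 180,
                              ischemic_mean = 500,
                              ischemic_sd = 150,
                              n_genotype_covariates = 3,
                              lib_size_log_mean = 0,
                              lib_size_log_sd = 0.3,
                              nb_dispersion = 0.1,
                              n_null = 1500,
                              n_core_aging = 100,
                              n_disease_driven = 100,
                              n_healthy_specific = 100,
                              n_disease_de_only = 100,
                              n_sex_interaction = 100,
                              gamma_age = 0.015,
                              d_disease = 1.0,
                              d_disease_weak = 0.3,
                              delta_sex = 0.5,
                              core_d_disease = 0,
                              n_latent_factors = 5,
                              latent_loading_sd = 0.3,
                              base_log2_range = c(2, 8),
                              rin_loading_sd = 0.02,
                              pmi_loading_sd = 0.0005,
                              tissue = "adipose_subcutaneous",
                              seed = 1L) {
  cfg <- as.list(environment())
  num <- cfg[!names(cfg) %in% "tissue"]
  for (nm in names(num)) assert_finite(num[[nm]], nm)
  stopifnot(
    n_donors >= 1,
    length(age_range) == 2, age_range[1] < age_range[2],
    sex_prob >= 0, sex_prob <= 1,
    irrelevant_disease_prob >= 0, irrelevant_disease_prob <= 1,
    nb_dispersion > 0,
    n_genotype_covariates >= 0
  )
  counts <- c(n_null, n_core_aging, n_disease_driven, n_healthy_specific,
              n_disease_de_only, n_sex_interaction)
  if (any(counts < 0)) abort("Gene class counts must be non-negative.")
  if (sum(counts) == 0) abort("Gene class counts sum to zero genes.")
  structure(cfg, class = "simulation_config")
}

#' Simulate donors and samples for one tissue
#'
#' Ages are uniform on `age_range`; the tissue-relevant disease is Bernoulli
#' with `plogis(intercept + slope * age)`; BMI, RIN, PMI and ischemic time
#' follow the configured normal models. Each donor contributes one sample.
#'
#' @param config A [simulation_config()].
#' @return A list with tibbles `donors` (donor_id, age, sex, bmi,
#'   disease_codes, pmi, genotype_1..k) and `samples` (sample_id, donor_id,
#'   tissue, rin, ischemic_time). `disease_codes` is a `;`-separated string,
#'   empty for annotation-free donors.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(substream_seed(config$seed, "cohort"), {
    n <- config$n_donors
    age <- stats::runif(n, config$age_range[1], config$age_range[2])
    p_dis <- stats::plogis(config$disease_logit_intercept +
                             config$disease_logit_slope * age)
    has_disease <- stats::rbinom(n, 1, p_dis) == 1
    has_other <- stats::rbinom(n, 1, config$irrelevant_disease_prob) == 1
    sex <- ifelse(stats::rbinom(n, 1, config$sex_prob) == 1, "male", "female")
    bmi <- stats::rnorm(n, config$bmi_mean +
                          config$bmi_age_slope * (age - 40), config$bmi_sd)
    bmi <- pmax(bmi, 15)
    pmi <- pmax(stats::rnorm(n, config$pmi_mean, config$pmi_sd), 1)
    rin <- pmin(pmax(stats::rnorm(n, config$rin_mean, config$rin_sd), 1), 10)
    isch <- pmax(stats::rnorm(n, config$ischemic_mean, config$ischemic_sd), 1)

    codes <- character(n)
    relevant <- default_tissue_map()[[config$tissue]]$codes[1] %||% "T2D"
    codes[has_disease] <- relevant
    codes[has_other] <- ifelse(nzchar(codes[has_other]),
                               paste(codes[has_other], "asthma", sep = ";"),
                               "asthma")

    donors <- tibble(
      donor_id = sprintf("D%04d", seq_len(n)),
      age = age, sex = sex, bmi = bmi,
      disease_codes = codes, pmi = pmi
    )
    k <- config$n_genotype_covariates
    if (k > 0) {
      geno <- matrix(stats::rnorm(n * k), n, k,
                     dimnames = list(NULL, paste0("genotype_", seq_len(k))))
      donors <- bind_cols(donors, as_tibble(geno))
    }
    samples <- tibble(
      sample_id = sprintf("S%04d", seq_len(n)),
      donor_id = donors$donor_id,
      tissue = config$tissue,
      rin = rin,
      ischemic_time = isch
    )
    list(donors = donors, samples = samples)
  })
}

#' Simulate a negative-binomial expression matrix with known ground truth
#'
#' @param donors,samples Tibbles from [simulate_cohort()].
#' @param config A [simulation_config()].
#' @return A list with integer matrix `counts` (genes x samples), numeric
#'   matrix `tpm` (counts rescaled to a per-sample total of 1e6) and tibble
#'   `truth` (gene_id, gene_class, gamma_age, d_disease, delta_sex,
#'   base_log2) aligned to matrix rows.
#' @export
simulate_expression <- function(donors, samples, config) {
  stopifnot(inherits(config, "simulation_config"))
  stopifnot(all(samples$donor_id %in% donors$donor_id))
  with_seed(substream_seed(config$seed, "expression"), {
    classes <- c(
      rep("null", config$n_null),
      rep("core_aging", config$n_core_aging),
      rep("disease_driven", config$n_disease_driven),
      rep("healthy_specific", config$n_healthy_specific),
      rep("disease_de_only", config$n_disease_de_only),
      rep("sex_interaction", config$n_sex_interaction)
    )
    g <- length(classes)
    if (g == 0) abort("Gene class counts sum to zero genes.")
    sign_of <- function(m) ifelse(stats::runif(g) < 0.5, -1, 1) * m
    gamma <- sign_of(config$gamma_age) *
      (classes %in% c("core_aging", "healthy_specific"))
    d <- sign_of(config$d_disease)
    d[classes == "disease_de_only"] <- sign(d[classes == "disease_de_only"]) *
      config$d_disease_weak
    d[!classes %in% c("disease_driven", "disease_de_only")] <- 0
    if (config$core_d_disease > 0) {
      core <- classes == "core_aging"
      d[core] <- sign(gamma[core]) * config$core_d_disease
    }
    delta <- sign_of(config$delta_sex) * (classes == "sex_interaction")
    base <- stats::runif(g, config$base_log2_range[1], config$base_log2_range[2])
    load_rin <- stats::rnorm(g, 0, config$rin_loading_sd)
    load_pmi <- stats::rnorm(g, 0, config$pmi_loading_sd)
    kf <- config$n_latent_factors
    factor_load <- matrix(stats::rnorm(g * kf, 0, config$latent_loading_sd),
                          g, kf)

    dn <- donors[match(samples$donor_id, donors$donor_id), ]
    relevant <- default_tissue_map()[[config$tissue]]$codes[1] %||% "T2D"
    disease <- map_lgl(dn$disease_codes, ~ relevant %in% split_codes(.x))
    male <- as.numeric(dn$sex == "male")
    age_c <- dn$age - 45
    rin_c <- samples$rin - config$rin_mean
    pmi_c <- dn$pmi - config$pmi_mean
    # Core genes track centred age in everyone. Healthy-specific genes track
    # uncentred age in donors free of the tissue-relevant disease only, so a
    # diseased donor sits at baseline: their marginal age association in the
    # mixed cohort is near zero once disease prevalence rises with age.
    hs <- classes == "healthy_specific"
    age_term <- matrix(0, g, nrow(samples))
    age_term[!hs, ] <- gamma[!hs] %o% age_c
    if (any(hs)) {
      age_term[hs, ] <- (gamma[hs] %o% dn$age) *
        matrix(rep(!disease, each = sum(hs)), sum(hs))
    }

    n <- nrow(samples)
    log2mu <- base +
      age_term +
      d %o% as.numeric(disease) +
      delta %o% male +
      load_rin %o% rin_c +
      load_pmi %o% pmi_c
    if (kf > 0) {
      factor_scores <- matrix(stats::rnorm(n * kf), n, kf)
      log2mu <- log2mu + factor_load %*% t(factor_scores)
    }
    libf <- exp(stats::rnorm(n, config$lib_size_log_mean, config$lib_size_log_sd))
    mu <- 2^log2mu * rep(libf, each = g)
    counts <- matrix(
      stats::rnbinom(g * n, mu = mu, size = 1 / config$nb_dispersion),
      nrow = g, ncol = n
    )
    gene_ids <- sprintf("G%05d", seq_len(g))
    dimnames(counts) <- list(gene_ids, samples$sample_id)
    totals <- pmax(colSums(counts), 1)
    tpm <- sweep(counts, 2, totals, "/") * 1e6

    truth <- tibble(
      gene_id = gene_ids, gene_class = classes,
      gamma_age = gamma, d_disease = d, delta_sex = delta,
      base_log2 = base
    )
    list(counts = counts, tpm = tpm, truth = truth)
  })
}

#' Simulate a complete single-tissue dataset
#'
#' Convenience wrapper running [simulate_cohort()] then
#' [simulate_expression()].
#'
#' @param config A [simulation_config()].
#' @return A list with `donors`, `samples`, `counts`, `tpm`, `truth`, and the
#'   `config` used.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  coh <- simulate_cohort(config)
  expr <- simulate_expression(coh$donors, coh$samples, config)
  c(coh, expr, list(config = config))
}
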