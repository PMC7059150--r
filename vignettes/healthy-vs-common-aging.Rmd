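---
title: "Separating healthy from common transcriptomic aging: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating healthy from common transcriptomic aging: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agewise)
```

# The problem

Age-related disease is so prevalent in older donors of post-mortem tissue
banks that "expression change with age" and "expression change with
disease" are statistically entangled: a gene that responds only to, say,
type-2 diabetes will correlate with age in the full cohort simply because
diabetes prevalence rises with age. `agewise` operationalises one way to
untangle them: compute aging signatures separately in the *common* cohort
(everyone) and the *tissue-level healthy* cohort (donors free of the
diseases relevant to that tissue), then partition the aging genes by where
they reach significance. Genes significant only with disease donors
included (CSAGs) are candidates for disease-driven age association; genes
significant only in the healthy cohort (HSAGs) are candidates for
processes specific to aging in good health; genes significant in both
(CAGs) form a core aging program.

This vignette documents the statistical machinery, the parameters a user
might want to change, what the synthetic-data generator does and does not
emulate, and the design decisions that were genuinely open.

# Cohort stratification

A donor is **tissue-level healthy** when they carry none of the
tissue-relevant disease codes and pass any tissue-specific predicate. The
shipped map covers the three tissues whose rules are fully specifiable from
their clinical definitions: subcutaneous adipose (no type-2 diabetes *and*
BMI < 30 kg/m²), tibial artery (no ischemic heart disease, heart attack or
acute coronary syndrome) and lung (no chronic respiratory disease, asthma
or pneumonia). Users supply their own map for other tissues.

Boundary readings are deliberate and tested:

* BMI exactly 30 counts as obese (the clinical convention), so a donor at
  30.0 fails the adipose healthy predicate.
* "More than 80 samples" is strict — 81 qualifies, 80 does not. "More than
  20% disease samples" likewise.
* The **unhealthy** cohort pools tissue-healthy donors aged [20, 40) with
  donors meeting the *full* disease predicate (for adipose: T2D *and*
  BMI ≥ 30) aged [40, 70]; a donor aged exactly 40 falls in the old arm.
  Young donors meeting the disease predicate are excluded entirely, since
  early-onset disease is not an aging phenotype and dilutes the age signal.
* Donors with missing disease annotations are treated as unannotated (with
  a warning); donors with missing BMI where a BMI predicate applies cannot
  be classified and are excluded with a recorded reason.
* One sample per donor per tissue; duplicates resolve to the highest-RIN
  sample.

# The age-association model

Per gene, ordinary least squares of `log2(TPM + 1)` on age, sex, three
genotype-derived covariates, the top `n_pcs` expression principal
components, RIN and PMI. The age coefficient (log2 units per year) is
tested two-sided with the exact residual degrees of freedom;
Benjamini–Hochberg FDR is applied across genes, and `fdr <= 0.01` calls an
aging gene.

Assumptions worth stating: expression is linear in age on the log scale
over the observed range (no splines), nuisance variation is either
measured (RIN, PMI) or captured by the leading principal components, and
residuals are approximately homoskedastic after the log transform — the
count-level mean-variance relationship is handled properly only in the DE
stage, which is why the aging regression runs on TPM while DE runs on raw
counts.

Tunable parameters:

| parameter | default | units | rationale |
|---|---|---|---|
| expression filter | > 0.1 TPM in ≥ 20% of samples | — | conventional low-expression filter; genes below it have log values dominated by sampling noise |
| `n_pcs` | 5 | components | enough to absorb dominant technical/cell-composition axes without eating the age signal; computed per analysis cohort |
| `fdr_cutoff` (aging) | 0.01 | — | the aging-gene definition |
| age coding | continuous years | years | decade-bracketed inputs should be mapped to midpoints before entry |

PCs are computed on the gene-centred log-expression matrix of the cohort
being analysed (not on all samples before subsetting — a genuinely open
choice; per-cohort is the default because the nuisance structure worth
removing is the one present in the samples actually fitted, and the
alternative is one argument away since `compute_expression_pcs()` is
exported). Component signs are fixed by making each component's
largest-magnitude loading positive, so results are fully deterministic.

Numerical notes: the per-gene fits share one QR decomposition of the design
(the design is identical across genes), standard errors come from the
Cholesky inverse of the Gram matrix, a rank-deficient design raises an
error naming the collinear columns, and a zero-variance gene is flagged
with p = 1 rather than propagating 0/0.

# Differential expression

The disease-vs-healthy contrast is fitted on raw counts with a
precision-weighted linear model and empirical-Bayes moderation, written
from first principles rather than calling the reference implementation
(which serves as an independent cross-check in the test suite):

1. `log2((count + 0.5) / (libsize + 1) * 1e6)` log-CPM transform.
2. Per-gene OLS on `condition + sex + age + RIN + ischemic time +
   genotype`; lowess (span 0.5) of the square-root residual SD against
   average log2 count; each observation's weight is the trend prediction at
   its fitted log2 count raised to the power −4. Predictions are floored at
   0.01 so degenerate trends cannot produce infinite weights; with fewer
   than 10 genes the trend is refused and unit weights are used.
3. Weighted least squares per gene; prior df and prior variance estimated
   by matching the mean and variance of log residual variances to the
   implied log-F moments (digamma/trigamma inversion, with a Newton
   iteration for the trigamma inverse); posterior variances
   `(d0 s0² + d s²) / (d0 + d)`; moderated t with `d0 + d` degrees of
   freedom; BH-FDR, DEGs at `fdr < 0.05` (strict).

Degenerate regimes have defined behaviour: `prior_df = 0` reproduces
ordinary t-tests exactly; when the log-variances show no excess spread the
prior df is infinite and the prior variance is their geometric mean, making
equal variances a fixed point of the shrinkage. PMI is a covariate of the
aging model but not of the DE design; ischemic time, conversely, enters
only the DE design — the two stages adjust for the nuisance most relevant
to their contrast.

# Signatures, concordance, enrichment

The partition's background universe is the intersection of genes tested in
both analyses (genes tested in only one are excluded and reported). All
overlap statements use the upper-tail hypergeometric probability
P(X ≥ k) — enrichment only; depletion is not reported. Direction
concordance compares the sign of the healthy-cohort age coefficient with
the sign of the disease log-fold-change among genes significant in both
analyses; zero-direction genes are dropped rather than counted as
discordant, and the consistent fraction is tested against 0.5 with an
exact binomial test. Disease-catalog loading applies exactly two numeric
filters — GWAS associations at p < 5×10⁻⁸ (strict) and ≥ 5 genes per term
after deduplication — because the catalog is accepted pre-merged;
reconstructing the merge of GWAS and OMIM sources is out of scope.
Catalog FDR is applied within each set-by-direction column.

# What the synthetic generator emulates

`simulation_config()` defines a single-tissue study of 500 donors aged
20–70 (uniform), with:

* **Disease ~ age confounding**: P(tissue-relevant disease | age) =
  logistic(−4.7 + 0.08 · age), i.e. ≈ 4% at 20 rising to ≈ 71% at 70,
  ≈ 27% overall. Combined with the BMI predicate this retains ≈ 40% of
  adipose samples in the disease cohort — comparable to real adipose
  cohorts and comfortably past the 20% eligibility gate. An
  age-independent irrelevant annotation (asthma, 15%) keeps
  "disease-free" a strict subset of "tissue-level healthy".
* **Covariates**: BMI normal with a mild age trend (26 + 0.05/yr, SD 4),
  RIN ~ N(7.5, 0.8) clamped to [1, 10], PMI ~ N(600, 180) min, ischemic
  time ~ N(500, 150) min, three standard-normal genotype covariates.
* **Expression**: negative-binomial counts (dispersion 0.1, i.e.
  biological CV ≈ 0.3) with lognormal library-size factors (SD 0.3 on the
  natural-log scale); a TPM-like matrix is the counts rescaled to a
  per-sample total of 10⁶.
* **Gene classes** (2,000 genes: 1,500 null + 100 per class), each with
  randomised effect signs:
  * *core_aging*: age slope ±0.015 log2/yr in everyone (0.75 log2 units
    across the age range — a strong but realistic bulk-tissue trend).
  * *disease_driven*: ±1.0 log2 disease effect, no age effect — their age
    association in the common cohort is pure confounding.
  * *healthy_specific*: age slope ±0.015 log2/yr applied only to donors
    free of the tissue-relevant disease; a diseased donor sits at
    baseline. With prevalence rising in age, the induced marginal age
    slope in the mixed cohort is ≈ 0.03 of the true slope — the HSAG
    mechanism.
  * *disease_de_only*: ±0.3 log2 disease effect — large enough for the
    direct disease contrast, while the age association it induces through
    confounding stays below the aging-FDR radar. This is what separates
    the class from *disease_driven*.
  * *sex_interaction*: ±0.5 log2 sex effect, for the sex-coefficient
    screen.
* **Latent nuisance factors**: five per-sample standard-normal factors
  loading on every gene with N(0, 0.3²) log2 loadings. They emulate the
  technical and cell-composition variance that dominates the leading
  principal components of real bulk expression — without them the leading
  PCs would be the biological effect directions themselves and the PC
  adjustment would absorb the age signal, which is not how PC correction
  behaves on real data.
* Small per-gene loadings on centred RIN (SD 0.02) and PMI (SD 0.0005)
  give the nuisance covariates something real to adjust for.

One root seed governs everything through per-stage derived substreams, so
cohort and expression stages are independently reproducible.

What it does **not** emulate: batch structure, read-level sampling, eQTL
architecture behind the genotype covariates, multiple tissues per donor
(multi-tissue studies are independent runs), nonlinear age trajectories,
and compositional shifts beyond the mechanical one induced by per-sample
total normalisation. Passing tests on synthetic data therefore validate
the statistical machinery and the confounding logic, not robustness to
every artefact of real GTEx-scale data.

A note on that compositional shift: because TPM values are constrained to a
fixed per-sample total, any net drift of the total with age subtracts a
shared offset from every gene's slope. At the default ~10% signal density
the offset is negligible relative to per-gene noise; at unrealistically
dense signal it becomes visible. The acceptance suite measures slope
recovery at the default density and also verifies the tighter recovery
after removing the offset estimated from null genes.

# Problem sizes and determinism

The shipped analyses use 2,000 genes × 500 donors for end-to-end runs,
2,000 null genes × 200 donors for type-I-error measurement, 20 seeds of
500 × 150 for FDR control, and 5,000 draws for shrinkage-hyperparameter
recovery — sizes chosen so each estimate's Monte-Carlo error is well below
the margins being tested while a full validation run stays interactive.
Exact-agreement checks (hypergeometric vs enumeration, BH vs direct
step-up, WLS vs normal equations) use exhaustive small instances where
enumeration is feasible.

# Known limitations

* The tissue-disease map ships rules for three tissues only; other tissues
  need user-supplied rules.
* Age enters linearly; late-life plateaus or accelerations are invisible.
* The genotype covariates are accepted as numeric columns; the package
  does not compute ancestry components from genotypes.
* The catalog loader trusts its input's gene identifiers; no ortholog or
  symbol-synonym mapping is attempted.
* Hypergeometric enrichment treats genes as exchangeable; expression-level
  or gene-length biases in set membership are not modelled.
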