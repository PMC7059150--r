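# agewise

Most donors in large post-mortem expression resources such as GTEx carry at
least one chronic disease, and the prevalence of tissue-relevant disease
rises steeply with age. A naive per-gene regression of expression on age in
such a cohort therefore mixes two very different signals: genuine aging
biology, and disease biology that merely *tracks* age because old donors are
sicker. `agewise` implements the comparative "healthy" versus "common" aging
analysis that untangles the two, for bulk RNA-seq cohorts with donor-level
disease annotations — and ships a synthetic-data generator that reproduces
the age → disease → expression confounding structure with known ground
truth, so the whole pipeline can be exercised and validated without any
protected data.

It is aimed at computational biologists studying transcriptomic aging who
want cohort stratification, age-association testing, differential
expression, and signature comparison in one tidyverse-native package:
every stage takes a data frame and returns a tibble, fitted objects have
`tidy()` / `glance()` / `autoplot()` methods, and the whole analysis chains
with the pipe.

## The model

**Cohorts.** Within a tissue, donors are split by their disease
annotations: *tissue-level healthy* donors carry none of the tissue-relevant
disease codes (for subcutaneous adipose: no type-2 diabetes and BMI < 30);
*tissue-level disease* donors are the complement; the *common* cohort is
everyone; *disease-free* donors carry no annotation at all. An *unhealthy*
cohort pools healthy donors aged 20–40 with fully diseased donors aged
40–70 (young diseased donors are excluded — their disease is not
age-associated). A tissue enters the analysis only with more than 80
samples, and enters the healthy-vs-disease comparison only when more than
20% of samples come from disease donors.

**Age association.** Per gene *j* and sample *i*, ordinary least squares on
log2 expression:

    Y_ij = beta_j + gamma_j Age_i + delta_j Sex_i + sum_k mu_jk Genotype_ik
           + sum_k alpha_jk PC_ik + theta_j RIN_i + phi_j PMI_i + eps_ij

with genotype-derived covariates, the top expression principal components,
RNA integrity number and post-mortem interval as nuisance terms. The age
coefficient gamma_j is tested two-sided; genes at Benjamini–Hochberg
FDR ≤ 0.01 are *aging genes*.

**Differential expression.** Disease vs healthy on raw counts via a
precision-weighted linear model with empirical-Bayes moderated t
(a from-first-principles implementation of the voom/limma computation):
log-CPM transform, lowess mean-variance trend, inverse-variance observation
weights, per-gene weighted least squares on
`condition + sex + age + RIN + ischemic time + genotype`, and
moment-matched variance shrinkage. Genes at FDR < 0.05 are DEGs.

**Signatures.** Aging genes from the common and healthy cohorts are
partitioned into core aging genes (**CAG**, significant in both),
common-specific (**CSAG**, common only — candidates for disease-driven age
association) and healthy-specific (**HSAG**, healthy only). Overlaps with
DEGs, external signatures (GMT) and disease-gene catalogs (GWAS/OMIM-style,
with the genome-wide significance and ≥ 5-genes-per-term filters) use the
upper-tail hypergeometric test; aging-vs-disease direction concordance is
summarised with an exact binomial test.

## Worked example

```r
library(agewise)

cfg <- pipeline_config(seed = 7)        # default synthetic adipose study
res <- run_pipeline(cfg)

res$eligibility
#> # A tibble: 1 × 5
#>   n_samples n_disease disease_fraction analysis_eligible healthy_vs_disease_el…
#> 1       500       214            0.428 TRUE              TRUE

res$aging$common
#> <aging_fit> 2000 genes x 500 samples; 213 aging genes at FDR <= 0.01 (99 up, 114 down)
res$aging$tissue_healthy
#> <aging_fit> 2000 genes x 286 samples; 180 aging genes at FDR <= 0.01 (96 up, 84 down)
res$de
#> <de_fit> 2000 genes; 282 DEGs at FDR < 0.05 (135 up, 147 down); prior df = 18.3
res$partition
#> <signature_partition> background 2000; CAG 91, CSAG 122, HSAG 89
```

The 500-donor synthetic cohort retains every sample (42.8% from disease
donors, so both eligibility gates pass). The common cohort yields more
aging genes (213) than the healthy cohort (180): the surplus is mostly
genes whose expression responds to the tissue-relevant disease, which rises
in prevalence with age — exactly the confounding the stratification is
designed to expose. Accordingly the partition assigns 122 genes to CSAG
(in this simulation, 93% of the truly disease-driven genes land there)
and 89 to HSAG (91% of the truly healthy-specific genes). Per-gene tables
come from `tidy(res$aging$common)`, `tidy(res$de)` and
`tidy(res$partition)`; `autoplot()` on any of these objects draws the
matching diagnostic figure.

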