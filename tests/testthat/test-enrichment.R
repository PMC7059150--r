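catalog_fixture <- function() {
  tibble::tibble(
    term = c(rep("t2d", 6), rep("copd", 5), rep("rare", 4)),
    gene = c(paste0("g", 1:6), paste0("g", 4:8), paste0("g", 1:4)),
    p = c(4e-8, 6e-8, rep(1e-9, 4), rep(NA, 5), rep(NA, 4)),
    source = c(rep("gwas", 6), rep("omim", 5), rep("omim", 4))
  )
}

test_that("catalog filters apply the stated numeric rules strictly", {
  cat0 <- load_disease_catalog(catalog_fixture(), min_genes = 2)
  t2d <- cat0$gene[cat0$term == "t2d"]
  expect_true("g1" %in% t2d)    # p = 4e-8 < 5e-8: kept
  expect_false("g2" %in% t2d)   # p = 6e-8: dropped
  # OMIM rows keep their genes regardless of p
  expect_length(cat0$gene[cat0$term == "copd"], 5)

  # default min_genes = 5 drops the 4-gene term
  cat5 <- load_disease_catalog(catalog_fixture())
  expect_false("rare" %in% cat5$term)
  expect_equal(sort(unique(cat5$term)), c("copd", "t2d"))

  # duplicate (term, gene) rows collapse to one membership
  dup <- dplyr::bind_rows(catalog_fixture(), catalog_fixture())
  expect_identical(load_disease_catalog(dup, min_genes = 2),
                   load_disease_catalog(catalog_fixture(), min_genes = 2))

  expect_error(load_disease_catalog(tibble::tibble(x = 1)),
               "required column")
})

test_that("catalog loading is round-trip idempotent", {
  cat0 <- load_disease_catalog(catalog_fixture(), min_genes = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(cat0, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cat1 <- load_disease_catalog(path, min_genes = 2)
  expect_equal(as.data.frame(cat1), as.data.frame(cat0))
})

fake_partition <- function(bg, cag, csag, hsag, dirs = NULL) {
  mem <- dplyr::bind_rows(
    tibble::tibble(gene_id = cag, set = "CAG"),
    tibble::tibble(gene_id = csag, set = "CSAG"),
    tibble::tibble(gene_id = hsag, set = "HSAG")
  )
  mem$direction <- if (is.null(dirs)) 1 else dirs
  structure(list(cag = cag, csag = csag, hsag = hsag,
                 common_sig = union(cag, csag), healthy_sig = union(cag, hsag),
                 background = bg, membership = mem),
            class = "signature_partition")
}

test_that("disease enrichment reports every set-direction column", {
  bg <- paste0("g", 1:40)
  part <- fake_partition(bg, cag = bg[1:5], csag = bg[6:10], hsag = bg[11:15])
  catalog <- tibble::tibble(
    term = rep(c("catch_cag", "elsewhere"), each = 5),
    gene = c(bg[1:5], bg[30:34]),
    source = "merged"
  )
  res <- disease_enrichment(part, catalog, top_k = 1)
  expect_setequal(unique(res$set), c("CAG", "CSAG", "HSAG"))
  expect_setequal(unique(res$direction), c("up", "down"))

  # term identical to the up-regulated CAG set: maximal enrichment there
  cag_up <- dplyr::filter(res, set == "CAG", direction == "up")
  expect_equal(cag_up$p[cag_up$term == "catch_cag"],
               oracle_hyper(40, 5, 5, 5), tolerance = 1e-12)
  expect_true(cag_up$top[cag_up$term == "catch_cag"])
  # empty columns (no down-regulated genes here) give p = 1
  expect_true(all(dplyr::filter(res, direction == "down")$p == 1))
  # every p equals the overlap test on its own margins
  for (i in seq_len(nrow(res))) {
    expect_equal(res$p[i],
                 oracle_hyper(res$N[i], res$K[i], res$n[i], res$k[i]),
                 tolerance = 1e-12)
  }

  # out-of-background terms are skipped
  cat_out <- tibble::tibble(term = "alien", gene = paste0("x", 1:6),
                            source = "merged")
  expect_message(res_out <- disease_enrichment(part, cat_out), "skipped")
  expect_equal(nrow(res_out), 0)
})

test_that("a term planted inside disease-driven genes ranks first for CSAGs", {
  hits <- 0
  n_runs <- 10
  for (s in seq_len(n_runs)) {
    cfg <- simulation_config(
      n_donors = 300, n_null = 600, n_core_aging = 50, n_disease_driven = 50,
      n_healthy_specific = 50, n_disease_de_only = 0, n_sex_interaction = 0,
      seed = 500 + s
    )
    sim <- simulate_dataset(cfg)
    a <- assign_cohorts(sim$donors, sim$samples, "adipose_subcutaneous")
    le <- suppressMessages(preprocess_expression(sim$tpm))
    cov <- dplyr::select(a, sample_id, age, sex, rin, pmi,
                         dplyr::starts_with("genotype_"))
    fit_c <- fit_age_regression(le, cov)
    fit_h <- fit_age_regression(
      le[, a$sample_id[a$tissue_healthy]],
      dplyr::filter(cov, sample_id %in% a$sample_id[a$tissue_healthy])
    )
    part <- suppressMessages(partition_signatures(tidy(fit_c), tidy(fit_h)))

    dd <- sim$truth$gene_id[sim$truth$gene_class == "disease_driven"]
    withr::with_seed(600 + s, {
      planted <- sample(dd, 40)  # 80% of the disease-driven genes
      decoys <- replicate(5, sample(sim$truth$gene_id, 40), simplify = FALSE)
    })
    catalog <- tibble::tibble(
      term = rep(c("planted", paste0("decoy", 1:5)), each = 40),
      gene = c(planted, unlist(decoys)),
      source = "merged"
    )
    res <- disease_enrichment(part, catalog, top_k = 1)
    csag <- dplyr::filter(res, set == "CSAG")
    best <- csag$term[which.min(csag$p)]
    hits <- hits + (best == "planted")
  }
  expect_gte(hits / n_runs, 0.9)
})

test_that("candidate aging-gene overlap flags enrichment where planted", {
  bg <- paste0("g", 1:50)
  part <- fake_partition(bg, cag = bg[1:10], csag = bg[11:20],
                         hsag = bg[21:30])
  expect_true(all(genage_overlap(part, character(0))$p == 1))

  res <- genage_overlap(part, bg[1:10])  # the CAG set itself
  expect_equal(res$p[res$set == "CAG"], oracle_hyper(50, 10, 10, 10),
               tolerance = 1e-12)
  expect_true(res$enriched[res$set == "CAG"])
  expect_false(res$enriched[res$set == "HSAG"])
})
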