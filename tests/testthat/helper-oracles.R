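# Independent oracles used to check the package's computations.

# Benjamini-Hochberg step-up computed directly from its definition:
# q_(i) = min_{j >= i} p_(j) * m / j, capped at 1, mapped to input order.
oracle_bh <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Upper-tail hypergeometric probability by explicit enumeration over the
# count of white balls drawn: P(X >= k) = sum_j C(K,j) C(N-K,n-j) / C(N,n).
oracle_hyper <- function(N, K, n, k) {
  js <- k:min(K, n)
  js <- js[js >= max(0, n - (N - K))]
  if (length(js) == 0) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Weighted least squares by brute-force normal equations.
oracle_wls <- function(X, y, w = rep(1, length(y))) {
  XtW <- t(X * w)
  beta <- solve(XtW %*% X, XtW %*% y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(w * res^2) / df
  se <- sqrt(diag(solve(XtW %*% X)) * s2)
  list(coefficients = drop(beta), se = se, sigma2 = s2)
}

# A small synthetic dataset shared by tests that only need realistic shapes.
small_config <- function(seed = 42, n_donors = 150, ...) {
  simulation_config(
    n_donors = n_donors, n_null = 250, n_core_aging = 30,
    n_disease_driven = 30, n_healthy_specific = 30, n_disease_de_only = 30,
    n_sex_interaction = 30, seed = seed, ...
  )
}

# Minimal donor/sample tables for cohort tests.
make_donors <- function(age, codes = "", bmi = 24, sex = "female",
                        pmi = 600) {
  n <- length(age)
  tibble::tibble(
    donor_id = sprintf("D%03d", seq_len(n)),
    age = age,
    sex = rep_len(sex, n),
    bmi = rep_len(bmi, n),
    disease_codes = rep_len(codes, n),
    pmi = rep_len(pmi, n),
    genotype_1 = 0, genotype_2 = 0, genotype_3 = 0
  )
}

make_samples <- function(donors, tissue = "adipose_subcutaneous", rin = 7.5) {
  tibble::tibble(
    sample_id = sub("D", "S", donors$donor_id),
    donor_id = donors$donor_id,
    tissue = tissue,
    rin = rep_len(rin, nrow(donors)),
    ischemic_time = 500
  )
}
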