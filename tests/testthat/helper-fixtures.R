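# Small deterministic fixtures and brute-force oracles shared across tests.

# Free-standing annotation for a set of probe IDs: one probe per locus on
# chr1, no islands, no flags.
flat_annotation <- function(probe_ids, chromosome = "chr1",
                            gene = paste0("G", seq_along(probe_ids))) {
  tibble::tibble(
    probe_id = probe_ids,
    chromosome = chromosome,
    position = seq_along(probe_ids) * 1000L,
    island_name = NA_character_,
    hil_class = "nonisland",
    closest_tss_gene = gene,
    distance_to_tss = 100L,
    snp_flag = FALSE,
    crossreactive_flag = FALSE
  )
}

# A tiny hand-built cohort: all detection p passing, no missing cells.
toy_cohort <- function(n_probes = 10, n_samples = 4, seed = 42) {
  set.seed(seed)
  probe_ids <- sprintf("p%02d", seq_len(n_probes))
  sample_ids <- sprintf("s%d", seq_len(n_samples))
  beta <- matrix(runif(n_probes * n_samples, 0.05, 0.95),
                 nrow = n_probes, dimnames = list(probe_ids, sample_ids))
  detp <- matrix(runif(n_probes * n_samples, 0, 1e-6),
                 nrow = n_probes, dimnames = list(probe_ids, sample_ids))
  cov <- tibble::tibble(
    sample_id = sample_ids,
    G = rep_len(c(0L, 1L), n_samples),
    T = rep_len(1:5, n_samples),
    B = runif(n_samples, 4, 9),
    W = rep_len(c(0L, 1L), n_samples),
    S = rep_len(0:2, n_samples)
  )
  methylation_cohort(beta, detp, cov)
}

# Covariate table large enough for stable model fits.
toy_covariates <- function(n = 30, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    sample_id = sprintf("s%03d", seq_len(n)),
    G = rbinom(n, 1, 0.4),
    T = sample(1:5, n, replace = TRUE),
    B = runif(n, 4, 9),
    W = rep_len(c(0L, 1L), n),
    S = rbinom(n, 2, 0.5)
  )
}

# Brute-force quantile normalization following the textbook definition:
# reference distribution = mean of the column-sorted matrix; each value is
# replaced by the reference value at its within-column rank, ties sharing
# the mean of the reference values their rank span covers.
qn_brute <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    rk <- rank(m[, j], ties.method = "average")
    # fractional ranks (ties) interpolate between adjacent reference values
    lo <- floor(rk); hi <- ceiling(rk)
    out[, j] <- (ref[lo] + ref[hi]) / 2
  }
  out
}

# Brute-force BH step-up from the definition.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- pmin(1, p[o] * m / seq_len(m))
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- q
  out
}

# Direct normal-equations OLS solve (independent of the package fit path).
ols_oracle <- function(y, X) {
  drop(solve(t(X) %*% X) %*% t(X) %*% y)
}
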