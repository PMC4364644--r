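test_that("the design matrix carries the model's covariate coding", {
  cov <- toy_covariates(8)
  X <- build_design(cov, model_spec("W"))
  expect_identical(dim(X), c(8L, 5L))
  expect_identical(colnames(X), c("(Intercept)", "G", "T", "W", "B"))
  # the genotype model appends the additive dose column (TT=0, TC=1, CC=2)
  Xs <- build_design(cov, model_spec("S"))
  expect_identical(colnames(Xs)[6], "S")
  expect_equal(unname(Xs[, "S"]), as.numeric(cov$S))
  # samples with missing covariates are dropped and recorded
  cov2 <- cov
  cov2$B[3] <- NA
  expect_message(X2 <- build_design(cov2, model_spec("W")), "Dropping 1")
  expect_identical(nrow(X2), 7L)
  expect_identical(attr(X2, "dropped_samples"), cov$sample_id[3])
  # a single-sex cohort makes G constant -> rank-deficiency error naming G
  cov3 <- cov
  cov3$G <- 0L
  expect_error(build_design(cov3, model_spec("W")), "G")
})

test_that("a noiseless response reproduces the generating coefficients", {
  cov <- toy_covariates(20)
  X <- build_design(cov, model_spec("W"))
  b_true <- c(1, 0.5, -0.2, 2, 0.1)
  y <- drop(X %*% b_true)
  fit <- robust_fit(y, X, model_spec("W"))
  expect_equal(unname(fit$coefficients), b_true, tolerance = 1e-8)
  expect_equal(fit$sigma2, 0, tolerance = 1e-12)
  expect_identical(fit$df, nrow(X) - ncol(X))
  expect_true(fit$converged)
})

test_that("robust equals OLS when no residual reaches the Huber threshold", {
  n <- 200
  cov <- toy_covariates(n, seed = 3)
  X <- build_design(cov, model_spec("W"))
  b_true <- c(0.5, 0.1, 0.05, 1, -0.02)
  # bounded residuals with max|r|/median|r| well under 1.994, so even after
  # the OLS projection no residual reaches the Huber threshold and every
  # weight is exactly 1
  set.seed(91)
  e <- sample(c(-1, 1), n, replace = TRUE) * seq(0.60, 0.80, length.out = n)
  y <- drop(X %*% b_true) + e
  b_ols <- ols_oracle(y, X)   # direct normal-equations solve
  r_ols <- drop(y - X %*% b_ols)
  stopifnot(max(abs(r_ols)) < 1.994 * median(abs(r_ols)))
  fit_r <- robust_fit(y, X, model_spec("W", robust = TRUE))
  expect_equal(unname(fit_r$coefficients), unname(b_ols), tolerance = 1e-6)
  expect_true(all(fit_r$weights == 1))
})

test_that("robust fits stay close to OLS on clean Gaussian data", {
  set.seed(7)
  cov <- toy_covariates(60, seed = 7)
  X <- build_design(cov, model_spec("W"))
  delta <- replicate(20, {
    y <- drop(X %*% c(0, 0.1, 0, 0.8, 0)) + rnorm(60, sd = 0.4)
    fr <- robust_fit(y, X, model_spec("W"))
    abs(fr$coefficients["W"] - ols_oracle(y, X)[4])
  })
  expect_lt(max(delta), 0.08)
  expect_lt(mean(delta), 0.03)
})

test_that("Huber IRLS agrees with the reference M-estimation implementation", {
  set.seed(12)
  cov <- toy_covariates(50, seed = 12)
  X <- build_design(cov, model_spec("W"))
  y <- drop(X %*% c(0.2, 0, 0.1, 0.7, 0)) + rnorm(50, sd = 0.5)
  y[7] <- y[7] + 8    # one outlier so the weights matter
  ours <- robust_fit(y, X, model_spec("W"))
  ref <- MASS::rlm(X, y, psi = MASS::psi.huber, k = 1.345,
                   scale.est = "MAD", maxit = 200, acc = 1e-10)
  expect_equal(unname(ours$coefficients), unname(coef(ref)),
               tolerance = 2e-2)
})

test_that("one gross outlier moves the robust fit less than OLS", {
  set.seed(19)
  cov <- toy_covariates(30, seed = 19)
  X <- build_design(cov, model_spec("W"))
  y <- drop(X %*% c(0, 0, 0, 1, 0)) + rnorm(30, sd = 0.3)
  y_out <- y
  y_out[5] <- y[5] + 25
  # three fits: full OLS, leave-outlier-out OLS, robust on contaminated data
  b_full <- ols_oracle(y_out, X)[4]
  b_loo <- ols_oracle(y_out[-5], X[-5, ])[4]
  b_rob <- robust_fit(y_out, X, model_spec("W"))$coefficients["W"]
  expect_lt(abs(b_rob - b_loo), abs(b_full - b_loo))
  expect_lt(robust_fit(y_out, X, model_spec("W"))$weights[5], 0.2)
})

test_that("non-convergence at max_iter is flagged, not an error", {
  set.seed(2)
  cov <- toy_covariates(25, seed = 2)
  X <- build_design(cov, model_spec("W"))
  y <- drop(X %*% c(0, 0, 0, 0.5, 0)) + rt(25, df = 1)
  fit <- robust_fit(y, X, model_spec("W", max_iter = 1))
  expect_false(fit$converged)
  expect_true(all(is.finite(fit$coefficients)))
})

test_that("equal residual variances collapse to the d0 = Inf branch", {
  cov <- toy_covariates(20, seed = 5)
  m <- matrix(rnorm(200), nrow = 10,
              dimnames = list(sprintf("L%02d", 1:10), cov$sample_id))
  fit <- fit_locations(m, cov, model_spec("W", robust = FALSE))
  v <- 0.37
  fit$table$sigma2 <- v
  out <- ebayes_moderate(fit)
  expect_identical(out$prior$d0, Inf)
  expect_equal(out$prior$s0_2, v, tolerance = 1e-9)
  expect_equal(out$table$s2_moderated, rep(v, 10), tolerance = 1e-9)
  # d0 -> Inf limit: moderated t = b / (u * s0)
  expect_equal(
    out$table$t,
    out$table$coefficient / (out$table$se_unscaled * sqrt(v)),
    tolerance = 1e-9
  )
})

test_that("moment matching recovers a known (d0, s0^2) prior", {
  set.seed(101)
  d0_true <- 4; s0_true <- 1; d <- 10; n_loc <- 200
  # true variances from a scaled inverse chi-square, then observed
  # variances from the usual chi-square sampling model
  sigma2 <- d0_true * s0_true / rchisq(n_loc, df = d0_true)
  s2 <- sigma2 * rchisq(n_loc, df = d) / d

  cov <- toy_covariates(d + 6, seed = 6)
  m <- matrix(rnorm(n_loc * (d + 6)), nrow = n_loc,
              dimnames = list(sprintf("L%03d", seq_len(n_loc)),
                              cov$sample_id))
  fit <- fit_locations(m, cov, model_spec("W", robust = FALSE))
  fit$table$sigma2 <- s2
  fit$table$df <- d
  out <- ebayes_moderate(fit)

  # independent oracle: same moment equations solved by stats::uniroot
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  v <- var(e) - trigamma(d / 2)
  d0_oracle <- 2 * uniroot(function(x) trigamma(x) - v,
                           c(1e-3, 1e3), tol = 1e-12)$root
  s0_oracle <- exp(mean(e) + digamma(d0_oracle / 2) - log(d0_oracle / 2))
  expect_equal(out$prior$d0, d0_oracle, tolerance = 1e-6)
  expect_equal(out$prior$s0_2, s0_oracle, tolerance = 1e-6)
  # and the recovered prior sits near the simulation truth
  expect_lt(abs(out$prior$d0 - d0_true), 2)
  expect_lt(abs(out$prior$s0_2 - s0_true), 0.3)
})

test_that("moderated statistics agree with the reference eBayes pipeline", {
  set.seed(55)
  cov <- toy_covariates(30, seed = 55)
  # heteroscedastic rows so the prior degrees of freedom come out finite
  # and the full moment-matching path is exercised
  row_sd <- runif(80, 0.2, 1.2)
  m <- matrix(rnorm(80 * 30), nrow = 80,
              dimnames = list(sprintf("L%03d", 1:80), cov$sample_id)) * row_sd
  m[1:5, cov$W == 1] <- m[1:5, cov$W == 1] + 1

  spec <- model_spec("W", robust = FALSE)
  fit <- ebayes_moderate(fit_locations(m, cov, spec))
  expect_true(is.finite(fit$prior$d0))

  X <- build_design(cov, spec)
  lf <- limma::eBayes(limma::lmFit(m, X))
  expect_equal(fit$prior$d0, lf$df.prior, tolerance = 1e-6)
  expect_equal(fit$prior$s0_2, lf$s2.prior, tolerance = 1e-6)
  expect_equal(fit$table$t, unname(lf$t[, "W"]), tolerance = 1e-8)
  expect_equal(fit$table$p_value, unname(lf$p.value[, "W"]), tolerance = 1e-8)
})

test_that("forcing d0 = 0 recovers the classical per-location t-test", {
  set.seed(77)
  cov <- toy_covariates(25, seed = 77)
  m <- matrix(rnorm(40 * 25), nrow = 40,
              dimnames = list(sprintf("L%02d", 1:40), cov$sample_id))
  spec <- model_spec("W", robust = FALSE)
  out <- ebayes_moderate(fit_locations(m, cov, spec), d0 = 0, s0_2 = 1)
  X <- build_design(cov, spec)
  t_classic <- apply(m, 1, function(y) {
    summary(lm(y ~ X - 1))$coefficients["XW", "t value"]
  })
  expect_equal(out$table$t, unname(t_classic), tolerance = 1e-8)
})

test_that("BH adjustment matches the step-up definition", {
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(123)
  for (mlen in c(5, 100, 1000)) {
    p <- runif(mlen)^2
    q <- bh_adjust(p)
    expect_equal(q, bh_brute(p), tolerance = 1e-12)
    expect_true(all(q >= p) && all(q <= 1))
    # monotone in the raw order after sorting
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("ranking returns the smallest raw p first with deterministic ties", {
  tbl <- tibble::tibble(
    location_id = c("c", "a", "b"),
    coefficient = c(1, 2, 3),
    t = c(1, 2, 3),
    p_value = c(0.5, 0.01, 0.01),
    p_adjusted = c(0.5, 0.03, 0.03),
    converged = TRUE
  )
  fit <- structure(list(table = tbl, spec = model_spec("W"), prior = NULL),
                   class = "meth_fit")
  top1 <- rank_top(fit, k = 1)
  expect_identical(top1$location_id, "a")     # tie at p=0.01 -> "a" before "b"
  top2 <- rank_top(fit, k = 2)
  expect_identical(top2$location_id, c("a", "b"))
  expect_warning(all_rows <- rank_top(fit, k = 10), "exceeds")
  expect_identical(nrow(all_rows), 3L)
})

test_that("an overwhelming spiked effect ranks first, agreeing with a t-test oracle", {
  sim <- simulate_cohort(sim_config(
    n_probes = 2000, n_samples = 69, frac_weight_effect = 0,
    frac_snp_effect = 0, frac_island_members = 0, n_islands = 1,
    frac_snp_probes = 0, frac_crossreactive = 0, frac_sex_chrom = 0,
    effect_size_m = 2, n_shared_genes = 0, seed = 33
  ))
  m <- quantile_normalize(beta_to_m(sim$cohort$beta))
  # spike one probe by hand at +2 M-units in the obese group
  w <- sim$cohort$covariates$W
  spiked <- "cg0001000"
  m[spiked, w == 1] <- m[spiked, w == 1] + 2
  fit <- diff_methylation(m, sim$cohort$covariates, model_spec("W"))
  expect_identical(rank_top(fit, k = 1)$location_id, spiked)
  # oracle: plain two-sample t-test per probe finds the same probe
  p_oracle <- apply(m, 1, function(y) t.test(y[w == 1], y[w == 0])$p.value)
  expect_identical(names(which.min(p_oracle)), spiked)
})
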