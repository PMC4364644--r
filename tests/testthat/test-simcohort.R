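test_that("identical config and seed reproduce the cohort bit for bit", {
  cfg <- sim_config(n_probes = 400, n_samples = 20, seed = 11,
                    frac_missing = 0.01, detection_fail_rate = 0.001)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$cohort$beta, b$cohort$beta)
  expect_identical(a$cohort$detection_p, b$cohort$detection_p)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$truth, b$truth)
  c <- simulate_cohort(sim_config(n_probes = 400, n_samples = 20, seed = 12,
                                  frac_missing = 0.01,
                                  detection_fail_rate = 0.001))
  expect_false(identical(a$cohort$beta, c$cohort$beta))
})

test_that("truth set matches the configured effect fractions exactly", {
  sim <- simulate_cohort(sim_config(
    n_probes = 2000, n_samples = 69, frac_weight_effect = 0.01,
    frac_snp_effect = 0, effect_size_m = 1.5, seed = 1
  ))
  expect_identical(sum(sim$truth$true_weight_effect != 0), 20L)
  expect_true(all(abs(sim$truth$true_weight_effect[
    sim$truth$true_weight_effect != 0]) == 1.5))
  expect_true(all(sim$truth$true_snp_effect == 0))

  null_sim <- simulate_cohort(sim_config(
    n_probes = 500, n_samples = 10, frac_weight_effect = 0,
    frac_snp_effect = 0, seed = 2
  ))
  expect_true(all(null_sim$truth$true_weight_effect == 0))
  expect_true(all(null_sim$truth$true_snp_effect == 0))
  # weight and genotype truth sets are disjoint by construction
  both <- simulate_cohort(sim_config(n_probes = 1000, n_samples = 10,
                                     frac_weight_effect = 0.1,
                                     frac_snp_effect = 0.1, seed = 3))
  expect_identical(
    sum(both$truth$true_weight_effect != 0 & both$truth$true_snp_effect != 0),
    0L
  )
})

test_that("cohort structure obeys the domain invariants", {
  sim <- simulate_cohort(sim_config(n_probes = 1000, n_samples = 30, seed = 5,
                                    frac_missing = 0.01))
  beta <- sim$cohort$beta
  expect_true(all(beta[!is.na(beta)] > 0 & beta[!is.na(beta)] < 1))
  cov <- sim$cohort$covariates
  expect_true(all(cov$G %in% 0:1))
  expect_true(all(cov$W %in% 0:1))
  expect_true(all(cov$S %in% 0:2))
  expect_true(all(cov$T %in% 1:5))
  expect_true(all(cov$B > 0))
  # island invariants: members share a chromosome, names parse to spans
  ann <- sim$annotation
  expect_silent(validate_annotation(ann, rownames(beta)))
  members <- ann[!is.na(ann$island_name), ]
  expect_gt(nrow(members), 0)
  parsed <- parse_island_name(unique(members$island_name))
  expect_true(all(parsed$start <= parsed$end))
  expect_true(all(parsed$class_token %in% c("HC", "IC", "ICshore")))
})

test_that("baseline beta distribution follows the configured mixture", {
  bm <- list(weights = c(0.5, 0.2, 0.3), shape1 = c(2, 5, 15),
             shape2 = c(15, 5, 2))
  sim <- simulate_cohort(sim_config(
    n_probes = 10000, n_samples = 2, frac_weight_effect = 0,
    frac_snp_effect = 0, frac_island_members = 0, n_islands = 1,
    noise_sd_m = 0.05, beta_mixture = bm, seed = 9
  ))
  # with near-zero noise the per-probe mean beta approximates the mixture
  grand_mean <- mean(rowMeans(sim$cohort$beta))
  mix_mean <- sum(bm$weights * bm$shape1 / (bm$shape1 + bm$shape2))
  expect_lt(abs(grand_mean - mix_mean), 0.02)
})

test_that("detection failures appear at the configured cell rate", {
  sim <- simulate_cohort(sim_config(n_probes = 2000, n_samples = 20,
                                    detection_fail_rate = 0.1, seed = 13))
  detp <- sim$cohort$detection_p
  expect_true(all(detp < 1e-6 | detp >= 0.05))
  expect_lt(abs(mean(detp >= 0.05) - 0.1), 0.01)
})

test_that("fixtures round-trip through write and read", {
  sim <- simulate_cohort(sim_config(n_probes = 10, n_samples = 4, seed = 21))
  dir <- withr::local_tempdir()
  paths <- write_fixture(sim$cohort, sim$annotation, dir)
  expect_true(all(file.exists(paths)))
  beta_lines <- readLines(paths["beta"])
  expect_length(beta_lines, 11)                      # header + 10 probes
  expect_length(strsplit(beta_lines[1], "\t")[[1]], 5)  # id + 4 samples

  back <- read_cohort(paths["beta"], paths["detection_p"], paths["covariates"])
  expect_equal(back$beta, sim$cohort$beta, tolerance = 1e-12)
  expect_equal(back$detection_p, sim$cohort$detection_p, tolerance = 1e-12)
  ann_back <- read_annotation(paths["annotation"])
  expect_equal(as.data.frame(ann_back), as.data.frame(sim$annotation))
})

test_that("an empty cohort writes valid header-only files", {
  cov <- toy_covariates(4)
  beta <- matrix(numeric(0), nrow = 0, ncol = 4,
                 dimnames = list(character(0), cov$sample_id))
  cohort <- methylation_cohort(beta, beta, cov)
  dir <- withr::local_tempdir()
  paths <- write_fixture(cohort, flat_annotation(character(0)), dir)
  expect_length(readLines(paths["beta"]), 1)
  back <- read_beta_matrix(paths["beta"])
  expect_identical(dim(back), c(0L, 4L))
})

test_that("invalid configurations are rejected naming the offending field", {
  expect_error(sim_config(n_probes = 0, seed = 1), "n_probes")
  expect_error(sim_config(frac_missing = 1.2, seed = 1), "frac_missing")
  expect_error(sim_config(frac_weight_effect = 0.6, frac_snp_effect = 0.6,
                          seed = 1), "frac_weight_effect")
  expect_error(sim_config(noise_sd_m = 0, seed = 1), "noise_sd_m")
  expect_error(sim_config(), "seed")
})

test_that("shared-gene spiking marks one gene for both contrasts", {
  sim <- simulate_cohort(sim_config(n_probes = 500, n_samples = 20,
                                    frac_weight_effect = 0,
                                    frac_snp_effect = 0,
                                    n_shared_genes = 1, seed = 17))
  expect_length(sim$shared_genes, 1)
  gene_probes <- sim$annotation$probe_id[
    sim$annotation$closest_tss_gene == sim$shared_genes]
  tr <- sim$truth[sim$truth$probe_id %in% gene_probes, ]
  expect_identical(sum(tr$true_weight_effect != 0), 1L)
  expect_identical(sum(tr$true_snp_effect != 0), 1L)
})
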