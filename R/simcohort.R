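#' Configuration for the synthetic-cohort simulator
#'
#' Builds and validates the parameter set for [simulate_cohort()]. Defaults
#' emulate a mixed-sex preadolescent whole-blood cohort profiled on an
#' Infinium-style 27k array: 69 children (35 obese / 34 normal-weight,
#' 47 girls / 22 boys), a promoter-biased three-component Beta mixture for
#' baseline methylation, island membership for roughly 42% of probes at an
#' average of ~2.1 members per island, and differential effects spiked
#' additively on the M scale.
#'
#' @param n_probes Number of probes on the synthetic array.
#' @param n_samples Number of samples (children) in the cohort.
#' @param frac_weight_effect Proportion of probes carrying a true
#'   weight-category effect (obese vs normal-weight).
#' @param frac_snp_effect Proportion of probes carrying a true per-allele
#'   genotype-dose effect. Weight and genotype truth sets are disjoint.
#' @param effect_size_m Absolute effect magnitude in M-value units; each
#'   spiked probe receives a random sign.
#' @param frac_island_members Proportion of probes assigned to a named CpG
#'   island or island shore.
#' @param n_islands Number of distinct islands among the member probes.
#' @param frac_snp_probes Proportion of probes flagged as containing a SNP.
#' @param frac_crossreactive Proportion flagged as cross-reactive
#'   (non-specific). Disjoint from the SNP flag and from sex chromosomes so
#'   that removal counts are additive.
#' @param frac_sex_chrom Proportion of probes placed on chrX/chrY.
#' @param frac_missing Proportion of probes given one missing beta cell.
#'   The default cohort is complete-case, matching the processed
#'   series-matrix style of deposited data; raise this to exercise the
#'   missing-value QC rules.
#' @param detection_fail_rate Per-cell probability that a detection p-value
#'   is drawn from the failing stratum `U(0.05, 1)` rather than the passing
#'   stratum `U(0, 1e-6)`; the two strata fall unambiguously on either side
#'   of both QC thresholds (0.05 and 1e-5).
#' @param beta_mixture Three-component Beta mixture for baseline probe
#'   methylation: a list with numeric vectors `weights`, `shape1`, `shape2`
#'   of length 3 (unmethylated / hemimethylated / methylated).
#' @param noise_sd_m Within-group noise standard deviation on the M scale.
#' @param confounding_rho Latent correlation between Tanner stage and weight
#'   category, so covariate adjustment is genuinely exercised.
#' @param n_obese,n_male Group sizes used when dichotomizing weight category
#'   and sex; scaled proportionally when `n_samples` differs from 69.
#' @param snp_allele_freq Risk-allele frequency for the additive genotype
#'   dose (TT=0, TC=1, CC=2) drawn under Hardy-Weinberg equilibrium.
#' @param n_shared_genes Number of genes spiked for *both* contrasts: one
#'   member probe receives a weight effect and a second probe of the same
#'   gene a genotype effect, both negative (the hypomethylation pattern the
#'   discovery step is designed to catch).
#' @param seed Integer RNG seed. Mandatory: identical configuration and
#'   seed reproduce the cohort bit for bit.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_probes = 5000,
                       n_samples = 69,
                       frac_weight_effect = 0.02,
                       frac_snp_effect = 0.02,
                       effect_size_m = 1.5,
                       frac_island_members = 0.42,
                       n_islands = 1000,
                       frac_snp_probes = 0.03,
                       frac_crossreactive = 0.02,
                       frac_sex_chrom = 0.04,
                       frac_missing = 0,
                       detection_fail_rate = 0,
                       beta_mixture = list(
                         weights = c(0.60, 0.15, 0.25),
                         shape1 = c(1.5, 5, 15),
                         shape2 = c(15, 5, 1.5)
                       ),
                       noise_sd_m = 0.5,
                       confounding_rho = 0.3,
                       n_obese = NULL,
                       n_male = NULL,
                       snp_allele_freq = 0.48,
                       n_shared_genes = 0,
                       seed = NULL) {
  cfg <- list(
    n_probes = n_probes, n_samples = n_samples,
    frac_weight_effect = frac_weight_effect,
    frac_snp_effect = frac_snp_effect,
    effect_size_m = effect_size_m,
    frac_island_members = frac_island_members,
    n_islands = n_islands,
    frac_snp_probes = frac_snp_probes,
    frac_crossreactive = frac_crossreactive,
    frac_sex_chrom = frac_sex_chrom,
    frac_missing = frac_missing,
    detection_fail_rate = detection_fail_rate,
    beta_mixture = beta_mixture,
    noise_sd_m = noise_sd_m,
    confounding_rho = confounding_rho,
    n_obese = n_obese %||% round(n_samples * 35 / 69),
    n_male = n_male %||% round(n_samples * 22 / 69),
    snp_allele_freq = snp_allele_freq,
    n_shared_genes = n_shared_genes,
    seed = seed
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  bad_count <- function(x) !is.numeric(x) || length(x) != 1 || is.na(x) ||
    x < 1 || x != round(x)
  for (fld in c("n_probes", "n_samples", "n_islands")) {
    if (bad_count(cfg[[fld]])) {
      abort(sprintf("Invalid configuration: `%s` must be a positive integer.", fld))
    }
  }
  props <- c(
    "frac_weight_effect", "frac_snp_effect", "frac_island_members",
    "frac_snp_probes", "frac_crossreactive", "frac_sex_chrom",
    "frac_missing", "detection_fail_rate", "snp_allele_freq"
  )
  for (fld in props) {
    x <- cfg[[fld]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
      abort(sprintf("Invalid configuration: `%s` must be a proportion in [0, 1].", fld))
    }
  }
  if (cfg$frac_weight_effect + cfg$frac_snp_effect > 1) {
    abort(paste(
      "Invalid configuration: `frac_weight_effect` + `frac_snp_effect`",
      "must not exceed 1 (truth sets are disjoint by construction)."
    ))
  }
  if (!is.numeric(cfg$effect_size_m) || cfg$effect_size_m < 0) {
    abort("Invalid configuration: `effect_size_m` must be non-negative.")
  }
  if (!is.numeric(cfg$noise_sd_m) || cfg$noise_sd_m <= 0) {
    abort("Invalid configuration: `noise_sd_m` must be positive.")
  }
  if (abs(cfg$confounding_rho) >= 1) {
    abort("Invalid configuration: `confounding_rho` must lie in (-1, 1).")
  }
  bm <- cfg$beta_mixture
  if (!is.list(bm) || !all(c("weights", "shape1", "shape2") %in% names(bm)) ||
      any(lengths(bm[c("weights", "shape1", "shape2")]) != 3) ||
      any(bm$weights < 0) || sum(bm$weights) <= 0 ||
      any(bm$shape1 <= 0) || any(bm$shape2 <= 0)) {
    abort(paste(
      "Invalid configuration: `beta_mixture` must hold 3 non-negative",
      "`weights` and 3 positive `shape1`/`shape2` values."
    ))
  }
  if (is.null(cfg$seed) || !is.numeric(cfg$seed) || is.na(cfg$seed)) {
    abort("Invalid configuration: `seed` is mandatory for reproducibility.")
  }
  invisible(cfg)
}

#' Simulate a synthetic Infinium-like methylation cohort
#'
#' Draws a complete probe-by-sample beta-value matrix, a matching detection
#' p-value matrix, sample covariates, a probe annotation manifest and the
#' ground-truth effect table, with the statistical structure the downstream
#' analysis assumes. Baseline methylation comes from a three-component Beta
#' mixture; differential effects are injected additively on the M scale
#' (where the linear model lives) and mapped back to beta for storage.
#' Islands are laid out contiguously along synthetic chromosomes so that
#' island spans are well-formed and members share a chromosome.
#'
#' @param cfg A [sim_config()] object.
#' @return A list with components:
#'   * `cohort` — a [methylation_cohort()] (beta, detection p, covariates),
#'   * `annotation` — probe annotation tibble (see [validate_annotation()]),
#'   * `truth` — tibble with `probe_id`, `true_weight_effect`,
#'     `true_snp_effect` (signed M-scale effects, 0 for null probes).
#' @examples
#' sim <- simulate_cohort(sim_config(n_probes = 200, n_samples = 20, seed = 1))
#' sim$cohort
#' @export
simulate_cohort <- function(cfg) {
  if (!inherits(cfg, "sim_config")) cfg <- do.call(sim_config, cfg)
  validate_sim_config(cfg)
  set.seed(cfg$seed)

  n <- cfg$n_probes
  ns <- cfg$n_samples
  probe_ids <- sprintf("cg%07d", seq_len(n))
  sample_ids <- sprintf("S%03d", seq_len(ns))

  covariates <- simulate_covariates(cfg, sample_ids)
  annotation <- simulate_annotation(cfg, probe_ids)

  # --- truth assignment ---------------------------------------------------
  # Effects are spiked on "clean" free-standing autosomal probes (no QC
  # flag, no island membership, no missing cell) so that spiked probes
  # survive QC and are not diluted by island averaging.
  n_missing <- round(cfg$frac_missing * n)
  flagged <- annotation$snp_flag | annotation$crossreactive_flag
  on_sex <- is_sex_chromosome(annotation$chromosome)
  in_island <- !is.na(annotation$island_name)
  clean <- which(!flagged & !on_sex & !in_island)

  missing_probes <- if (n_missing > 0) {
    sample(clean, min(n_missing, length(clean)))
  } else integer(0)
  eligible <- setdiff(clean, missing_probes)

  n_we <- round(cfg$frac_weight_effect * n)
  n_se <- round(cfg$frac_snp_effect * n)
  need <- n_we + n_se + 2L * cfg$n_shared_genes
  if (need > length(eligible)) {
    abort(sprintf(
      "Cannot place %d spiked probes on %d clean free-standing probes; lower the effect fractions or the flag/island fractions.",
      need, length(eligible)
    ))
  }
  picks <- sample(eligible, need)
  we_idx <- picks[seq_len(n_we)]
  se_idx <- picks[n_we + seq_len(n_se)]

  true_w <- true_s <- numeric(n)
  true_w[we_idx] <- cfg$effect_size_m * sample(c(-1, 1), n_we, replace = TRUE)
  true_s[se_idx] <- cfg$effect_size_m * sample(c(-1, 1), n_se, replace = TRUE)

  shared_genes <- character(0)
  if (cfg$n_shared_genes > 0) {
    sh <- picks[n_we + n_se + seq_len(2L * cfg$n_shared_genes)]
    for (g in seq_len(cfg$n_shared_genes)) {
      pw <- sh[2 * g - 1]
      ps <- sh[2 * g]
      gene <- sprintf("SHARED%03d", g)
      annotation$closest_tss_gene[c(pw, ps)] <- gene
      true_w[pw] <- -cfg$effect_size_m
      true_s[ps] <- -cfg$effect_size_m
      shared_genes <- c(shared_genes, gene)
    }
  }

  truth <- tibble::tibble(
    probe_id = probe_ids,
    true_weight_effect = true_w,
    true_snp_effect = true_s
  )

  # --- baseline methylation and effect injection --------------------------
  bm <- cfg$beta_mixture
  comp <- sample.int(3, n, replace = TRUE, prob = bm$weights / sum(bm$weights))
  beta0 <- rbeta(n, bm$shape1[comp], bm$shape2[comp])
  # background correction and scanner saturation keep reported beta-values
  # away from the exact 0/1 boundaries on real arrays
  beta0 <- pmin(pmax(beta0, 0.01), 0.99)
  m0 <- beta_to_m(beta0)

  noise <- matrix(rnorm(n * ns, sd = cfg$noise_sd_m), nrow = n)
  m <- m0 + outer(true_w, covariates$W) + outer(true_s, covariates$S) + noise
  beta <- m_to_beta(m)
  dimnames(beta) <- list(probe_ids, sample_ids)

  if (length(missing_probes) > 0) {
    miss_col <- sample.int(ns, length(missing_probes), replace = TRUE)
    beta[cbind(missing_probes, miss_col)] <- NA_real_
  }

  # --- detection p-values -------------------------------------------------
  fail <- matrix(
    runif(n * ns) < cfg$detection_fail_rate,
    nrow = n
  )
  detection_p <- matrix(runif(n * ns, 0, 1e-6), nrow = n)
  detection_p[fail] <- runif(sum(fail), 0.05, 1)
  dimnames(detection_p) <- dimnames(beta)

  cohort <- methylation_cohort(beta, detection_p, covariates)
  list(
    cohort = cohort,
    annotation = annotation,
    truth = truth,
    shared_genes = shared_genes
  )
}

# Covariates: G (sex, female=0/male=1), T (Tanner stage 1-5), B (white
# blood cell count, 10^9 cells/L), W (weight category, normal=0/obese=1),
# S (additive risk-allele dose, TT=0/TC=1/CC=2). Tanner stage is drawn
# from a latent normal correlated with the weight-category latent so the
# two covariates are mildly confounded.
simulate_covariates <- function(cfg, sample_ids) {
  ns <- cfg$n_samples
  z_w <- rnorm(ns)
  w <- as.integer(rank(z_w, ties.method = "first") > ns - cfg$n_obese)
  z_t <- cfg$confounding_rho * z_w +
    sqrt(1 - cfg$confounding_rho^2) * rnorm(ns)
  tanner <- as.integer(cut(z_t, breaks = qnorm(seq(0, 1, by = 0.2)),
                           include.lowest = TRUE, labels = FALSE))
  g <- integer(ns)
  g[sample.int(ns, cfg$n_male)] <- 1L
  b <- rlnorm(ns, meanlog = log(6.5), sdlog = 0.25)
  s <- rbinom(ns, 2, cfg$snp_allele_freq)
  tibble::tibble(
    sample_id = sample_ids,
    G = g, T = tanner, B = b, W = w, S = as.integer(s)
  )
}

# Annotation: probes are laid along synthetic chromosomes in index order.
# Autosomal probes form "units" -- islands (contiguous blocks of member
# probes) interleaved with free-standing probes -- and chromosome breaks
# fall only between units, so an island never straddles chromosomes.
# Sex-chromosome probes occupy the tail of the index range.
simulate_annotation <- function(cfg, probe_ids) {
  n <- cfg$n_probes
  n_sex <- round(cfg$frac_sex_chrom * n)
  n_auto <- n - n_sex
  n_mem <- round(cfg$frac_island_members * n)
  if (n_mem > n_auto) {
    abort("Invalid configuration: `frac_island_members` + `frac_sex_chrom` exceed the probe budget (islands are autosomal).")
  }
  n_isl <- if (n_mem == 0) 0L else min(cfg$n_islands, n_mem)

  # island sizes: at least 1 member each, remainder spread at random
  isl_sizes <- integer(0)
  if (n_isl > 0) {
    isl_sizes <- rep(1L, n_isl)
    extra <- n_mem - n_isl
    if (extra > 0) {
      add <- table(sample.int(n_isl, extra, replace = TRUE))
      isl_sizes[as.integer(names(add))] <- isl_sizes[as.integer(names(add))] + as.integer(add)
    }
  }

  # interleave islands with free probes: unit sequence over autosomal probes
  n_free <- n_auto - n_mem
  gap_sizes <- integer(n_isl + 1)
  if (n_free > 0 && n_isl > 0) {
    cuts <- table(sample.int(n_isl + 1, n_free, replace = TRUE))
    gap_sizes[as.integer(names(cuts))] <- as.integer(cuts)
  } else if (n_isl == 0) {
    gap_sizes <- n_free
  }

  unit_kind <- integer(0)   # 0 = free probe, island index otherwise
  for (i in seq_len(n_isl)) {
    unit_kind <- c(unit_kind, rep(0L, gap_sizes[i]), i)
  }
  unit_kind <- c(unit_kind, rep(0L, gap_sizes[n_isl + 1]))
  unit_sizes <- ifelse(unit_kind == 0, 1L, isl_sizes[pmax(unit_kind, 1L)])

  # chromosome assignment at unit granularity
  n_units <- length(unit_kind)
  n_chrom <- min(22L, max(1L, n_units))
  unit_chrom <- if (n_units > 0) {
    as.integer(cut(seq_len(n_units), breaks = n_chrom, labels = FALSE))
  } else integer(0)

  island_of <- integer(n_auto)
  chrom_of <- integer(n_auto)
  idx <- 1L
  for (u in seq_len(n_units)) {
    take <- unit_sizes[u]
    island_of[idx:(idx + take - 1L)] <- unit_kind[u]
    chrom_of[idx:(idx + take - 1L)] <- unit_chrom[u]
    idx <- idx + take
  }

  # positions: cumulative steps within chromosome; island members sit close
  position <- integer(n_auto)
  for (ch in unique(chrom_of)) {
    ii <- which(chrom_of == ch)
    in_isl <- island_of[ii] > 0
    same_as_prev <- c(FALSE, island_of[ii][-1] > 0 &
                        island_of[ii][-1] == island_of[ii][-length(ii)])
    step <- ifelse(same_as_prev, sample(50:500, length(ii), replace = TRUE),
                   sample(2000:50000, length(ii), replace = TRUE))
    position[ii] <- cumsum(step) + 10000L
  }

  chromosome <- character(n)
  chromosome[seq_len(n_auto)] <- paste0("chr", chrom_of)
  if (n_sex > 0) {
    n_y <- max(0L, round(n_sex / 3))
    chromosome[(n_auto + 1):n] <- c(rep("chrX", n_sex - n_y), rep("chrY", n_y))
  }
  sex_pos <- if (n_sex > 0) cumsum(sample(2000:50000, n_sex, replace = TRUE)) else integer(0)
  position_all <- c(position, sex_pos)

  # island classes and names (chr<k>_<class>:<start>-<end>)
  hil <- rep("nonisland", n)
  island_name <- rep(NA_character_, n)
  if (n_isl > 0) {
    isl_class <- sample(c("HC", "IC", "ICshore"), n_isl, replace = TRUE,
                        prob = c(0.45, 0.35, 0.20))
    for (i in seq_len(n_isl)) {
      ii <- which(island_of == i)
      nm <- sprintf("%s_%s:%d-%d", paste0("chr", chrom_of[ii[1]]),
                    isl_class[i], min(position[ii]), max(position[ii]))
      island_name[ii] <- nm
      hil[ii] <- isl_class[i]
    }
  }

  # genes in runs of 1-4 consecutive probes
  gene_run <- sample(1:4, n, replace = TRUE)
  gene_idx <- rep(seq_along(gene_run), gene_run)[seq_len(n)]
  gene <- sprintf("GENE%05d", gene_idx)
  dist_tss <- sample(-2000:2000, n, replace = TRUE)

  # QC flags: SNP and cross-reactive, disjoint from each other and from
  # the sex chromosomes so per-rule removal counts are additive
  n_snp <- round(cfg$frac_snp_probes * n)
  n_cross <- round(cfg$frac_crossreactive * n)
  if (n_snp + n_cross > n_auto) {
    abort("Invalid configuration: `frac_snp_probes` + `frac_crossreactive` exceed the autosomal probe budget.")
  }
  flag_pool <- sample.int(n_auto, n_snp + n_cross)
  snp_flag <- logical(n)
  crossreactive_flag <- logical(n)
  snp_flag[flag_pool[seq_len(n_snp)]] <- TRUE
  crossreactive_flag[flag_pool[n_snp + seq_len(n_cross)]] <- TRUE

  tibble::tibble(
    probe_id = probe_ids,
    chromosome = chromosome,
    position = as.integer(position_all),
    island_name = island_name,
    hil_class = hil,
    closest_tss_gene = gene,
    distance_to_tss = as.integer(dist_tss),
    snp_flag = snp_flag,
    crossreactive_flag = crossreactive_flag
  )
}

#' Write a simulated cohort as the pipeline's TSV input set
#'
#' Emits `beta.tsv`, `detection_p.tsv`, `annotation.tsv` and
#' `covariates.tsv` in the exact dialects read by [read_beta_matrix()],
#' [read_annotation()] and [read_covariates()]; writing then reading
#' round-trips the cohort within float formatting precision.
#'
#' @param cohort A [methylation_cohort()].
#' @param annotation Probe annotation tibble.
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named character vector of the four file paths.
#' @export
write_fixture <- function(cohort, annotation, dir) {
  stopifnot(inherits(cohort, "methylation_cohort"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("Cannot create output directory '%s'.", dir))
  }
  paths <- c(
    beta = file.path(dir, "beta.tsv"),
    detection_p = file.path(dir, "detection_p.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    covariates = file.path(dir, "covariates.tsv")
  )
  write_matrix_tsv(cohort$beta, paths["beta"])
  write_matrix_tsv(cohort$detection_p, paths["detection_p"])
  readr::write_tsv(annotation, paths["annotation"], progress = FALSE)
  readr::write_tsv(cohort$covariates, paths["covariates"], progress = FALSE)
  invisible(paths)
}

write_matrix_tsv <- function(mat, path) {
  df <- tibble::as_tibble(mat, rownames = "probe_id")
  readr::write_tsv(df, path, progress = FALSE)
}
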