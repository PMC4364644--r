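#' Pipeline configuration
#'
#' Collects paths, thresholds and model settings for [run_pipeline()].
#' Either the four input paths or an in-memory cohort + annotation must be
#' supplied.
#'
#' @param beta_path,detection_path,annotation_path,covariates_path Input
#'   TSVs in the dialects of [read_beta_matrix()], [read_annotation()] and
#'   [read_covariates()]. Ignored when `cohort` is given.
#' @param cohort Optional in-memory [methylation_cohort()].
#' @param annotation Optional in-memory annotation tibble.
#' @param thresholds A [qc_thresholds()] object.
#' @param spec_weight,spec_genotype [model_spec()] objects for the
#'   weight-category and genotype-dose models.
#' @param k Top-table size. Default 15.
#' @param out_dir Output directory for the result bundle.
#' @param seed Integer seed echoed into the run manifest (the analysis
#'   itself is deterministic; the seed pins any simulated input).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(beta_path = NULL, detection_path = NULL,
                            annotation_path = NULL, covariates_path = NULL,
                            cohort = NULL, annotation = NULL,
                            thresholds = qc_thresholds(),
                            spec_weight = model_spec("W"),
                            spec_genotype = model_spec("S"),
                            k = 15,
                            out_dir = NULL,
                            seed = NULL) {
  if (is.null(cohort) &&
      (is.null(beta_path) || is.null(detection_path) ||
       is.null(covariates_path))) {
    abort("Provide either `cohort` or the beta/detection/covariates paths.")
  }
  if (is.null(annotation) && is.null(annotation_path)) {
    abort("Provide either `annotation` or `annotation_path`.")
  }
  if (is.null(out_dir)) abort("`out_dir` is required.")
  if (is.null(seed)) abort("`seed` is required (no silent clock seeding).")
  if (k < 1) abort("`k` must be at least 1.")
  structure(
    list(
      beta_path = beta_path, detection_path = detection_path,
      annotation_path = annotation_path, covariates_path = covariates_path,
      cohort = cohort, annotation = annotation,
      thresholds = thresholds,
      spec_weight = spec_weight, spec_genotype = spec_genotype,
      k = k, out_dir = out_dir, seed = seed
    ),
    class = "pipeline_config"
  )
}

#' Run the full discovery pipeline
#'
#' Executes QC -> beta-to-M -> quantile normalization -> island collapsing
#' -> the two per-location models (weight contrast; genotype contrast) ->
#' top-k ranking -> gene-level intersection, and writes the result bundle
#' to `out_dir`: `qc_report.tsv`, `fit_model1.tsv`, `fit_model2.tsv`,
#' `top15_model1.tsv`, `top15_model2.tsv`, `intersection.tsv` and
#' `run_manifest.json` (configuration echo, seed, per-stage row counts,
#' convergence flags). On a stage error, partial outputs are kept and a
#' `FAILED` marker file records the message before the error propagates.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `qc`, `locations`, `fit_weight`,
#'   `fit_genotype`, `top_weight`, `top_genotype`, `intersection`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  run <- function() {
    cohort <- config$cohort %||% read_cohort(
      config$beta_path, config$detection_path, config$covariates_path
    )
    annotation <- config$annotation %||% read_annotation(config$annotation_path)

    inform(sprintf("Input: %d probes x %d samples",
                   nrow(cohort$beta), ncol(cohort$beta)))
    qc <- qc_filter(cohort, annotation, config$thresholds)
    for (i in seq_len(nrow(qc$report$rules))) {
      r <- qc$report$rules[i, ]
      inform(sprintf("QC %-28s removed %d %s(s)",
                     r$rule, r$n_removed, r$entity_type))
    }
    write_qc_report(qc$report, file.path(config$out_dir, "qc_report.tsv"))

    m <- quantile_normalize(beta_to_m(qc$cohort$beta))
    coll <- collapse_islands(m, annotation)
    inform(sprintf("Collapsed %d probes to %d interrogated locations",
                   nrow(m), nrow(coll$m)))

    fit_w <- diff_methylation(coll$m, qc$cohort$covariates, config$spec_weight)
    fit_s <- diff_methylation(coll$m, qc$cohort$covariates, config$spec_genotype)
    readr::write_tsv(tidy(fit_w), file.path(config$out_dir, "fit_model1.tsv"),
                     progress = FALSE)
    readr::write_tsv(tidy(fit_s), file.path(config$out_dir, "fit_model2.tsv"),
                     progress = FALSE)

    top_w <- rank_top(fit_w, coll$locations, k = config$k)
    top_s <- rank_top(fit_s, coll$locations, k = config$k)
    readr::write_tsv(top_w, file.path(config$out_dir, "top15_model1.tsv"),
                     progress = FALSE)
    readr::write_tsv(top_s, file.path(config$out_dir, "top15_model2.tsv"),
                     progress = FALSE)

    inter <- cross_model_intersect(top_w, top_s)
    readr::write_tsv(tibble::as_tibble(inter),
                     file.path(config$out_dir, "intersection.tsv"),
                     progress = FALSE)

    manifest <- list(
      seed = config$seed,
      k = config$k,
      thresholds = unclass(config$thresholds),
      model_weight = unclass(config$spec_weight),
      model_genotype = unclass(config$spec_genotype),
      counts = c(
        qc$report$totals,
        list(
          locations = nrow(coll$m),
          islands = sum(coll$locations$kind == "island"),
          free_sites = sum(coll$locations$kind == "site"),
          intersection_pairs = nrow(inter)
        )
      ),
      converged = list(
        model_weight = sum(tidy(fit_w)$converged),
        model_genotype = sum(tidy(fit_s)$converged)
      ),
      prior = list(
        model_weight = fit_w$prior,
        model_genotype = fit_s$prior
      )
    )
    jsonlite::write_json(manifest, file.path(config$out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
    list(
      qc = qc, locations = coll$locations,
      fit_weight = fit_w, fit_genotype = fit_s,
      top_weight = top_w, top_genotype = top_s,
      intersection = inter, manifest = manifest
    )
  }

  res <- tryCatch(run(), error = function(e) {
    writeLines(conditionMessage(e), file.path(config$out_dir, "FAILED"))
    abort(sprintf("Pipeline failed: %s", conditionMessage(e)), parent = e)
  })
  invisible(res)
}
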