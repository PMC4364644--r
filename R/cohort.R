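#' Methylation cohort container
#'
#' Bundles the probe-by-sample beta-value matrix, the matching detection
#' p-value matrix and the per-sample covariate table. Both matrices must
#' share dimensions and dimnames, and every sample must appear in the
#' covariate table.
#'
#' @param beta Numeric matrix of beta-values in `[0, 1]` (probes x samples),
#'   `NA` allowed; rownames are probe IDs, colnames sample IDs.
#' @param detection_p Numeric matrix of detection p-values, same shape and
#'   dimnames as `beta`.
#' @param covariates Tibble with a `sample_id` column plus the model
#'   covariates `G` (sex, female=0/male=1), `T` (Tanner stage 1-5),
#'   `B` (white-blood-cell count), `W` (weight category,
#'   normal-weight=0/obese=1) and optionally `S` (risk-allele dose,
#'   TT=0/TC=1/CC=2).
#' @return A `methylation_cohort` object.
#' @export
methylation_cohort <- function(beta, detection_p, covariates) {
  if (!is.matrix(beta) || !is.matrix(detection_p)) {
    abort("`beta` and `detection_p` must be matrices (probes x samples).")
  }
  if (!identical(dim(beta), dim(detection_p)) ||
      !identical(dimnames(beta), dimnames(detection_p))) {
    abort("`beta` and `detection_p` must share shape and dimnames.")
  }
  if ((nrow(beta) > 0 && is.null(rownames(beta))) ||
      (ncol(beta) > 0 && is.null(colnames(beta)))) {
    abort("`beta` needs probe IDs as rownames and sample IDs as colnames.")
  }
  if (!"sample_id" %in% names(covariates)) {
    abort("`covariates` must have a `sample_id` column.")
  }
  missing_cov <- setdiff(colnames(beta), covariates$sample_id)
  if (length(missing_cov) > 0) {
    abort(sprintf(
      "Samples absent from `covariates`: %s.",
      paste(utils::head(missing_cov, 5), collapse = ", ")
    ))
  }
  bad <- !is.na(beta) & (beta < 0 | beta > 1)
  if (any(bad)) abort("`beta` values must lie in [0, 1].")
  structure(
    list(
      beta = beta,
      detection_p = detection_p,
      covariates = tibble::as_tibble(covariates)
    ),
    class = "methylation_cohort"
  )
}

#' @export
print.methylation_cohort <- function(x, ...) {
  cat(sprintf(
    "<methylation_cohort> %d probes x %d samples (%d beta cells missing)\n",
    nrow(x$beta), ncol(x$beta), sum(is.na(x$beta))
  ))
  cat("covariates:", paste(setdiff(names(x$covariates), "sample_id"),
                           collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.methylation_cohort <- function(x) dim(x$beta)

#' Tidy a methylation cohort into long format
#'
#' @param x A [methylation_cohort()].
#' @param ... Unused.
#' @return Tibble with one row per probe-sample cell: `probe_id`,
#'   `sample_id`, `beta`, `detection_p`.
#' @method tidy methylation_cohort
#' @export
tidy.methylation_cohort <- function(x, ...) {
  long <- tibble::as_tibble(x$beta, rownames = "probe_id") |>
    tidyr::pivot_longer(-"probe_id", names_to = "sample_id", values_to = "beta")
  long$detection_p <- as.vector(t(x$detection_p))
  long
}

#' Density of beta-values per sample
#'
#' The classic array-QC view: one beta-value density curve per sample.
#' Bimodality (peaks near 0 and 1) is the expected signature of Infinium
#' data; deviating samples stand out.
#'
#' @param object A [methylation_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot methylation_cohort
#' @export
autoplot.methylation_cohort <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long[!is.na(long$beta), ],
                  ggplot2::aes(x = .data$beta, group = .data$sample_id)) +
    ggplot2::geom_density(alpha = 0.3, linewidth = 0.3, colour = "grey30") +
    ggplot2::labs(x = expression(beta ~ value), y = "Density",
                  title = "Per-sample beta-value distributions") +
    ggplot2::theme_minimal()
}

#' Validate a probe annotation manifest
#'
#' Checks the columns and invariants the pipeline relies on: required
#' fields present, island names parseable with members sharing a
#' chromosome, and coverage of a supplied probe set. A missing `hil_class`
#' is accepted and treated as `"nonisland"`.
#'
#' @param annotation Tibble with columns `probe_id`, `chromosome`,
#'   `position`, `island_name` (NA for free-standing probes), `hil_class`,
#'   `closest_tss_gene`, `distance_to_tss`, `snp_flag`,
#'   `crossreactive_flag`.
#' @param probe_ids Optional character vector that must be covered.
#' @return The annotation, invisibly, with `hil_class` NAs filled.
#' @export
validate_annotation <- function(annotation, probe_ids = NULL) {
  req <- c(
    "probe_id", "chromosome", "position", "island_name", "hil_class",
    "closest_tss_gene", "distance_to_tss", "snp_flag", "crossreactive_flag"
  )
  miss <- setdiff(req, names(annotation))
  if (length(miss) > 0) {
    abort(sprintf("Annotation is missing column(s): %s.",
                  paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(annotation$probe_id)) {
    abort("Annotation has duplicated probe IDs.")
  }
  if (!is.null(probe_ids)) {
    uncovered <- setdiff(probe_ids, annotation$probe_id)
    if (length(uncovered) > 0) {
      abort(sprintf(
        "Annotation does not cover %d probe(s) (first: %s).",
        length(uncovered), uncovered[1]
      ))
    }
  }
  annotation$hil_class[is.na(annotation$hil_class)] <- "nonisland"
  with_island <- annotation[!is.na(annotation$island_name), ]
  if (nrow(with_island) > 0) {
    n_chrom <- tapply(with_island$chromosome, with_island$island_name,
                      function(x) length(unique(x)))
    if (any(n_chrom > 1)) {
      abort(sprintf(
        "Island '%s' spans multiple chromosomes.",
        names(n_chrom)[n_chrom > 1][1]
      ))
    }
  }
  invisible(annotation)
}

is_sex_chromosome <- function(chromosome) {
  toupper(sub("^chr", "", chromosome, ignore.case = TRUE)) %in% c("X", "Y")
}
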