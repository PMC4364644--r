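#' QC thresholds and switches
#'
#' Default thresholds mirror standard Infinium practice: probes are judged
#' against a detection p-value of 0.05 and samples against 1e-5, and both
#' must have at least 75% of their cells below 1e-5.
#'
#' @param site_detection_p Threshold for the probe-level aggregated
#'   detection p-value rule. Default 0.05.
#' @param sample_detection_p Threshold for the sample-level aggregated
#'   detection p-value rule. Default 1e-5.
#' @param detection_fraction Minimum fraction of cells that must fall below
#'   `fraction_p` for a probe/sample to survive. Default 0.75.
#' @param fraction_p Inner threshold for the fraction rules. Default 1e-5.
#' @param aggregation How a probe's (or sample's) detection p-values are
#'   collapsed to a scalar for the threshold rules: `"mean"` (default),
#'   `"max"`, or `"any"` (any cell above the threshold fails; equivalent to
#'   `"max"`).
#' @param order `"samples_first"` (default) runs the sample rules before
#'   the probe rules, so failing samples cannot drag down probe statistics;
#'   `"probes_first"` reverses this.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(site_detection_p = 0.05,
                          sample_detection_p = 1e-5,
                          detection_fraction = 0.75,
                          fraction_p = 1e-5,
                          aggregation = c("mean", "max", "any"),
                          order = c("samples_first", "probes_first")) {
  aggregation <- match.arg(aggregation)
  order <- match.arg(order)
  for (fld in c("site_detection_p", "sample_detection_p", "fraction_p")) {
    x <- get(fld)
    if (!is.numeric(x) || x <= 0 || x >= 1) {
      abort(sprintf("`%s` must lie in (0, 1).", fld))
    }
  }
  if (detection_fraction <= 0 || detection_fraction > 1) {
    abort("`detection_fraction` must lie in (0, 1].")
  }
  structure(
    list(
      site_detection_p = site_detection_p,
      sample_detection_p = sample_detection_p,
      detection_fraction = detection_fraction,
      fraction_p = fraction_p,
      aggregation = aggregation,
      order = order
    ),
    class = "qc_thresholds"
  )
}

aggregate_detection <- function(p, margin, how) {
  f <- switch(how, mean = mean, max = max, any = max)
  apply(p, margin, function(x) f(x, na.rm = TRUE))
}

#' Quality-control filtering of a methylation cohort
#'
#' Applies the seven-rule QC cascade plus sex-chromosome removal. With the
#' default `samples_first` order the rules run as: (1) sample rules on the
#' full matrix — any missing beta-value, aggregated detection p above
#' `sample_detection_p`, fewer than `detection_fraction` of sites at
#' detection p below `fraction_p`; (2) probe rules on the surviving
#' samples — any missing beta-value, aggregated detection p above
#' `site_detection_p`, fewer than `detection_fraction` of samples at
#' detection p below `fraction_p`, SNP-flagged probes, cross-reactive
#' probes; (3) probes on chrX/chrY, counted separately from the QC
#' removals. Each entity is attributed to the first rule that removes it,
#' so per-rule ID lists are disjoint and counts are additive.
#'
#' @param cohort A [methylation_cohort()].
#' @param annotation Probe annotation covering all probes
#'   (see [validate_annotation()]).
#' @param thresholds A [qc_thresholds()] object.
#' @return A list with `cohort` (the filtered [methylation_cohort()]) and
#'   `report` (a `qc_report`; see [tidy.qc_report()]).
#' @examples
#' sim <- simulate_cohort(sim_config(n_probes = 300, n_samples = 12, seed = 4))
#' res <- qc_filter(sim$cohort, sim$annotation)
#' res$report
#' @export
qc_filter <- function(cohort, annotation, thresholds = qc_thresholds()) {
  stopifnot(inherits(cohort, "methylation_cohort"))
  annotation <- validate_annotation(annotation, rownames(cohort$beta))
  th <- thresholds

  beta <- cohort$beta
  detp <- cohort$detection_p
  rules <- list()

  run_sample_rules <- function() {
    removed <- character(0)
    take <- function(rule, ids) {
      ids <- setdiff(ids, removed)
      rules[[length(rules) + 1]] <<- tibble::tibble(
        rule = rule, entity_type = "sample", n_removed = length(ids),
        ids = list(ids)
      )
      removed <<- c(removed, ids)
    }
    samp <- colnames(beta)
    take("sample_missing_beta", samp[colSums(is.na(beta)) > 0])
    agg <- aggregate_detection(detp, 2, th$aggregation)
    take("sample_detection_p", samp[agg > th$sample_detection_p])
    frac <- colMeans(detp < th$fraction_p, na.rm = TRUE)
    take("sample_detection_fraction", samp[frac < th$detection_fraction])
    keep <- setdiff(samp, removed)
    if (length(keep) == 0) abort("Empty after QC: all samples removed.")
    beta <<- beta[, keep, drop = FALSE]
    detp <<- detp[, keep, drop = FALSE]
  }

  run_probe_rules <- function() {
    removed <- character(0)
    take <- function(rule, ids) {
      ids <- setdiff(ids, removed)
      rules[[length(rules) + 1]] <<- tibble::tibble(
        rule = rule, entity_type = "probe", n_removed = length(ids),
        ids = list(ids)
      )
      removed <<- c(removed, ids)
    }
    pr <- rownames(beta)
    take("probe_missing_beta", pr[rowSums(is.na(beta)) > 0])
    agg <- aggregate_detection(detp, 1, th$aggregation)
    take("probe_detection_p", pr[agg > th$site_detection_p])
    frac <- rowMeans(detp < th$fraction_p, na.rm = TRUE)
    take("probe_detection_fraction", pr[frac < th$detection_fraction])
    ann <- annotation[match(pr, annotation$probe_id), ]
    take("probe_snp", pr[ann$snp_flag])
    take("probe_crossreactive", pr[ann$crossreactive_flag])
    keep <- setdiff(pr, removed)
    if (length(keep) == 0) abort("Empty after QC: all probes removed.")
    beta <<- beta[keep, , drop = FALSE]
    detp <<- detp[keep, , drop = FALSE]
  }

  probes_in <- nrow(beta)
  samples_in <- ncol(beta)
  if (th$order == "samples_first") {
    run_sample_rules()
    run_probe_rules()
  } else {
    run_probe_rules()
    run_sample_rules()
  }

  # sex-chromosome probes, counted apart from the QC rules
  pr <- rownames(beta)
  ann <- annotation[match(pr, annotation$probe_id), ]
  sex_ids <- pr[is_sex_chromosome(ann$chromosome)]
  rules[[length(rules) + 1]] <- tibble::tibble(
    rule = "probe_sex_chromosome", entity_type = "probe",
    n_removed = length(sex_ids), ids = list(sex_ids)
  )
  keep <- setdiff(pr, sex_ids)
  if (length(keep) == 0) abort("Empty after QC: all probes removed.")
  beta <- beta[keep, , drop = FALSE]
  detp <- detp[keep, , drop = FALSE]

  report_tbl <- dplyr::bind_rows(rules)
  qc_rules <- report_tbl$entity_type == "probe" &
    report_tbl$rule != "probe_sex_chromosome"
  report <- structure(
    list(
      rules = report_tbl,
      totals = list(
        probes_in = probes_in,
        samples_in = samples_in,
        probes_removed_qc = sum(report_tbl$n_removed[qc_rules]),
        probes_removed_sex = length(sex_ids),
        probes_retained = nrow(beta),
        samples_removed = sum(report_tbl$n_removed[report_tbl$entity_type == "sample"]),
        samples_retained = ncol(beta)
      ),
      order = th$order
    ),
    class = "qc_report"
  )

  covariates <- cohort$covariates[
    cohort$covariates$sample_id %in% colnames(beta), , drop = FALSE
  ]
  list(
    cohort = methylation_cohort(beta, detp, covariates),
    report = report
  )
}

#' @export
print.qc_report <- function(x, ...) {
  t <- x$totals
  cat(sprintf(
    "<qc_report> %d -> %d probes (%d QC, %d sex-chromosome); %d -> %d samples\n",
    t$probes_in, t$probes_retained, t$probes_removed_qc,
    t$probes_removed_sex, t$samples_in, t$samples_retained
  ))
  tbl <- x$rules
  for (i in seq_len(nrow(tbl))) {
    cat(sprintf("  %-28s %-7s removed %d\n",
                tbl$rule[i], tbl$entity_type[i], tbl$n_removed[i]))
  }
  invisible(x)
}

#' Tidy a QC report
#'
#' @param x A `qc_report` from [qc_filter()].
#' @param ... Unused.
#' @return Tibble with columns `rule`, `entity_type`, `n_removed`, `ids`
#'   (list-column of removed IDs), in application order.
#' @method tidy qc_report
#' @export
tidy.qc_report <- function(x, ...) x$rules

#' One-row summary of a QC report
#'
#' @param x A `qc_report`.
#' @param ... Unused.
#' @return One-row tibble with the removal totals.
#' @method glance qc_report
#' @export
glance.qc_report <- function(x, ...) tibble::as_tibble(x$totals)

#' Bar chart of per-rule QC removals
#'
#' @param object A `qc_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qc_report
#' @export
autoplot.qc_report <- function(object, ...) {
  tbl <- object$rules
  tbl$rule <- factor(tbl$rule, levels = rev(tbl$rule))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$n_removed, y = .data$rule,
                                    fill = .data$entity_type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Entities removed", y = NULL, fill = NULL,
                  title = "QC removals by rule (application order, top first)") +
    ggplot2::theme_minimal()
}

#' Write a QC report as TSV
#'
#' Machine-readable per-rule counts (`rule`, `entity_type`, `n_removed`,
#' semicolon-joined `ids`).
#'
#' @param report A `qc_report`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_qc_report <- function(report, path) {
  tbl <- report$rules
  tbl$ids <- vapply(tbl$ids, paste, collapse = ";", FUN.VALUE = character(1))
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}
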