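#' Read a probe-by-sample matrix from TSV
#'
#' Series-matrix-like layout: a header row of sample IDs, probe IDs in the
#' first column, tab-separated numeric values; empty cells become missing.
#' Duplicate probe IDs and ragged rows are rejected.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix with probe rownames and sample colnames.
#' @export
read_beta_matrix <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: '%s'.", path))
  hdr <- names(readr::read_tsv(path, n_max = 0, col_types = readr::cols(),
                               progress = FALSE, show_col_types = FALSE))
  spec <- do.call(readr::cols, c(
    setNames(list(readr::col_character()), hdr[1]),
    list(.default = readr::col_double())
  ))
  df <- suppressWarnings(
    readr::read_tsv(path, col_types = spec, progress = FALSE,
                    show_col_types = FALSE)
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(sprintf("Parse error in '%s' at line %d: expected %s, got '%s'.",
                  path, probs$row[1], probs$expected[1], probs$actual[1]))
  }
  ids <- df[[1]]
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(sprintf("Duplicated probe ID(s) in '%s': %s.",
                  path, paste(unique(utils::head(dup, 5)), collapse = ", ")))
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- ids
  mat
}

#' @rdname read_beta_matrix
#' @export
read_detection_matrix <- read_beta_matrix

#' Read a probe annotation manifest from TSV
#'
#' Expected columns: `probe_id`, `chromosome`, `position`, `island_name`,
#' `hil_class`, `closest_tss_gene`, `distance_to_tss`, `snp_flag`,
#' `crossreactive_flag`. Missing `hil_class` values are accepted and
#' treated as non-island.
#'
#' @param path Path to the TSV file.
#' @return Validated annotation tibble.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: '%s'.", path))
  df <- readr::read_tsv(path, col_types = readr::cols(
    probe_id = readr::col_character(),
    chromosome = readr::col_character(),
    position = readr::col_integer(),
    island_name = readr::col_character(),
    hil_class = readr::col_character(),
    closest_tss_gene = readr::col_character(),
    distance_to_tss = readr::col_integer(),
    snp_flag = readr::col_logical(),
    crossreactive_flag = readr::col_logical()
  ), progress = FALSE, show_col_types = FALSE)
  ann <- validate_annotation(df)
  ann
}

#' Read a sample covariate table from TSV
#'
#' Expected columns: `sample_id`, `G` (sex, female=0/male=1), `T` (Tanner
#' stage), `B` (white-blood-cell count), `W` (weight category,
#' normal-weight=0/obese=1) and optionally `S` (risk-allele dose 0/1/2).
#'
#' @param path Path to the TSV file.
#' @return Covariate tibble.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: '%s'.", path))
  df <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE, show_col_types = FALSE)
  if (!"sample_id" %in% names(df)) {
    abort(sprintf("'%s' lacks a `sample_id` column.", path))
  }
  df
}

#' Read a full cohort from the four TSV inputs
#'
#' @param beta_path,detection_path,covariates_path Paths to the matrix and
#'   covariate TSVs (dialects of [read_beta_matrix()] /
#'   [read_covariates()]).
#' @return A [methylation_cohort()].
#' @export
read_cohort <- function(beta_path, detection_path, covariates_path) {
  methylation_cohort(
    beta = read_beta_matrix(beta_path),
    detection_p = read_detection_matrix(detection_path),
    covariates = read_covariates(covariates_path)
  )
}

#' Bundled published top-15 result tables
#'
#' Two small TSVs shipped with the package: the top-15 differentially
#' methylated locations for the weight-category model and for the
#' rs4929949 genotype-dose model from a published childhood-obesity
#' whole-blood EWAS, with gene symbol, Entrez-style ID, location string,
#' HIL class, closest-TSS position, contrast coefficient and raw/adjusted
#' p-values. They serve as a worked input for the gene-level intersection:
#' feeding them to [cross_model_intersect()] nominates CORO7 with
#' negative coefficients in both models.
#'
#' @return A list with tibbles `weight` and `genotype`, each carrying the
#'   `ranked_table` class.
#' @examples
#' tabs <- published_top_tables()
#' cross_model_intersect(tabs$weight, tabs$genotype)
#' @export
published_top_tables <- function() {
  read_one <- function(f, contrast) {
    path <- system.file("extdata", f, package = "methduet", mustWork = TRUE)
    df <- readr::read_tsv(path, col_types = readr::cols(
      gene = readr::col_character(),
      gene_id = readr::col_character(),
      location_id = readr::col_character(),
      hil_class = readr::col_character(),
      closest_tss_position = readr::col_integer(),
      coefficient = readr::col_double(),
      p_value = readr::col_double(),
      p_adjusted = readr::col_double()
    ), progress = FALSE, show_col_types = FALSE)
    structure(df, class = c("ranked_table", class(df)),
              contrast = contrast, k = nrow(df))
  }
  list(
    weight = read_one("top15_weight_published.tsv", "W"),
    genotype = read_one("top15_genotype_published.tsv", "S")
  )
}
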