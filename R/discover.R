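#' Candidate gene tokens of a symbol
#'
#' Readthrough and fusion-style symbols such as `"CORO7-PAM16"` denote a
#' locus overlapping several genes; annotation manifests are inconsistent
#' about which form they print. The token set of a symbol is the full
#' symbol plus its `"-"`-separated components, and two symbols match when
#' their token sets intersect — so `"CORO7-PAM16"` matches `"CORO7"`.
#'
#' @param symbol Character vector of gene symbols.
#' @return A list of character token vectors, one per symbol.
#' @examples
#' gene_tokens("CORO7-PAM16")
#' @export
gene_tokens <- function(symbol) {
  if (any(is.na(symbol) | !nzchar(symbol))) {
    abort("Gene symbols must be non-empty strings.")
  }
  lapply(symbol, function(s) unique(c(s, strsplit(s, "-", fixed = TRUE)[[1]])))
}

#' Intersect two models' top-ranked tables at the gene level
#'
#' The discovery rule: a gene is nominated when a top-ranked location in
#' each of the two models maps to it. Matching is token-based by default
#' (see [gene_tokens()]); locations are matched only through genes, never
#' through coordinate overlap — two distinct CpG sites of one gene count.
#' For every shared gene the matching rows of both tables are reported
#' together with `direction_consistent`, which is `TRUE` when the two
#' contrast coefficients share a sign (e.g. both hypomethylated with
#' rising obesity risk).
#'
#' @param a,b `ranked_table` objects from [rank_top()] (or tibbles with
#'   `gene` and `coefficient` columns). Rows with missing genes are
#'   excluded.
#' @param match `"tokens"` (default) or `"exact"` symbol matching.
#' @return A `meth_intersection` tibble: `gene` (the shared token(s)),
#'   `location_a`, `coefficient_a`, `gene_a`, `location_b`,
#'   `coefficient_b`, `gene_b`, `direction_consistent`.
#' @examples
#' a <- tibble::tibble(location_id = "chr16:4466649",
#'                     gene = "CORO7-PAM16", coefficient = -0.137)
#' b <- tibble::tibble(location_id = "chr16:4465731",
#'                     gene = "CORO7", coefficient = -0.144)
#' cross_model_intersect(a, b)
#' @export
cross_model_intersect <- function(a, b, match = c("tokens", "exact")) {
  match <- match.arg(match)
  for (nm in c("gene", "coefficient")) {
    if (!nm %in% names(a) || !nm %in% names(b)) {
      abort(sprintf("Both tables need a `%s` column.", nm))
    }
  }
  a <- a[!is.na(a$gene) & nzchar(a$gene), , drop = FALSE]
  b <- b[!is.na(b$gene) & nzchar(b$gene), , drop = FALSE]

  empty <- tibble::tibble(
    gene = character(0),
    location_a = character(0), coefficient_a = numeric(0), gene_a = character(0),
    location_b = character(0), coefficient_b = numeric(0), gene_b = character(0),
    direction_consistent = logical(0)
  )
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(structure(empty, class = c("meth_intersection", class(empty))))
  }

  tok_a <- if (match == "tokens") gene_tokens(a$gene) else as.list(a$gene)
  tok_b <- if (match == "tokens") gene_tokens(b$gene) else as.list(b$gene)

  rows <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      shared <- intersect(tok_a[[i]], tok_b[[j]])
      if (length(shared) > 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          gene = paste(sort(shared), collapse = ";"),
          location_a = a$location_id[i],
          coefficient_a = a$coefficient[i],
          gene_a = a$gene[i],
          location_b = b$location_id[j],
          coefficient_b = b$coefficient[j],
          gene_b = b$gene[j],
          direction_consistent =
            sign(a$coefficient[i]) == sign(b$coefficient[j])
        )
      }
    }
  }
  out <- if (length(rows) > 0) dplyr::bind_rows(rows) else empty
  structure(out, class = c("meth_intersection", class(out)))
}

#' @export
print.meth_intersection <- function(x, ...) {
  cat(sprintf("<meth_intersection> %d shared gene pair(s)\n", nrow(x)))
  if (nrow(x) > 0) print(tibble::as_tibble(x))
  invisible(x)
}

#' Tidy an intersection result
#'
#' @param x A `meth_intersection`.
#' @param ... Unused.
#' @return The underlying tibble.
#' @method tidy meth_intersection
#' @export
tidy.meth_intersection <- function(x, ...) tibble::as_tibble(x)

#' One-row summary of an intersection result
#'
#' @param x A `meth_intersection`.
#' @param ... Unused.
#' @return One-row tibble with the number of shared genes and how many are
#'   direction-consistent.
#' @method glance meth_intersection
#' @export
glance.meth_intersection <- function(x, ...) {
  tibble::tibble(
    n_shared = length(unique(x$gene)),
    n_pairs = nrow(x),
    n_direction_consistent = sum(x$direction_consistent)
  )
}
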