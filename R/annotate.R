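#' Parse a CpG island name
#'
#' Island names encode chromosome, CpG-density class and inclusive 1-based
#' span, e.g. `"chr19_IC:17905037-17906698"` is an intermediate-density
#' island on chromosome 19 between positions 17905037 and 17906698.
#' Compound names (several spans joined by `";"`) are parsed from their
#' first span; en dashes are tolerated as span separators. Site-style
#' strings without a class token (`"chr2:113521873"`) are rejected — those
#' denote free-standing CpG sites, not islands.
#'
#' @param name Character vector of island names.
#' @return Tibble with one row per name: `island_name`, `chromosome`,
#'   `class_token`, `start`, `end`.
#' @examples
#' parse_island_name("chr19_IC:17905037-17906698")
#' @export
parse_island_name <- function(name) {
  if (length(name) == 0 || any(is.na(name)) || any(!nzchar(name))) {
    abort("Island names must be non-empty strings.")
  }
  first_span <- vapply(strsplit(name, ";", fixed = TRUE),
                       function(x) trimws(x[[1]]), character(1))
  canon <- gsub("–", "-", first_span)   # en dash -> hyphen
  pat <- "^(chr[0-9XYxy]+)_([A-Za-z]+):([0-9]+)-([0-9]+)$"
  ok <- grepl(pat, canon)
  if (any(!ok)) {
    abort(sprintf("Malformed island name: '%s'.", name[!ok][1]),
          class = "methduet_parse_error")
  }
  start <- as.integer(sub(pat, "\\3", canon))
  end <- as.integer(sub(pat, "\\4", canon))
  if (any(start > end)) {
    abort(sprintf("Malformed island name (start > end): '%s'.",
                  name[start > end][1]),
          class = "methduet_parse_error")
  }
  tibble::tibble(
    island_name = name,
    chromosome = sub(pat, "\\1", canon),
    class_token = sub(pat, "\\2", canon),
    start = start,
    end = end
  )
}

#' Assign a gene symbol to a set of member probes
#'
#' The gene of a location is the closest-TSS gene of the member probe with
#' the smallest absolute TSS distance; ties break to the lexicographically
#' smallest probe ID. Empty or missing gene fields yield the sentinel
#' `NA`, which excludes the location from gene-level intersection.
#'
#' @param members Annotation tibble rows (columns `probe_id`,
#'   `closest_tss_gene`, `distance_to_tss`).
#' @return A list with `gene` and `distance_to_tss` of the winning member.
#' @export
assign_gene <- function(members) {
  if (nrow(members) == 0) return(list(gene = NA_character_, distance_to_tss = NA_integer_))
  ord <- order(abs(members$distance_to_tss), members$probe_id)
  win <- members[ord[1], ]
  gene <- win$closest_tss_gene
  if (is.na(gene) || !nzchar(gene)) gene <- NA_character_
  list(gene = gene, distance_to_tss = win$distance_to_tss)
}

#' Collapse island-member probes into interrogated locations
#'
#' Probes sharing an island name (keyed on the full verbatim string) are
#' replaced by a single location whose per-sample M-value is the
#' arithmetic mean of the member probes; free-standing probes pass through
#' unchanged. For S retained sites of which m belong to I distinct
#' islands, the output has S - m + I locations. Island gene and TSS
#' fields come from the member with minimal absolute TSS distance
#' (ties to the smallest probe ID); islands whose members were all
#' removed by QC are simply absent.
#'
#' @param m Numeric matrix of (normalized) M-values for QC-retained probes
#'   (probes x samples).
#' @param annotation Probe annotation covering the rows of `m`.
#' @return List with `m` (locations x samples matrix) and `locations`
#'   (tibble: `location_id`, `kind` (`"site"`/`"island"`), `member_probe_ids`
#'   list-column, `n_members`, `chromosome`, `start`, `end`, `hil_class`,
#'   `closest_tss_gene`, `distance_to_tss`).
#' @examples
#' sim <- simulate_cohort(sim_config(n_probes = 100, n_samples = 8, seed = 2))
#' m <- beta_to_m(sim$cohort$beta)
#' coll <- collapse_islands(m, sim$annotation)
#' nrow(coll$m)
#' @export
collapse_islands <- function(m, annotation) {
  if (!is.matrix(m)) abort("`m` must be a matrix (probes x samples).")
  annotation <- validate_annotation(annotation, rownames(m))
  ann <- annotation[match(rownames(m), annotation$probe_id), ]

  is_member <- !is.na(ann$island_name) & nzchar(ann$island_name)

  # free-standing sites pass through
  free <- ann[!is_member, ]
  site_rows <- tibble::tibble(
    location_id = free$probe_id,
    kind = "site",
    member_probe_ids = as.list(free$probe_id),
    n_members = 1L,
    chromosome = free$chromosome,
    start = free$position,
    end = free$position,
    hil_class = free$hil_class,
    closest_tss_gene = ifelse(
      is.na(free$closest_tss_gene) | !nzchar(free$closest_tss_gene),
      NA_character_, free$closest_tss_gene
    ),
    distance_to_tss = free$distance_to_tss
  )

  island_rows <- NULL
  island_m <- NULL
  if (any(is_member)) {
    mem <- ann[is_member, ]
    groups <- split(seq_len(nrow(mem)), mem$island_name)
    mem_m <- m[is_member, , drop = FALSE]
    island_m <- t(vapply(
      groups,
      function(ii) colMeans(mem_m[ii, , drop = FALSE]),
      numeric(ncol(m))
    ))
    rownames(island_m) <- names(groups)
    island_rows <- purrr::map2_dfr(groups, names(groups), function(ii, nm) {
      rows <- mem[ii, ]
      ga <- assign_gene(rows)
      tibble::tibble(
        location_id = nm,
        kind = "island",
        member_probe_ids = list(rows$probe_id),
        n_members = length(ii),
        chromosome = rows$chromosome[1],
        start = min(rows$position),
        end = max(rows$position),
        hil_class = rows$hil_class[1],
        closest_tss_gene = ga$gene,
        distance_to_tss = ga$distance_to_tss
      )
    })
  }

  locations <- dplyr::bind_rows(site_rows, island_rows)
  out_m <- rbind(m[!is_member, , drop = FALSE], island_m)

  # deterministic genomic order
  ord <- order(locations$chromosome, locations$start, locations$location_id)
  locations <- locations[ord, ]
  out_m <- out_m[locations$location_id, , drop = FALSE]

  list(m = out_m, locations = locations)
}
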