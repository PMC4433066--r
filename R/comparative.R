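#' AS level of a merged catalog
#'
#' The AS level of a species/group is the average number of unique AS events
#' per alternatively spliced gene: unique events divided by the number of
#' genes with at least one event, reported to 2 decimals.
#'
#' @param catalog Merged (non-redundant) event catalog, see
#'   [merge_catalogs()].
#' @return One-row tibble `n_events`, `n_as_genes`, `as_level` (`as_level`
#'   is `NA` when no gene has an event).
#' @export
as_level <- function(catalog) {
  n_events <- nrow(catalog)
  n_genes <- dplyr::n_distinct(catalog$gene_id)
  tibble::tibble(
    n_events = n_events,
    n_as_genes = n_genes,
    as_level = if (n_genes == 0L) NA_real_ else round(n_events / n_genes, 2)
  )
}

#' Events per gene from precomputed counts
#'
#' The same 2-decimal ratio as [as_level()], for when only the total unique
#' event count and the AS gene count are at hand (e.g. published per-species
#' totals).
#'
#' @param n_events Unique AS event count.
#' @param n_as_genes Number of alternatively spliced genes.
#' @return The ratio, rounded to 2 decimals (`NA` when `n_as_genes` is 0).
#' @export
events_per_gene <- function(n_events, n_as_genes) {
  ifelse(n_as_genes == 0, NA_real_, round(n_events / n_as_genes, 2))
}

#' Expression-matched gene set
#'
#' AS-level comparisons are restricted to genes expressed similarly in the
#' two groups, so that AS-detection differences do not just track expression
#' differences. With a differential-expression flag set supplied, the matched
#' set is the universe minus the flagged genes. Without one, a pseudo-count
#' log-fold-change rule is applied: matched genes satisfy
#' |log2((fpkm_a + 1) / (fpkm_b + 1))| <= lfc_max.
#'
#' @param expr Tibble with `gene_id`, `fpkm_a`, `fpkm_b`.
#' @param de_genes Optional character vector of differentially expressed
#'   gene ids to exclude.
#' @param lfc_max Absolute log2 fold-change ceiling (default 1).
#' @return Character vector of matched gene ids.
#' @export
expression_match <- function(expr, de_genes = NULL, lfc_max = 1) {
  if (any(expr$fpkm_a < 0 | expr$fpkm_b < 0)) {
    stop("expression values must be >= 0", call. = FALSE)
  }
  if (!is.null(de_genes)) {
    return(setdiff(expr$gene_id, de_genes))
  }
  lfc <- log2((expr$fpkm_a + 1) / (expr$fpkm_b + 1))
  expr$gene_id[abs(lfc) <= lfc_max]
}

#' Classify AS-level-altered genes between two groups
#'
#' For every expression-matched gene, the unique event counts of the two
#' merged catalogs are compared: events in A but none in B is `gained`; the
#' reverse `lost`; a >= `fold`-fold excess of nonzero counts is
#' `up_fourfold` / `down_fourfold`; anything else `unchanged`. Genes outside
#' the matched set are labelled `excluded_expression` and never counted as
#' altered. Counts are unique merged events, so the classification is
#' invariant to library order and merge order.
#'
#' @param catalog_a,catalog_b Merged event catalogs keyed on the same gene
#'   id space (translate one side through its ortholog map first if needed).
#' @param matched_genes Character vector of expression-matched gene ids; the
#'   record universe is `matched_genes` plus every gene with an event.
#' @param fold Fold threshold (default 4).
#' @return A tibble of class `as_comparison` with columns `gene_id`,
#'   `n_events_a`, `n_events_b`, `fold`, `status`.
#' @export
classify_altered_genes <- function(catalog_a, catalog_b, matched_genes,
                                   fold = 4) {
  counts <- function(catalog) dplyr::count(catalog, .data$gene_id)
  tab <- dplyr::full_join(
    dplyr::rename(counts(catalog_a), n_events_a = "n"),
    dplyr::rename(counts(catalog_b), n_events_b = "n"),
    by = "gene_id")
  universe <- tibble::tibble(gene_id = union(matched_genes, tab$gene_id))
  tab <- dplyr::left_join(universe, tab, by = "gene_id") |>
    dplyr::mutate(
      n_events_a = dplyr::coalesce(.data$n_events_a, 0L),
      n_events_b = dplyr::coalesce(.data$n_events_b, 0L),
      fold = dplyr::if_else(
        .data$n_events_a > 0L & .data$n_events_b > 0L,
        pmax(.data$n_events_a / .data$n_events_b,
             .data$n_events_b / .data$n_events_a),
        NA_real_),
      status = dplyr::case_when(
        !.data$gene_id %in% matched_genes ~ "excluded_expression",
        .data$n_events_a >= 1L & .data$n_events_b == 0L ~ "gained",
        .data$n_events_b >= 1L & .data$n_events_a == 0L ~ "lost",
        .data$n_events_a >= !!fold * .data$n_events_b &
          .data$n_events_b >= 1L ~ "up_fourfold",
        .data$n_events_b >= !!fold * .data$n_events_a &
          .data$n_events_a >= 1L ~ "down_fourfold",
        TRUE ~ "unchanged")
    ) |>
    dplyr::arrange(.data$gene_id)
  class(tab) <- c("as_comparison", class(tab))
  attr(tab, "fold_threshold") <- fold
  tab
}

#' @export
tidy.as_comparison <- function(x, ...) {
  x |>
    dplyr::filter(.data$status != "excluded_expression") |>
    dplyr::count(.data$status, name = "n_genes") |>
    dplyr::arrange(dplyr::desc(.data$n_genes))
}

#' @export
glance.as_comparison <- function(x, ...) {
  matched <- dplyr::filter(x, .data$status != "excluded_expression")
  tibble::tibble(
    n_matched = nrow(matched),
    n_gained = sum(matched$status == "gained"),
    n_lost = sum(matched$status == "lost"),
    n_up_fourfold = sum(matched$status == "up_fourfold"),
    n_down_fourfold = sum(matched$status == "down_fourfold"),
    n_unchanged = sum(matched$status == "unchanged"),
    n_excluded = nrow(x) - nrow(matched),
    fold_threshold = attr(x, "fold_threshold")
  )
}

#' Translate one catalog's gene ids through an ortholog map
#'
#' @param catalog Event catalog keyed on one id space (e.g. teosinte
#'   unigenes).
#' @param pairs Ortholog pair tibble (`gene_id`, `unigene_id`), mapping
#'   `unigene_id` (the catalog's space) to the reference `gene_id`.
#' @return The catalog restricted to mapped genes, re-keyed on the reference
#'   gene ids.
#' @export
translate_gene_ids <- function(catalog, pairs) {
  map <- stats::setNames(pairs$gene_id, pairs$unigene_id)
  out <- dplyr::filter(catalog, .data$gene_id %in% names(map))
  dplyr::mutate(out, gene_id = unname(map[.data$gene_id]))
}

#' Intersect altered genes with selection regions
#'
#' A gene lies in a selection region iff its genomic span overlaps any
#' region by at least 1 bp. Returns the in-region records — the "putatively
#' improved gene" candidates when the regions encode selection during
#' improvement — with the per-status counts as a `tidy`-style attribute.
#'
#' @param records `as_comparison` tibble from [classify_altered_genes()].
#' @param gene_spans Tibble `gene_id`, `chrom`, `start`, `end` of gene
#'   spans.
#' @param regions Tibble `chrom`, `start`, `end` (e.g. from [read_bed()]).
#' @return The in-region records joined with the first overlapping region's
#'   coordinates; attribute `status_counts` holds counts by status.
#' @export
intersect_with_regions <- function(records, gene_spans, regions) {
  spans <- dplyr::inner_join(dplyr::as_tibble(records), gene_spans,
                             by = "gene_id")
  if (nrow(spans) == 0L) {
    out <- dplyr::mutate(spans, region_start = integer(),
                         region_end = integer())
  } else {
    hit <- purrr::pmap(list(spans$chrom, spans$start, spans$end),
      function(ch, s, e) {
        ov <- regions$chrom == ch & regions$start < e & regions$end > s
        if (any(ov)) {
          i <- which(ov)[1]
          c(regions$start[i], regions$end[i])
        } else {
          NULL
        }
      })
    keep <- !purrr::map_lgl(hit, is.null)
    out <- spans[keep, , drop = FALSE]
    out$region_start <- purrr::map_int(hit[keep], ~ as.integer(.x[1]))
    out$region_end <- purrr::map_int(hit[keep], ~ as.integer(.x[2]))
  }
  attr(out, "status_counts") <- dplyr::count(out, .data$status,
                                             name = "n_genes")
  out
}
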