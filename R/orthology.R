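#' Read a 12-column tabular alignment file (blast outfmt 6 dialect)
#'
#' @param path Path to a tab-separated hit table with the standard columns
#'   qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend, sstart,
#'   send, evalue, bitscore.
#' @return Tibble with columns `query_id`, `subject_id`, `percent_identity`,
#'   `alignment_length`, `mismatches`, `gap_opens`, `q_start`, `q_end`,
#'   `s_start`, `s_end`, `evalue`, `bitscore`.
#' @export
read_blast_tab <- function(path) {
  cols <- c("query_id", "subject_id", "percent_identity", "alignment_length",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start",
            "s_end", "evalue", "bitscore")
  out <- readr::read_tsv(path, col_names = cols, comment = "#",
                         show_col_types = FALSE,
                         col_types = "ccdiiiiiiidd")
  if (any(out$evalue < 0) ||
      any(out$percent_identity < 0 | out$percent_identity > 100)) {
    stop("invalid hit table: e-values must be >= 0 and identities in [0,100]",
         call. = FALSE)
  }
  out
}

#' Best hit per query
#'
#' The best hit minimizes the e-value; ties are broken by maximal bitscore,
#' then by lexicographically smallest subject_id, so the result is
#' deterministic regardless of input order.
#'
#' @param hits Hit tibble (see [read_blast_tab()]).
#' @return One row per query_id.
#' @export
best_hit_per_query <- function(hits) {
  hits |>
    dplyr::arrange(.data$query_id, .data$evalue,
                   dplyr::desc(.data$bitscore), .data$subject_id) |>
    dplyr::distinct(.data$query_id, .keep_all = TRUE)
}

#' Reciprocal-best-hit ortholog pairs
#'
#' A pair (a, b) is an ortholog call iff b is a's best hit in the A->B table,
#' a is b's best hit in the B->A table, and both best-hit e-values are at or
#' below `evalue_max`.
#'
#' @param hits_ab Hits of A queries against B subjects.
#' @param hits_ba Hits of B queries against A subjects.
#' @param evalue_max Inclusive e-value ceiling (default 1e-10).
#' @return Tibble `gene_id` (A side), `unigene_id` (B side), `evalue_fwd`,
#'   `evalue_rev`, sorted by `gene_id`.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, evalue_max = 1e-10) {
  best_ab <- dplyr::filter(best_hit_per_query(hits_ab),
                           .data$evalue <= evalue_max)
  best_ba <- dplyr::filter(best_hit_per_query(hits_ba),
                           .data$evalue <= evalue_max)
  dplyr::inner_join(
    dplyr::select(best_ab, gene_id = "query_id", unigene_id = "subject_id",
                  evalue_fwd = "evalue"),
    dplyr::select(best_ba, unigene_id = "query_id", gene_id = "subject_id",
                  evalue_rev = "evalue"),
    by = c("gene_id", "unigene_id")) |>
    dplyr::arrange(.data$gene_id)
}

#' Orthologs shared between two pair sets
#'
#' Intersects two reciprocal-best-hit pair tables on the reference-side
#' `gene_id` — e.g. the maize genes with an ortholog call in each of two
#' teosinte subspecies.
#'
#' @param pairs_sub1,pairs_sub2 Tibbles with a `gene_id` column.
#' @return Sorted character vector of shared gene ids.
#' @export
shared_orthologs <- function(pairs_sub1, pairs_sub2) {
  sort(intersect(unique(pairs_sub1$gene_id), unique(pairs_sub2$gene_id)))
}

#' Filter hits by identity and query coverage
#'
#' Keeps hits with `percent_identity >= identity_min` and query coverage
#' (alignment_length / query length x 100, single best HSP, no chaining)
#' `>= coverage_min`.
#'
#' @param hits Hit tibble.
#' @param query_lengths Named numeric vector (or two-column data frame
#'   `query_id`, `length`) of query sequence lengths in bp.
#' @param identity_min,coverage_min Inclusive thresholds in percent
#'   (default 95 each).
#' @return The retained hits, with a `query_coverage` column added.
#' @export
filter_matched_transcripts <- function(hits, query_lengths,
                                       identity_min = 95,
                                       coverage_min = 95) {
  if (is.data.frame(query_lengths)) {
    query_lengths <- stats::setNames(query_lengths$length,
                                     query_lengths$query_id)
  }
  len <- unname(query_lengths[hits$query_id])
  if (anyNA(len)) {
    stop("missing query length for: ",
         hits$query_id[which(is.na(len))[1]], call. = FALSE)
  }
  hits |>
    dplyr::mutate(query_coverage = 100 * .data$alignment_length / len) |>
    dplyr::filter(.data$percent_identity >= identity_min,
                  .data$query_coverage >= coverage_min)
}
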