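#' Gene spans from an exon table
#'
#' @param exons Exon table.
#' @return Tibble `gene_id`, `chrom`, `strand`, `start`, `end` where
#'   [start, end) is the hull of all the gene's exons.
#' @export
gene_spans <- function(exons) {
  exons |>
    dplyr::group_by(.data$gene_id, .data$chrom, .data$strand) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop")
}

#' Per-gene genomic feature vectors
#'
#' Computes, for every gene, the ten architecture features whose association
#' with AS is examined: exon number and exon-length statistics on the union
#' of exons across isoforms; intron count/length statistics on the longest
#' transcript (the representative isoform); gene length as the exon-hull
#' span; GC content over the span sequence.
#'
#' @param exons Exon table.
#' @param genome Named character vector of chromosome sequences.
#' @return Tibble: `gene_id`, `exon_number`, `gene_length`,
#'   `total_intron_length`, `max_intron_length`, `gc_content`,
#'   `min_exon_length`, `avg_exon_length`, `max_exon_length`,
#'   `min_intron_length`, `avg_intron_length`. Intron statistics are 0 for
#'   monoexonic representatives.
#' @export
compute_features <- function(exons, genome) {
  spans <- gene_spans(exons)
  missing_chr <- setdiff(unique(spans$chrom), names(genome))
  if (length(missing_chr) > 0L) {
    stop("chromosome absent from genome: ", missing_chr[1], call. = FALSE)
  }
  if (any(spans$end > nchar(genome)[spans$chrom])) {
    stop("gene span beyond chromosome end", call. = FALSE)
  }

  # exon stats on the union of exon intervals across isoforms
  exon_union <- exons |>
    dplyr::distinct(.data$gene_id, .data$start, .data$end) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(df, key) {
      m <- merge_intervals(df$start, df$end)
      len <- m[, 2] - m[, 1]
      tibble::tibble(
        exon_number = nrow(m),
        min_exon_length = min(len),
        avg_exon_length = mean(len),
        max_exon_length = max(len))
    }) |>
    dplyr::ungroup()

  # intron stats on the longest transcript per gene
  tx_len <- exons |>
    dplyr::group_by(.data$gene_id, .data$transcript_id) |>
    dplyr::summarise(len = sum(.data$end - .data$start), .groups = "drop") |>
    dplyr::arrange(.data$gene_id, dplyr::desc(.data$len),
                   .data$transcript_id) |>
    dplyr::distinct(.data$gene_id, .keep_all = TRUE)
  rep_introns <- derive_introns(
    dplyr::semi_join(exons, tx_len, by = c("gene_id", "transcript_id")))
  intron_stats <- rep_introns |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      total_intron_length = sum(.data$end - .data$start),
      max_intron_length = max(.data$end - .data$start),
      min_intron_length = min(.data$end - .data$start),
      avg_intron_length = mean(.data$end - .data$start),
      .groups = "drop")

  gc <- unname(gc_content(substr(genome[spans$chrom], spans$start + 1L,
                                 spans$end)))

  spans |>
    dplyr::transmute(.data$gene_id,
                     gene_length = .data$end - .data$start,
                     gc_content = gc) |>
    dplyr::left_join(exon_union, by = "gene_id") |>
    dplyr::left_join(intron_stats, by = "gene_id") |>
    dplyr::mutate(dplyr::across(
      c("total_intron_length", "max_intron_length", "min_intron_length",
        "avg_intron_length"),
      ~ dplyr::coalesce(.x, 0))) |>
    dplyr::select("gene_id", "exon_number", "gene_length",
                  "total_intron_length", "max_intron_length", "gc_content",
                  "min_exon_length", "avg_exon_length", "max_exon_length",
                  "min_intron_length", "avg_intron_length") |>
    dplyr::arrange(.data$gene_id)
}

merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  out_s <- start[1]; out_e <- end[1]
  res <- list()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= out_e) {
      out_e <- max(out_e, end[i])
    } else {
      res[[length(res) + 1L]] <- c(out_s, out_e)
      out_s <- start[i]; out_e <- end[i]
    }
  }
  res[[length(res) + 1L]] <- c(out_s, out_e)
  do.call(rbind, res)
}

gc_content <- function(seqs) {
  n_gc <- nchar(gsub("[^GCgc]", "", seqs))
  n <- nchar(seqs)
  ifelse(n == 0L, NA_real_, n_gc / n)
}

#' Correlate gene features with unique AS event counts
#'
#' Rank (Spearman) correlation of each genomic feature against the per-gene
#' unique AS event count, with a two-sided p-value. Rank correlation is the
#' default because the features are heavy-tailed and only monotone
#' association is claimed; Pearson is available via `method`.
#'
#' @param features Feature tibble from [compute_features()].
#' @param event_counts Tibble `gene_id`, `n_events` (genes absent here count
#'   0 events).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Object of class `as_feature_cor`: a tibble `feature`,
#'   `coefficient`, `p_value`, ordered as the feature columns; constant
#'   features get `NA` coefficients rather than an error.
#' @export
correlate_features <- function(features, event_counts,
                               method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (nrow(features) < 3L) {
    stop("need at least 3 genes to correlate", call. = FALSE)
  }
  tab <- dplyr::left_join(features, event_counts, by = "gene_id") |>
    dplyr::mutate(n_events = dplyr::coalesce(.data$n_events, 0L))
  feat_cols <- setdiff(names(features), "gene_id")
  rows <- purrr::map(feat_cols, function(f) {
    x <- tab[[f]]
    if (length(unique(x)) < 2L || anyNA(x)) {
      return(tibble::tibble(feature = f, coefficient = NA_real_,
                            p_value = NA_real_))
    }
    ct <- suppressWarnings(
      stats::cor.test(x, tab$n_events, method = method, exact = FALSE))
    tibble::tibble(feature = f, coefficient = unname(ct$estimate),
                   p_value = ct$p.value)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("as_feature_cor", class(out))
  attr(out, "method") <- method
  attr(out, "n_genes") <- nrow(tab)
  out
}

#' @export
tidy.as_feature_cor <- function(x, ...) dplyr::as_tibble(x)

#' @export
glance.as_feature_cor <- function(x, ...) {
  tibble::tibble(
    n_genes = attr(x, "n_genes"),
    method = attr(x, "method"),
    n_features = nrow(x),
    n_significant = sum(x$p_value < 0.05, na.rm = TRUE)
  )
}

#' Retained-intron lengths of a catalog
#'
#' Collects the lengths of all retained introns across IR, IR_ALT and
#' IR_DOUBLE events.
#'
#' @param catalog Event catalog.
#' @return Tibble `gene_id`, `chrom`, `strand`, `start`, `end`, `length`,
#'   one row per retained intron occurrence.
#' @export
retained_intron_table <- function(catalog) {
  ir <- dplyr::filter(catalog,
                      .data$event_type %in% c("IR", "IR_ALT", "IR_DOUBLE"),
                      !is.na(.data$retained_introns))
  if (nrow(ir) == 0L) {
    return(tibble::tibble(gene_id = character(), chrom = character(),
                          strand = character(), start = integer(),
                          end = integer(), length = integer()))
  }
  ir |>
    dplyr::mutate(ri = strsplit(.data$retained_introns, ";", fixed = TRUE)) |>
    tidyr::unnest_longer("ri") |>
    tidyr::separate_wider_delim("ri", "-", names = c("start", "end")) |>
    dplyr::transmute(.data$gene_id, .data$chrom, .data$strand,
                     start = as.integer(.data$start),
                     end = as.integer(.data$end),
                     length = .data$end - .data$start)
}

#' Retained-intron length list and histogram
#'
#' @param catalog Event catalog.
#' @param breaks Histogram breaks passed to [graphics::hist()] semantics via
#'   [base::cut()]; default 20 equal bins.
#' @return List with `lengths` (integer vector), `range` (min/max, NULL when
#'   empty) and `histogram` (tibble `bin`, `n`).
#' @export
retained_intron_lengths <- function(catalog, breaks = 20) {
  lens <- retained_intron_table(catalog)$length
  if (length(lens) == 0L) {
    return(list(lengths = integer(), range = NULL,
                histogram = tibble::tibble(bin = character(), n = integer())))
  }
  cuts <- cut(lens, breaks = breaks, include.lowest = TRUE)
  list(
    lengths = lens,
    range = c(min = min(lens), max = max(lens)),
    histogram = tibble::tibble(bin = levels(cuts),
                               n = as.integer(table(cuts)))
  )
}

#' Transposable elements inside retained introns
#'
#' An intron "contains" a TE iff the TE interval lies fully inside the
#' intron interval (containment, not mere overlap; a boundary-straddling TE
#' does not count). With `rule = "overlap50"`, a TE instead counts when at
#' least half of its length overlaps the intron. A single intron may contain
#' several TEs.
#'
#' @param introns Tibble `chrom`, `start`, `end` (plus any id columns) of
#'   retained introns.
#' @param tes Tibble `chrom`, `start`, `end`, plus optional `te_class` and
#'   `te_type` columns (e.g. [read_bed()] output with `name` split as
#'   "class/type").
#' @param rule `"containment"` (default) or `"overlap50"`.
#' @return List: `hits` (intron x TE pairs), `by_type` (counts per
#'   te_class/te_type), `n_introns_with_te`, `n_te`, `n_retained_introns`,
#'   `pct_introns_with_te` (2 decimals).
#' @export
te_in_retained_introns <- function(introns, tes,
                                   rule = c("containment", "overlap50")) {
  rule <- match.arg(rule)
  introns <- dplyr::mutate(dplyr::as_tibble(introns),
                           .intron_id = dplyr::row_number())
  hits <- purrr::pmap(
    list(introns$chrom, introns$start, introns$end, introns$.intron_id),
    function(ch, s, e, id) {
      if (rule == "containment") {
        sel <- tes$chrom == ch & tes$start >= s & tes$end <= e
      } else {
        ov <- pmin(tes$end, e) - pmax(tes$start, s)
        sel <- tes$chrom == ch & ov >= (tes$end - tes$start) / 2
      }
      if (!any(sel)) return(NULL)
      dplyr::mutate(tes[sel, , drop = FALSE], .intron_id = id)
    }) |>
    purrr::compact() |>
    dplyr::bind_rows()
  if (nrow(hits) == 0L) {
    hits <- dplyr::mutate(tes[0, , drop = FALSE], .intron_id = integer())
  }
  by_type <- if (all(c("te_class", "te_type") %in% names(hits))) {
    dplyr::count(hits, .data$te_class, .data$te_type, name = "n_te")
  } else {
    tibble::tibble(te_class = character(), te_type = character(),
                   n_te = integer())
  }
  n_with <- dplyr::n_distinct(hits$.intron_id)
  list(
    hits = hits,
    by_type = by_type,
    n_introns_with_te = n_with,
    n_te = nrow(hits),
    n_retained_introns = nrow(introns),
    pct_introns_with_te = if (nrow(introns) == 0L) NA_real_ else
      round(100 * n_with / nrow(introns), 2)
  )
}
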