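#' Derive introns from an exon table
#'
#' For each transcript the introns are the gaps between consecutive exons:
#' a transcript with n exons yields n - 1 introns `[exon_i.end,
#' exon_{i+1}.start)`. Monoexonic transcripts contribute no rows.
#'
#' @param exons Exon table (see [read_gtf()]).
#' @return Tibble with columns `gene_id`, `transcript_id`, `chrom`, `strand`,
#'   `start`, `end`, one row per intron.
#' @export
derive_introns <- function(exons) {
  exons |>
    dplyr::distinct(.data$gene_id, .data$transcript_id, .data$chrom,
                    .data$strand, .data$start, .data$end) |>
    dplyr::arrange(.data$transcript_id, .data$start) |>
    dplyr::group_by(.data$gene_id, .data$transcript_id, .data$chrom,
                    .data$strand) |>
    dplyr::reframe(
      .intron_start = utils::head(.data$end, -1L),
      .intron_end = utils::tail(.data$start, -1L)
    ) |>
    dplyr::rename(start = ".intron_start", end = ".intron_end") |>
    dplyr::filter(!is.na(.data$start))
}

#' Keep only multiexonic genes
#'
#' A gene is multiexonic — and hence capable of splicing — if at least one of
#' its transcripts has two or more exons. Genes whose transcripts are all
#' monoexonic are dropped.
#'
#' @param exons Exon table.
#' @return The exon table restricted to multiexonic genes.
#' @export
filter_multiexonic <- function(exons) {
  keep <- exons |>
    dplyr::distinct(.data$gene_id, .data$transcript_id, .data$start,
                    .data$end) |>
    dplyr::count(.data$gene_id, .data$transcript_id) |>
    dplyr::filter(.data$n >= 2L) |>
    dplyr::distinct(.data$gene_id)
  dplyr::semi_join(exons, keep, by = "gene_id")
}

# ---- internal chain machinery -----------------------------------------------
# A splice chain is an n x 2 integer matrix of intron (start, end) rows,
# sorted by start. The empty chain is a 0 x 2 matrix.

chain_string <- function(m) {
  if (nrow(m) == 0L) return(".")
  paste(paste0(m[, 1], "-", m[, 2]), collapse = ",")
}

parse_chain <- function(s) {
  if (identical(s, ".") || !nzchar(s)) {
    return(matrix(integer(), ncol = 2L))
  }
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], "-", fixed = TRUE)
  m <- matrix(as.integer(unlist(parts)), ncol = 2L, byrow = TRUE)
  m[order(m[, 1]), , drop = FALSE]
}

mirror_chain <- function(m) {
  if (nrow(m) == 0L) return(m)
  out <- cbind(-m[, 2], -m[, 1])
  out[order(out[, 1]), , drop = FALSE]
}

chain_key <- function(m) chain_string(m)

intron_keys <- function(m) {
  if (nrow(m) == 0L) return(character(0))
  paste0(m[, 1], "-", m[, 2])
}

# Remove introns present (identically) in both chains.
strip_shared <- function(c1, c2) {
  k1 <- intron_keys(c1)
  k2 <- intron_keys(c2)
  list(c1[!(k1 %in% k2), , drop = FALSE],
       c2[!(k2 %in% k1), , drop = FALSE])
}

# Classify a pair of plus-oriented remainder chains (shared introns already
# stripped). Returns one of the named event types.
classify_remainders <- function(r1, r2) {
  if (nrow(r1) > nrow(r2)) { tmp <- r1; r1 <- r2; r2 <- tmp }
  n1 <- nrow(r1); n2 <- nrow(r2)
  if (n1 == 0L && n2 == 1L) return("IR")
  if (n1 == 0L && n2 == 2L) return("IR_DOUBLE")
  if (n1 == 1L && n2 == 1L) {
    s1 <- r1[1, 1]; e1 <- r1[1, 2]; s2 <- r2[1, 1]; e2 <- r2[1, 2]
    if (e1 == e2 && s1 != s2) return("AD")
    if (s1 == s2 && e1 != e2) return("AA")
    if (e1 < s2 || e2 < s1) return("IR_ALT")
    return("OTHER")
  }
  if (n1 == 1L && n2 %in% c(2L, 3L)) {
    a <- r1[1, 1]; b <- r1[1, 2]
    ok <- r2[1, 1] == a && r2[n2, 2] == b &&
      all(r2[-n2, 2] < r2[-1, 1])  # skipped exon(s) of positive width
    if (ok) return(if (n2 == 2L) "ES" else "ES_DOUBLE")
    return("OTHER")
  }
  "OTHER"
}

classify_chain_pair <- function(c1, c2, strand) {
  stripped <- strip_shared(c1, c2)
  r1 <- stripped[[1]]; r2 <- stripped[[2]]
  if (strand == "-") {
    r1 <- mirror_chain(r1)
    r2 <- mirror_chain(r2)
  }
  classify_remainders(r1, r2)
}

retained_from_pair <- function(c1, c2, type) {
  stripped <- strip_shared(c1, c2)
  r1 <- stripped[[1]]; r2 <- stripped[[2]]
  longer <- if (nrow(r1) >= nrow(r2)) r1 else r2
  switch(type,
    IR = longer,
    IR_DOUBLE = longer,
    IR_ALT = {
      both <- rbind(r1, r2)
      both[order(both[, 1]), , drop = FALSE]
    },
    matrix(integer(), ncol = 2L))
}

#' Classify an alternative-splicing event from its splice chains
#'
#' Given the distinct splice-site chains occupying one variable region, names
#' the event. For two chains the rule table is: empty vs one intron is intron
#' retention (IR); empty vs two introns is double retention (IR1 + IR2); two
#' single introns sharing an acceptor but not a donor is an alternative donor
#' (AD); sharing a donor but not an acceptor an alternative acceptor (AA);
#' two disjoint single introns are alternative retention (IR1 or IR2); one
#' intron vs two (or three) introns spanning the same bounds is exon skipping
#' (ES, or ES1 + ES2); anything else is OTHER. Donor/acceptor are
#' strand-aware: on the minus strand chains are mirrored before the rules
#' apply. With three or more chains, the event gets a simple type only if
#' every pairwise comparison agrees on that one simple type (IR, ES, AD, AA);
#' otherwise OTHER.
#'
#' @param chains A list of chain strings (e.g. `"100-200,250-400"`, `"."` for
#'   the empty chain) or of n x 2 intron matrices; at least two distinct
#'   chains.
#' @param strand `"+"` or `"-"`.
#' @return A single event-type string.
#' @export
classify_event <- function(chains, strand = "+") {
  mats <- purrr::map(chains, function(x) {
    if (is.character(x)) parse_chain(x) else x
  })
  keys <- purrr::map_chr(mats, chain_key)
  mats <- mats[!duplicated(keys)]
  if (length(mats) < 2L) {
    stop("classify_event needs at least 2 distinct chains", call. = FALSE)
  }
  if (length(mats) == 2L) {
    return(classify_chain_pair(mats[[1]], mats[[2]], strand))
  }
  pairs <- utils::combn(length(mats), 2L)
  types <- apply(pairs, 2L, function(ij) {
    classify_chain_pair(mats[[ij[1]]], mats[[ij[2]]], strand)
  })
  simple <- c("IR", "ES", "AD", "AA")
  if (length(unique(types)) == 1L && types[1] %in% simple) types[1] else "OTHER"
}

# Events between two splice structures. A structure is
# list(start =, end =, introns = n x 2 matrix). Variable regions are the
# segments between consecutive splice sites shared by the two transcripts
# (the intersection of their spans bounds the outermost segments); a segment
# whose chains differ is one event. Segments touched by an intron that
# straddles the span intersection are skipped: a difference there reflects
# differing transcript termini, which never count as AS events here.
pairwise_structure_events <- function(a, b, chrom, strand, gene_id) {
  w_start <- max(a$start, b$start)
  w_end <- min(a$end, b$end)
  if (w_start >= w_end) return(NULL)
  sites_a <- unique(as.vector(a$introns))
  sites_b <- unique(as.vector(b$introns))
  common <- sort(intersect(sites_a, sites_b))
  common <- common[common > w_start & common < w_end]
  bounds <- c(w_start, common, w_end)
  out <- vector("list", length(bounds) - 1L)
  for (i in seq_len(length(bounds) - 1L)) {
    L <- bounds[i]; R <- bounds[i + 1L]
    seg <- segment_chains(a$introns, b$introns, L, R)
    if (is.null(seg)) next  # straddling intron: terminus region, no event
    c1 <- seg[[1]]; c2 <- seg[[2]]
    if (identical(chain_key(c1), chain_key(c2))) next
    type <- classify_chain_pair(c1, c2, strand)
    ret <- retained_from_pair(c1, c2, type)
    keys <- sort(c(chain_key(c1), chain_key(c2)))
    out[[i]] <- tibble::tibble(
      gene_id = gene_id, chrom = chrom, strand = strand,
      flank_left = L, flank_right = R,
      event_type = type,
      chains = paste(keys, collapse = "|"),
      retained_introns = if (nrow(ret) > 0L) {
        paste(paste0(ret[, 1], "-", ret[, 2]), collapse = ";")
      } else NA_character_,
      signature = paste(chrom, strand, L, R,
                        paste(keys, collapse = "|"), sep = ":")
    )
  }
  out <- purrr::compact(out)
  if (length(out) == 0L) NULL else dplyr::bind_rows(out)
}

segment_chains <- function(m1, m2, L, R) {
  pick <- function(m) {
    if (nrow(m) == 0L) return(m)
    inter <- m[, 1] < R & m[, 2] > L
    contained <- m[, 1] >= L & m[, 2] <= R
    if (any(inter & !contained)) return(NULL)
    m[contained, , drop = FALSE]
  }
  c1 <- pick(m1); c2 <- pick(m2)
  if (is.null(c1) || is.null(c2)) NULL else list(c1, c2)
}

transcript_structures <- function(exons) {
  txs <- split(exons, exons$transcript_id)
  structs <- purrr::map(txs, function(tx) {
    tx <- tx[order(tx$start), ]
    n <- nrow(tx)
    introns <- if (n > 1L) {
      cbind(tx$end[-n], tx$start[-1])
    } else {
      matrix(integer(), ncol = 2L)
    }
    list(start = tx$start[1], end = tx$end[n], introns = introns)
  })
  keys <- purrr::map_chr(structs, function(s) {
    paste(s$start, s$end, chain_string(s$introns), sep = "|")
  })
  structs[!duplicated(keys)]
}

#' Enumerate the AS events of one gene
#'
#' Compares every pair of distinct isoform splice structures of the gene. For
#' each pair, the variable regions are the maximal segments between
#' consecutive splice sites common to the two transcripts (with the
#' intersection of the transcript spans bounding the outermost segments); a
#' segment where the two splice chains differ is one event, classified by
#' [classify_event()] rules. Events from different pairs that describe the
#' same difference collapse by signature, so a gene's event set is the
#' signature union over all isoform pairs. Differences in transcript 5'/3'
#' termini alone never produce events.
#'
#' @param exons Exon table of a single gene (>= 1 transcript). A single
#'   transcript, or identical transcripts, yield zero events.
#' @return Tibble of events: `gene_id`, `chrom`, `strand`, `flank_left`,
#'   `flank_right`, `event_type`, `chains`, `retained_introns`, `signature`.
#' @export
enumerate_gene_events <- function(exons) {
  if (dplyr::n_distinct(exons$gene_id) != 1L) {
    stop("enumerate_gene_events expects exons of exactly one gene",
         call. = FALSE)
  }
  if (dplyr::n_distinct(exons$strand) != 1L ||
      dplyr::n_distinct(exons$chrom) != 1L) {
    stop("gene ", exons$gene_id[1],
         ": transcripts on different strands or chromosomes", call. = FALSE)
  }
  structs <- transcript_structures(exons)
  if (length(structs) < 2L) return(empty_event_table())
  chrom <- exons$chrom[1]; strand <- exons$strand[1]
  gene_id <- exons$gene_id[1]
  pairs <- utils::combn(length(structs), 2L)
  ev <- purrr::map(seq_len(ncol(pairs)), function(k) {
    pairwise_structure_events(structs[[pairs[1, k]]], structs[[pairs[2, k]]],
                              chrom, strand, gene_id)
  })
  ev <- purrr::compact(ev)
  if (length(ev) == 0L) return(empty_event_table())
  dplyr::distinct(dplyr::bind_rows(ev), .data$signature, .keep_all = TRUE)
}

empty_event_table <- function() {
  tibble::tibble(
    gene_id = character(), chrom = character(), strand = character(),
    flank_left = integer(), flank_right = integer(),
    event_type = character(), chains = character(),
    retained_introns = character(), signature = character()
  )
}

#' Enumerate AS events for every gene of a library
#'
#' Applies [enumerate_gene_events()] gene by gene and tags the result with a
#' library identifier, producing a per-library event catalog.
#'
#' @param exons Exon table (any number of genes).
#' @param library_id Label stored in the `library_id` column.
#' @return Event catalog tibble (the per-gene event columns plus
#'   `library_id`).
#' @export
enumerate_events <- function(exons, library_id = "lib1") {
  out <- exons |>
    dplyr::group_split(.data$gene_id) |>
    purrr::map(enumerate_gene_events) |>
    dplyr::bind_rows()
  if (nrow(out) == 0L) out <- empty_event_table()
  dplyr::mutate(out, library_id = library_id)
}

#' Merge per-library event catalogs into a non-redundant catalog
#'
#' Identical events observed in different libraries (same signature within a
#' gene) collapse to one record. The merged catalog keeps the first
#' library_id seen; the pre-merge total and the merged unique count are
#' attached as attributes `n_total` and `n_unique` (the "total events" and
#' "species-unique events" of per-species accounting).
#'
#' @param ... Event catalogs (tibbles), or a single list of them.
#' @return Merged catalog tibble with attributes `n_total` and `n_unique`.
#' @export
merge_catalogs <- function(...) {
  cats <- list(...)
  if (length(cats) == 1L && is.list(cats[[1]]) &&
      !is.data.frame(cats[[1]])) {
    cats <- cats[[1]]
  }
  all_ev <- dplyr::bind_rows(cats)
  if (nrow(all_ev) == 0L) {
    out <- empty_event_table()
    out$library_id <- character()
    attr(out, "n_total") <- 0L
    attr(out, "n_unique") <- 0L
    return(out)
  }
  merged <- dplyr::distinct(all_ev, .data$gene_id, .data$signature,
                            .keep_all = TRUE)
  attr(merged, "n_total") <- nrow(all_ev)
  attr(merged, "n_unique") <- nrow(merged)
  merged
}

#' Summarize AS-event type composition
#'
#' Accepts either a (merged) event catalog or a precomputed count table with
#' columns `event_type` and `n`. Reports per-type counts and percentages of
#' the total (2 decimals), and — when the number of AS genes is known — the
#' average number of events per AS gene ("AS level") to 2 decimals.
#'
#' @param x Event catalog tibble, or count tibble (`event_type`, `n`).
#' @param n_as_genes Number of alternatively spliced genes; taken from the
#'   catalog when `x` is one and this is `NULL`.
#' @return Tibble (`event_type`, `n`, `pct`) with attributes `n_events`,
#'   `n_as_genes` and `events_per_gene`.
#' @export
summarize_types <- function(x, n_as_genes = NULL) {
  if ("signature" %in% names(x)) {
    counts <- dplyr::count(x, .data$event_type)
    if (is.null(n_as_genes)) n_as_genes <- dplyr::n_distinct(x$gene_id)
  } else {
    stopifnot(all(c("event_type", "n") %in% names(x)))
    counts <- dplyr::as_tibble(x)
  }
  if (any(counts$n < 0)) stop("negative event counts", call. = FALSE)
  total <- sum(counts$n)
  if (total == 0) {
    out <- tibble::tibble(event_type = character(), n = integer(),
                          pct = numeric())
  } else {
    out <- dplyr::mutate(
      dplyr::arrange(counts, dplyr::desc(.data$n)),
      pct = round(100 * .data$n / total, 2))
  }
  attr(out, "n_events") <- total
  attr(out, "n_as_genes") <- n_as_genes
  attr(out, "events_per_gene") <- if (!is.null(n_as_genes) &&
                                      isTRUE(n_as_genes > 0)) {
    round(total / n_as_genes, 2)
  } else {
    NA_real_
  }
  out
}
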