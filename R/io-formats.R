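#' Read transcript models from a GTF file
#'
#' Parses exon features of a GTF2.2 file into a tidy exon table, one row per
#' exon. GTF coordinates (1-based, inclusive) are converted to the package's
#' internal convention, 0-based half-open, at this boundary; every downstream
#' function consumes only that convention.
#'
#' Chromosome names are matched as exact text everywhere in the package: no
#' "chr"-prefix normalization is attempted.
#'
#' @param path Path to a GTF file whose exon lines carry `gene_id` and
#'   `transcript_id` attributes.
#' @return A tibble with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `start`, `end` (0-based half-open), sorted by
#'   (chrom, start, gene_id, transcript_id, start).
#' @export
read_gtf <- function(path) {
  lines <- readr::read_lines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(empty_exon_table())
  }
  fields <- stringr::str_split(lines[idx], "\t")
  bad <- which(lengths(fields) < 9L)
  if (length(bad) > 0L) {
    stop("malformed GTF line ", idx[bad[1]], " in ", path,
         ": expected 9 tab-separated fields", call. = FALSE)
  }
  mat <- do.call(rbind, lapply(fields, `[`, 1:9))
  feature <- mat[, 3]
  sel <- feature == "exon"
  if (!any(sel)) {
    return(empty_exon_table())
  }
  mat <- mat[sel, , drop = FALSE]
  line_no <- idx[sel]
  start1 <- suppressWarnings(as.integer(mat[, 4]))
  end1 <- suppressWarnings(as.integer(mat[, 5]))
  if (anyNA(start1) || anyNA(end1)) {
    first <- line_no[which(is.na(start1) | is.na(end1))[1]]
    stop("malformed GTF line ", first, " in ", path,
         ": non-numeric coordinates", call. = FALSE)
  }
  strand <- mat[, 7]
  if (any(!strand %in% c("+", "-"))) {
    first <- line_no[which(!strand %in% c("+", "-"))[1]]
    stop("malformed GTF line ", first, " in ", path,
         ": transcript exons need strand + or -", call. = FALSE)
  }
  gene_id <- gtf_attribute(mat[, 9], "gene_id")
  transcript_id <- gtf_attribute(mat[, 9], "transcript_id")
  if (anyNA(gene_id) || anyNA(transcript_id)) {
    first <- line_no[which(is.na(gene_id) | is.na(transcript_id))[1]]
    stop("malformed GTF line ", first, " in ", path,
         ": missing gene_id or transcript_id attribute", call. = FALSE)
  }
  exons <- tibble::tibble(
    gene_id = gene_id,
    transcript_id = transcript_id,
    chrom = mat[, 1],
    strand = strand,
    start = start1 - 1L,  # to 0-based half-open
    end = end1
  )
  validate_exon_table(exons)
  dplyr::arrange(exons, .data$chrom, .data$gene_id, .data$transcript_id,
                 .data$start)
}

gtf_attribute <- function(attrs, key) {
  m <- stringr::str_match(attrs, paste0(key, '\\s+"([^"]*)"'))
  m[, 2]
}

empty_exon_table <- function() {
  tibble::tibble(
    gene_id = character(), transcript_id = character(),
    chrom = character(), strand = character(),
    start = integer(), end = integer()
  )
}

#' Validate a tidy exon table
#'
#' Checks the invariants every transcript model must satisfy: 0 <= start < end,
#' strand in {+, -}, one chrom/strand per transcript, and exons of a transcript
#' pairwise disjoint with a gap of at least 1 base between consecutive exons
#' (adjacent exons would denote a zero-length intron).
#'
#' @param exons Exon table as returned by [read_gtf()].
#' @return The input, invisibly, if valid; otherwise an error naming the
#'   offending transcript.
#' @export
validate_exon_table <- function(exons) {
  stopifnot(all(c("gene_id", "transcript_id", "chrom", "strand",
                  "start", "end") %in% names(exons)))
  if (nrow(exons) == 0L) return(invisible(exons))
  if (any(exons$start < 0L) || any(exons$start >= exons$end)) {
    stop("invalid exon interval: need 0 <= start < end", call. = FALSE)
  }
  if (!all(exons$strand %in% c("+", "-"))) {
    stop("transcript exons must be stranded (+ or -); '.' is not allowed",
         call. = FALSE)
  }
  per_tx <- dplyr::group_by(exons, .data$transcript_id)
  bad_meta <- dplyr::filter(
    dplyr::summarise(per_tx,
                     n_chrom = dplyr::n_distinct(.data$chrom),
                     n_strand = dplyr::n_distinct(.data$strand),
                     n_gene = dplyr::n_distinct(.data$gene_id)),
    .data$n_chrom > 1L | .data$n_strand > 1L | .data$n_gene > 1L)
  if (nrow(bad_meta) > 0L) {
    stop("transcript ", bad_meta$transcript_id[1],
         " mixes chromosomes, strands or gene ids", call. = FALSE)
  }
  ordered <- dplyr::arrange(per_tx, .data$start, .by_group = TRUE)
  overlap <- dplyr::filter(
    dplyr::summarise(ordered,
                     ok = all(diff(.data$start) > 0) &&
                       all(utils::head(.data$end, -1) <
                             utils::tail(.data$start, -1)) ||
                       dplyr::n() == 1L),
    !.data$ok)
  if (nrow(overlap) > 0L) {
    stop("transcript ", overlap$transcript_id[1],
         " has overlapping or adjacent exons", call. = FALSE)
  }
  invisible(exons)
}

#' Write transcript models to a GTF file
#'
#' Emits one exon line per row, converting the internal 0-based half-open
#' coordinates back to GTF's 1-based inclusive convention. Attributes are
#' written as `gene_id` then `transcript_id`, and lines are sorted by
#' (chrom, gene_id, transcript_id, start), so `read_gtf(write_gtf(x))` is the
#' identity on the data model.
#'
#' @param exons Exon table (see [read_gtf()]).
#' @param path Output file path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(exons, path, source = "splicediverge") {
  validate_exon_table(exons)
  if (nrow(exons) == 0L) {
    readr::write_lines(character(), path)
    return(invisible(path))
  }
  exons <- dplyr::arrange(exons, .data$chrom, .data$gene_id,
                          .data$transcript_id, .data$start)
  lines <- sprintf(
    '%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    exons$chrom, source, exons$start + 1L, exons$end, exons$strand,
    exons$gene_id, exons$transcript_id)
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' Sequences are upper-cased and keyed by the first whitespace-delimited token
#' of each header.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  is_header <- startsWith(lines, ">")
  if (length(lines) == 0L) return(stats::setNames(character(), character()))
  if (!is_header[1]) stop("FASTA file does not start with a header", call. = FALSE)
  headers <- sub("^>", "", lines[is_header])
  names_ <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(names_)) {
    stop("duplicate FASTA header: ", names_[duplicated(names_)][1], call. = FALSE)
  }
  grp <- cumsum(is_header)
  seqs <- vapply(split(lines[!is_header], grp[!is_header]),
                 paste0, character(1), collapse = "")
  # groups with no sequence lines (trailing empty records) become ""
  out <- stats::setNames(rep("", length(names_)), names_)
  out[as.integer(names(seqs))] <- toupper(seqs)
  stats::setNames(out, names_)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  out <- unlist(purrr::imap(as.list(seqs), function(s, nm) {
    body <- substring(s, seq(1, nchar(s), width),
                      pmin(seq(1, nchar(s), width) + width - 1L, nchar(s)))
    c(paste0(">", nm), body)
  }), use.names = FALSE)
  readr::write_lines(out, path)
  invisible(path)
}

#' Read a BED3+ file
#'
#' BED is already 0-based half-open, so coordinates are preserved without any
#' shift. A fourth column, when present, is kept as `name`; a sixth as
#' `strand` (which may be "." for unstranded features).
#'
#' @param path Path to a BED file.
#' @return Tibble with columns `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer()))
  }
  fields <- stringr::str_split(lines, "\t")
  n <- min(lengths(fields))
  if (n < 3L) stop("BED line with fewer than 3 fields in ", path, call. = FALSE)
  col <- function(i) vapply(fields, `[`, character(1), i)
  out <- tibble::tibble(
    chrom = col(1),
    start = as.integer(col(2)),
    end = as.integer(col(3))
  )
  if (n >= 4L) out$name <- col(4)
  if (n >= 5L) out$score <- suppressWarnings(as.numeric(col(5)))
  if (n >= 6L) out$strand <- col(6)
  if (any(is.na(out$start)) || any(is.na(out$end)) ||
      any(out$start >= out$end) || any(out$start < 0L)) {
    stop("invalid BED interval (need 0 <= start < end) in ", path,
         call. = FALSE)
  }
  out
}

#' Write intervals to a BED file
#'
#' @param x Tibble with `chrom`, `start`, `end` and optional `name`, `score`,
#'   `strand` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- list(x$chrom, x$start, x$end)
  for (extra in c("name", "score", "strand")) {
    if (!is.null(x[[extra]])) cols <- c(cols, list(x[[extra]])) else break
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write a TSV report with commented metadata lines
#'
#' All tabular outputs of the pipeline share this format: optional
#' "#"-prefixed metadata lines followed by a header row and tab-separated
#' records.
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @param meta Character vector of metadata lines (written with a leading
#'   "# ").
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(x, path, meta = character()) {
  con <- file(path, open = "w")
  on.exit(close(con))
  if (length(meta) > 0) writeLines(paste0("# ", meta), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
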