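#' Extract unique splice junctions from transcript models
#'
#' A splice junction is the intron interval excised between a donor and an
#' acceptor site. Junction identity is (chrom, strand, start, end) only:
#' junctions shared across transcripts — and across overlapping genes —
#' collapse to one record.
#'
#' @param exons Exon table.
#' @return Tibble `chrom`, `strand`, `start`, `end`, one row per distinct
#'   junction, sorted by (chrom, start, end).
#' @export
extract_junctions <- function(exons) {
  derive_introns(exons) |>
    dplyr::distinct(.data$chrom, .data$strand, .data$start, .data$end) |>
    dplyr::arrange(.data$chrom, .data$start, .data$end)
}

#' Classify splice-junction boundary dinucleotides
#'
#' Looks up the first and last two intron bases in the genome. On the plus
#' strand GT..AG, GC..AG and AT..AC give the classes GT-AG, GC-AG and AT-AC;
#' everything else is "other". On the minus strand the same rule is applied
#' to the reverse complement of the intron, i.e. the genomic forward-strand
#' sequence reads CT..AC for a GT-AG junction.
#'
#' @param junctions Junction tibble (`chrom`, `strand`, `start`, `end`).
#' @param genome Named character vector of chromosome sequences (see
#'   [read_fasta()]).
#' @return The junction tibble with a `dinuc_class` column added.
#' @export
classify_dinucleotides <- function(junctions, genome) {
  if (nrow(junctions) == 0L) {
    return(dplyr::mutate(junctions, dinuc_class = character()))
  }
  if (any(junctions$end - junctions$start < 4L)) {
    stop("junction shorter than 4 bases cannot carry two dinucleotides",
         call. = FALSE)
  }
  missing_chr <- setdiff(unique(junctions$chrom), names(genome))
  if (length(missing_chr) > 0L) {
    stop("chromosome absent from genome: ", missing_chr[1], call. = FALSE)
  }
  chrom_len <- nchar(genome)[junctions$chrom]
  if (any(junctions$end > chrom_len)) {
    stop("junction beyond chromosome end", call. = FALSE)
  }
  seqs <- genome[junctions$chrom]
  left <- substr(seqs, junctions$start + 1L, junctions$start + 2L)
  right <- substr(seqs, junctions$end - 1L, junctions$end)
  minus <- junctions$strand == "-"
  donor <- ifelse(minus, revcomp(right), left)
  acceptor <- ifelse(minus, revcomp(left), right)
  pair <- paste0(donor, "-", acceptor)
  cls <- dplyr::case_match(pair,
    "GT-AG" ~ "GT-AG",
    "GC-AG" ~ "GC-AG",
    "AT-AC" ~ "AT-AC",
    .default = "other")
  dplyr::mutate(junctions, dinuc_class = cls)
}

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences (ACGTN, any case).
#' @return Reverse complements, upper-cased.
#' @export
revcomp <- function(x) {
  flipped <- chartr("ACGTNacgtn", "TGCANTGCAN", x)
  vapply(strsplit(flipped, NULL),
         function(s) paste(rev(s), collapse = ""), character(1))
}

#' Filter splice junctions by read support
#'
#' Retains junctions supported by strictly more than `min_reads` reads (so
#' the default keeps support >= 11). The strictness mirrors the usual
#' "more than 10 reads" false-discovery screen.
#'
#' @param junctions Junction tibble with a `support` column.
#' @param min_reads Support threshold (exclusive). Default 10.
#' @return The retained junctions.
#' @export
filter_by_support <- function(junctions, min_reads = 10L) {
  if (!"support" %in% names(junctions) || anyNA(junctions$support)) {
    stop("every junction needs a read-support count", call. = FALSE)
  }
  dplyr::filter(junctions, .data$support > min_reads)
}

#' Compare two junction sets
#'
#' Junction identity is (chrom, strand, start, end). Reports shared and
#' group-specific counts with percentages of the union (1 decimal).
#'
#' @param a,b Junction tibbles.
#' @return One-row tibble: `n_a`, `n_b`, `n_union`, `n_shared`, `n_a_only`,
#'   `n_b_only`, `pct_shared`, `pct_a_only`, `pct_b_only`.
#' @export
compare_junction_sets <- function(a, b) {
  key <- function(x) paste(x$chrom, x$strand, x$start, x$end, sep = ":")
  ka <- unique(key(a)); kb <- unique(key(b))
  shared <- length(intersect(ka, kb))
  a_only <- length(setdiff(ka, kb))
  b_only <- length(setdiff(kb, ka))
  n_union <- shared + a_only + b_only
  pct <- function(n) if (n_union == 0L) NA_real_ else round(100 * n / n_union, 1)
  tibble::tibble(
    n_a = length(ka), n_b = length(kb), n_union = n_union,
    n_shared = shared, n_a_only = a_only, n_b_only = b_only,
    pct_shared = pct(shared), pct_a_only = pct(a_only),
    pct_b_only = pct(b_only)
  )
}

#' Summarize junction dinucleotide classes
#'
#' @param junctions Junction tibble with `dinuc_class`.
#' @return Tibble `dinuc_class`, `n`, `pct` (2 decimals, percentages of all
#'   junctions). The "other" class is reported, never dropped.
#' @export
summarize_dinucleotides <- function(junctions) {
  total <- nrow(junctions)
  junctions |>
    dplyr::count(.data$dinuc_class) |>
    dplyr::arrange(dplyr::desc(.data$n)) |>
    dplyr::mutate(pct = round(100 * .data$n / total, 2))
}
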