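#' Read a variant table (TSV or minimal VCF)
#'
#' The primary dialect is a plain TSV with header columns `chrom`, `pos`
#' (0-based), `ref`, `alt`, `qual`, `depth`. Files starting with
#' `##fileformat=VCF` are parsed minimally instead: CHROM, POS (converted
#' from 1-based), REF, ALT, QUAL, and DP from INFO; multi-allelic records
#' are split into one record per ALT allele.
#'
#' @param path Path to the variant file.
#' @return Tibble `chrom`, `pos`, `ref`, `alt`, `qual`, `depth` with a
#'   derived `vclass` column (`"snp"` or `"indel"`).
#' @export
read_variants <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  if (length(first) == 1 && grepl("^##fileformat=VCF", first)) {
    out <- read_vcf_minimal(path)
  } else {
    out <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             chrom = "c", pos = "i", ref = "c", alt = "c",
                             qual = "d", depth = "i"))
  }
  dplyr::mutate(out, vclass = dplyr::if_else(
    nchar(.data$ref) == 1L & nchar(.data$alt) == 1L, "snp", "indel"))
}

read_vcf_minimal <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          qual = numeric(), depth = integer()))
  }
  f <- stringr::str_split(lines, "\t")
  if (any(lengths(f) < 8L)) stop("malformed VCF record", call. = FALSE)
  col <- function(i) vapply(f, `[`, character(1), i)
  dp <- stringr::str_match(col(8), "(?:^|;)DP=([0-9]+)")[, 2]
  out <- tibble::tibble(
    chrom = col(1),
    pos = as.integer(col(2)) - 1L,  # to 0-based
    ref = col(4),
    alt = col(5),
    qual = suppressWarnings(as.numeric(col(6))),
    depth = as.integer(dp)
  )
  tidyr::separate_longer_delim(out, "alt", ",")
}

ensure_vclass <- function(variants) {
  if (!"vclass" %in% names(variants)) {
    variants <- dplyr::mutate(variants, vclass = dplyr::if_else(
      nchar(.data$ref) == 1L & nchar(.data$alt) == 1L, "snp", "indel"))
  }
  variants
}

#' Filter variants to the high-quality set
#'
#' Keeps records with quality strictly above `min_qual` and depth strictly
#' above `min_depth` (defaults: qual > 20 and depth > 15).
#'
#' @param variants Variant tibble (see [read_variants()]).
#' @param min_qual,min_depth Exclusive thresholds.
#' @return The retained variants.
#' @export
filter_high_quality <- function(variants, min_qual = 20, min_depth = 15) {
  if (anyNA(variants$qual) || anyNA(variants$depth)) {
    stop("every variant needs qual and depth", call. = FALSE)
  }
  dplyr::filter(variants, .data$qual > min_qual, .data$depth > min_depth)
}

#' Classify SNPs as transitions or transversions
#'
#' Purine-purine (A<->G) and pyrimidine-pyrimidine (C<->T) substitutions are
#' transitions; the remaining eight base pairs are transversions.
#'
#' @param ref,alt Single-base allele vectors.
#' @return Character vector, `"transition"` or `"transversion"`.
#' @export
classify_snp <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(!ref %in% c("A", "C", "G", "T")) ||
      any(!alt %in% c("A", "C", "G", "T"))) {
    stop("SNP alleles must be single A/C/G/T bases", call. = FALSE)
  }
  if (any(ref == alt)) stop("ref and alt alleles are identical", call. = FALSE)
  purine <- c("A", "G")
  ifelse((ref %in% purine) == (alt %in% purine), "transition", "transversion")
}

#' Transition/transversion ratio
#'
#' @param n_transitions,n_transversions Counts.
#' @return The ratio rounded to 2 decimals; `NA` when there are no
#'   transversions.
#' @export
tstv_ratio <- function(n_transitions, n_transversions) {
  ifelse(n_transversions == 0, NA_real_,
         round(n_transitions / n_transversions, 2))
}

#' Assign variants to exon / intron / intergenic context
#'
#' A position inside any exon of any transcript is `exon`; otherwise inside
#' any gene span it is `intron`; otherwise `intergenic` (precedence
#' exon > intron > intergenic), so every variant gets exactly one label.
#'
#' @param variants Variant tibble with `chrom` and 0-based `pos`.
#' @param exons Exon table of the annotation.
#' @return The variants with a `region` column added.
#' @export
assign_region <- function(variants, exons) {
  spans <- gene_spans(exons)
  region <- purrr::map2_chr(variants$chrom, variants$pos, function(ch, p) {
    in_exon <- any(exons$chrom == ch & exons$start <= p & p < exons$end)
    if (in_exon) return("exon")
    in_gene <- any(spans$chrom == ch & spans$start <= p & p < spans$end)
    if (in_gene) "intron" else "intergenic"
  })
  dplyr::mutate(variants, region = region)
}

#' Signed indel size spectrum
#'
#' Indel size is `nchar(alt) - nchar(ref)` (insertions positive, deletions
#' negative).
#'
#' @param variants Variant tibble.
#' @return List: `sizes` (signed integer vector), `range` (min/max, NULL when
#'   no indels), `spectrum` (tibble `indel_size`, `n`).
#' @export
indel_size_spectrum <- function(variants) {
  ind <- dplyr::filter(ensure_vclass(variants), .data$vclass == "indel")
  sizes <- nchar(ind$alt) - nchar(ind$ref)
  if (any(sizes == 0L)) {
    stop("indel with equal-length ref and alt", call. = FALSE)
  }
  spectrum <- dplyr::count(tibble::tibble(indel_size = sizes),
                           .data$indel_size)
  list(
    sizes = sizes,
    range = if (length(sizes) == 0L) NULL else
      c(min = min(sizes), max = max(sizes)),
    spectrum = spectrum
  )
}

#' Summarize a variant table
#'
#' End-to-end convenience: filters to high quality, classifies SNPs,
#' assigns genomic context, and tabulates.
#'
#' @param variants Variant tibble.
#' @param exons Optional exon table for region assignment.
#' @param min_qual,min_depth Quality filter thresholds (see
#'   [filter_high_quality()]).
#' @return List: `variants` (filtered, annotated), `n_snps`, `n_indels`,
#'   `n_transitions`, `n_transversions`, `tstv`, `region_counts` (when
#'   `exons` supplied), `indel_range`.
#' @export
summarize_variants <- function(variants, exons = NULL, min_qual = 20,
                               min_depth = 15) {
  hq <- filter_high_quality(ensure_vclass(variants), min_qual, min_depth)
  snps <- dplyr::filter(hq, .data$vclass == "snp")
  kind <- if (nrow(snps) > 0L) classify_snp(snps$ref, snps$alt) else character()
  n_ts <- sum(kind == "transition")
  n_tv <- sum(kind == "transversion")
  region_counts <- NULL
  if (!is.null(exons)) {
    hq <- assign_region(hq, exons)
    region_counts <- dplyr::count(hq, .data$region)
  }
  spec <- indel_size_spectrum(hq)
  list(
    variants = hq,
    n_snps = nrow(snps),
    n_indels = sum(hq$vclass == "indel"),
    n_transitions = n_ts,
    n_transversions = n_tv,
    tstv = tstv_ratio(n_ts, n_tv),
    region_counts = region_counts,
    indel_range = spec$range
  )
}
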