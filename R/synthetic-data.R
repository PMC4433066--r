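#' Configuration for the synthetic data generator
#'
#' Builds (and validates) the parameter set controlling a synthetic bundle:
#' two species-group annotation sets over one genome, with a controlled AS
#' type mixture, AS-level divergence between the groups, TE insertions in a
#' fraction of retained introns, junction dinucleotide classes and read
#' support, expression, orthology hit tables and a variant table.
#'
#' Defaults emulate the maize/teosinte study conditions: the AS type mixture
#' is the published maize composition (IR 31.48%, AA 30.75%, AD 14.34%,
#' ES 11.49%, composite 4.53%, other 7.41%); 45.5% / 32.52% of multiexonic
#' genes are alternatively spliced in groups A and B with mean unique events
#' per AS gene 4.12 / 2.26; junction classes GT-AG 96.17%, GC-AG 2.79%,
#' AT-AC 0.51%, other 0.53%; 1.05% of retained introns carry an embedded TE;
#' the SNP transition/transversion ratio is 1.77.
#'
#' @param seed Integer seed; a fixed seed makes the bundle bit-reproducible.
#' @param n_genes Number of gene loci across both groups.
#' @param n_chromosomes Number of chromosomes the loci are spread over.
#' @param n_libs_a,n_libs_b Libraries (GTF files) per group.
#' @param ortholog_fraction Fraction of loci present in both groups.
#' @param exon_count_mean Mean exon count per gene (1 + geometric law).
#' @param exon_len_meanlog,exon_len_sdlog Log-normal exon length law (bp).
#' @param intron_len_meanlog,intron_len_sdlog Log-normal intron length law.
#' @param gc_content Genomic GC proportion.
#' @param as_type_mixture Named proportions over IR, AA, AD, ES, composite,
#'   other; must sum to 1.
#' @param as_gene_fraction_a,as_gene_fraction_b Fraction of multiexonic
#'   genes given extra isoforms in each group.
#' @param events_per_as_gene_a,events_per_as_gene_b Mean unique events per
#'   AS gene (1 + Poisson law).
#' @param gain_fraction Fraction of multiexonic ortholog genes with AS in
#'   group A only.
#' @param fourfold_up_fraction Fraction with a >= 4-fold event-count excess
#'   in group A.
#' @param te_in_ir_fraction Fraction of retained introns receiving an
#'   embedded TE (>= 5 bp inside both boundaries).
#' @param te_straddle If TRUE, additionally plants boundary-crossing TEs
#'   (never counted as contained).
#' @param dinuc_ratios Named proportions over GT-AG, GC-AG, AT-AC, other.
#' @param junction_support_mean,junction_support_dispersion Negative
#'   binomial read-support law (mean, size).
#' @param expression_meanlog,expression_sdlog Log-normal FPKM law.
#' @param de_fraction Fraction of ortholog genes flagged differentially
#'   expressed.
#' @param n_sweep_regions Number of selection-sweep intervals.
#' @param variant_rate Variants per kb of genome.
#' @param tstv Target transition/transversion ratio of planted SNPs.
#' @param indel_fraction Fraction of variants that are indels.
#' @param recurrence_prob Probability that a planted alternative isoform is
#'   annotated in any given library of its group (each isoform is guaranteed
#'   at least one library).
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_genes = 300L,
                             n_chromosomes = 2L,
                             n_libs_a = 10L,
                             n_libs_b = 6L,
                             ortholog_fraction = 0.8,
                             exon_count_mean = 5,
                             exon_len_meanlog = log(150),
                             exon_len_sdlog = 0.6,
                             intron_len_meanlog = log(300),
                             intron_len_sdlog = 0.8,
                             gc_content = 0.47,
                             as_type_mixture = c(IR = 0.3148, AA = 0.3075,
                                                 AD = 0.1434, ES = 0.1149,
                                                 composite = 0.0453,
                                                 other = 0.0741),
                             as_gene_fraction_a = 0.455,
                             as_gene_fraction_b = 0.3252,
                             events_per_as_gene_a = 4.12,
                             events_per_as_gene_b = 2.26,
                             gain_fraction = 0.20,
                             fourfold_up_fraction = 0.05,
                             te_in_ir_fraction = 0.0105,
                             te_straddle = FALSE,
                             dinuc_ratios = c("GT-AG" = 0.9617,
                                              "GC-AG" = 0.0279,
                                              "AT-AC" = 0.0051,
                                              other = 0.0053),
                             junction_support_mean = 50,
                             junction_support_dispersion = 0.5,
                             expression_meanlog = log(10),
                             expression_sdlog = 1,
                             de_fraction = 0.1,
                             n_sweep_regions = 20L,
                             variant_rate = 2,
                             tstv = 1.77,
                             indel_fraction = 0.3,
                             recurrence_prob = 0.8) {
  cfg <- as.list(environment())
  props <- c(cfg$ortholog_fraction, cfg$gc_content, cfg$as_gene_fraction_a,
             cfg$as_gene_fraction_b, cfg$gain_fraction,
             cfg$fourfold_up_fraction, cfg$te_in_ir_fraction,
             cfg$de_fraction, cfg$indel_fraction, cfg$recurrence_prob)
  if (any(props < 0 | props > 1)) {
    stop("all proportions must lie in [0, 1]", call. = FALSE)
  }
  need <- c("IR", "AA", "AD", "ES", "composite", "other")
  if (!setequal(names(cfg$as_type_mixture), need) ||
      abs(sum(cfg$as_type_mixture) - 1) > 1e-9) {
    stop("as_type_mixture must be named over ", paste(need, collapse = ", "),
         " and sum to 1", call. = FALSE)
  }
  if (abs(sum(cfg$dinuc_ratios) - 1) > 1e-9) {
    stop("dinuc_ratios must sum to 1", call. = FALSE)
  }
  ir_capable <- cfg$as_type_mixture[["IR"]] + cfg$as_type_mixture[["composite"]]
  if (cfg$te_in_ir_fraction > 0 && ir_capable == 0) {
    stop("te_in_ir_fraction > 0 requires a nonzero IR/composite mixture share",
         call. = FALSE)
  }
  if (cfg$gain_fraction + cfg$fourfold_up_fraction > cfg$as_gene_fraction_a) {
    stop("gain_fraction + fourfold_up_fraction cannot exceed ",
         "as_gene_fraction_a", call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

# composite subtypes in the proportion of their published shares
composite_split <- c(IR_ALT = 0.0198, IR_DOUBLE = 0.0147, ES_DOUBLE = 0.0108)

sample_event_type <- function(n, mixture, allow_ir_alt = TRUE) {
  sub <- composite_split / sum(composite_split) * mixture[["composite"]]
  w <- c(mixture[c("IR", "AA", "AD", "ES")], sub,
         OTHER = unname(mixture[["other"]]))
  names(w) <- c("IR", "AA", "AD", "ES", names(sub), "OTHER")
  if (!allow_ir_alt) w <- w[names(w) != "IR_ALT"]
  sample(names(w), n, replace = TRUE, prob = w)
}

slots_needed <- function(type) {
  switch(type, IR = 1L, AA = 1L, AD = 1L, OTHER = 1L,
         ES = 2L, IR_DOUBLE = 2L, IR_ALT = 2L, ES_DOUBLE = 3L)
}

#' Plant one AS event onto a base transcript
#'
#' Returns the alternative isoform(s) realizing the requested event type
#' against the base isoform: one isoform for IR, ES, AA, AD, IR_DOUBLE,
#' ES_DOUBLE and OTHER; two isoforms for IR_ALT (one retaining each of two
#' consecutive introns — that type is definable only as a pair). AA/AD
#' boundary shifts are at least 2 bp and the modified isoforms remain valid
#' transcript models.
#'
#' @param base Exon table of a single transcript.
#' @param type One of IR, ES, AD, AA, IR_ALT, IR_DOUBLE, ES_DOUBLE, OTHER.
#' @param slot Intron index at which to plant (1-based, leftmost of the
#'   consumed run); randomly chosen when `NULL`.
#' @return List of exon tables, one per alternative isoform.
#' @export
plant_event <- function(base, type, slot = NULL) {
  base <- dplyr::arrange(base, .data$start)
  m <- cbind(base$start, base$end)
  n <- nrow(m)
  need <- slots_needed(type)
  if (n - 1L < need) {
    stop("transcript has too few introns for a ", type, " event",
         call. = FALSE)
  }
  if (is.null(slot)) slot <- sample.int(n - need, 1L)
  if (slot < 1L || slot + need - 1L > n - 1L) {
    stop("slot out of range for ", type, call. = FALSE)
  }
  mats <- plant_event_at(m, type, slot, base$strand[1])
  purrr::imap(mats, function(mm, k) {
    tibble::tibble(
      gene_id = base$gene_id[1],
      transcript_id = paste0(base$transcript_id[1], ".", type, slot,
                             if (length(mats) > 1L) letters[k] else ""),
      chrom = base$chrom[1], strand = base$strand[1],
      start = as.integer(unname(mm[, 1])), end = as.integer(unname(mm[, 2])))
  })
}

# m: n x 2 exon matrix; slot: leftmost intron index consumed.
# Returns a list of exon matrices (alternative isoforms).
plant_event_at <- function(m, type, slot, strand) {
  n <- nrow(m)
  merge_run <- function(mm, i, j) {
    # merge exons i..j into one (retaining the introns between them)
    keep <- mm[-(i:j), , drop = FALSE]
    merged <- c(mm[i, 1], mm[j, 2])
    out <- rbind(keep, merged)
    out[order(out[, 1]), , drop = FALSE]
  }
  shift_delta <- function(intron_len, exon_len) {
    hi <- min(20L, intron_len - 20L, exon_len - 10L)
    if (hi < 2L) stop("no room for a boundary shift", call. = FALSE)
    sample(2:hi, 1L)
  }
  intron_len <- function(i) m[i + 1L, 1] - m[i, 2]
  switch(type,
    IR = list(merge_run(m, slot, slot + 1L)),
    IR_DOUBLE = list(merge_run(m, slot, slot + 2L)),
    IR_ALT = list(merge_run(m, slot, slot + 1L),
                  merge_run(m, slot + 1L, slot + 2L)),
    ES = {
      # skip the internal exon between introns slot and slot+1
      list(m[-(slot + 1L), , drop = FALSE])
    },
    ES_DOUBLE = {
      list(m[-c(slot + 1L, slot + 2L), , drop = FALSE])
    },
    AD = {
      # donor: intron start on +, intron end on -
      mm <- m
      if (strand == "+") {
        d <- shift_delta(intron_len(slot), m[slot, 2] - m[slot, 1])
        mm[slot, 2] <- mm[slot, 2] + d  # exon grows into the intron
      } else {
        d <- shift_delta(intron_len(slot), m[slot + 1L, 2] - m[slot + 1L, 1])
        mm[slot + 1L, 1] <- mm[slot + 1L, 1] - d
      }
      list(mm)
    },
    AA = {
      mm <- m
      if (strand == "+") {
        d <- shift_delta(intron_len(slot), m[slot + 1L, 2] - m[slot + 1L, 1])
        mm[slot + 1L, 1] <- mm[slot + 1L, 1] - d
      } else {
        d <- shift_delta(intron_len(slot), m[slot, 2] - m[slot, 1])
        mm[slot, 2] <- mm[slot, 2] + d
      }
      list(mm)
    },
    OTHER = {
      # both boundaries move: not one of the named shapes
      mm <- m
      len <- intron_len(slot)
      d1 <- min(5L, (len - 24L) %/% 2L)
      if (d1 < 2L) stop("intron too short for an OTHER plant", call. = FALSE)
      mm[slot, 2] <- mm[slot, 2] + d1
      mm[slot + 1L, 1] <- mm[slot + 1L, 1] - d1
      list(mm)
    },
    stop("unknown event type ", type, call. = FALSE))
}
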