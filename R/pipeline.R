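#' Read a pipeline run configuration from YAML
#'
#' The configuration names all inputs of an end-to-end comparison: the
#' per-library GTFs of the two groups, the genome FASTA, orthology hit
#' tables, expression table, junction-support table, TE and sweep BEDs and a
#' variant table, plus thresholds and a seed. Fields missing from the file
#' keep their defaults.
#'
#' @param path Path to a YAML file.
#' @param overrides Named list overriding fields after reading.
#' @return A list of class `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, c(overrides, cfg[setdiff(names(cfg), names(overrides))]))
}

#' Build a pipeline run configuration
#'
#' @param gtf_a,gtf_b Character vectors of per-library GTF paths for groups
#'   A and B.
#' @param genome_fa Genome FASTA path.
#' @param hits_ab,hits_ba Orthology hit table paths (A->B, B->A).
#' @param expression_tsv Expression table (`gene_id`, `fpkm_a`, `fpkm_b`,
#'   optional `de_flag`).
#' @param junction_support_tsv Junction support table.
#' @param te_bed TE annotation BED (name column "class/type").
#' @param sweeps_bed Selection-region BED.
#' @param variants_tsv Variant table (TSV dialect or minimal VCF).
#' @param outdir Output directory for report TSVs.
#' @param evalue_max,min_reads,fold,lfc_max RBH e-value ceiling, junction
#'   read-support threshold (exclusive), AS-level fold threshold, and
#'   expression log2-fold-change ceiling.
#' @param seed Seed for the saturation resampling.
#' @param ... Ignored (tolerates extra YAML fields).
#' @return A list of class `run_config`.
#' @export
run_config <- function(gtf_a = character(), gtf_b = character(),
                       genome_fa = NULL, hits_ab = NULL, hits_ba = NULL,
                       expression_tsv = NULL, junction_support_tsv = NULL,
                       te_bed = NULL, sweeps_bed = NULL, variants_tsv = NULL,
                       outdir = ".", evalue_max = 1e-10, min_reads = 10,
                       fold = 4, lfc_max = 1, seed = 1L, ...) {
  cfg <- list(gtf_a = gtf_a, gtf_b = gtf_b, genome_fa = genome_fa,
              hits_ab = hits_ab, hits_ba = hits_ba,
              expression_tsv = expression_tsv,
              junction_support_tsv = junction_support_tsv,
              te_bed = te_bed, sweeps_bed = sweeps_bed,
              variants_tsv = variants_tsv, outdir = outdir,
              evalue_max = evalue_max, min_reads = min_reads, fold = fold,
              lfc_max = lfc_max, seed = as.integer(seed))
  if (any(c(evalue_max, min_reads, fold, lfc_max) <= 0)) {
    stop("thresholds must be positive", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Run the end-to-end two-group AS comparison
#'
#' Chains the modules in the order of the study design: orthologs,
#' multiexonic filter, per-library event catalogs, merge, junctions,
#' AS level, expression-matched altered-gene classification, genomic
#' features and TE accounting, variants, and sweep overlap. Writes one TSV
#' per stage plus a `summary.tsv` of headline counts and returns the
#' manifest. The run is a pure function of (inputs, config, seed).
#'
#' @param config A `run_config`.
#' @return Named character vector of written report paths, invisibly;
#'   the computed tables are attached as attribute `results`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  paths <- c(config$gtf_a, config$gtf_b, config$genome_fa, config$hits_ab,
             config$hits_ba, config$expression_tsv,
             config$junction_support_tsv, config$te_bed, config$sweeps_bed,
             config$variants_tsv)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    stop("[input] missing input file: ", missing[1], call. = FALSE)
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- character()
  res <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  emit <- function(x, name, meta = character()) {
    p <- file.path(config$outdir, name)
    write_report_tsv(x, p, meta)
    out[[name]] <<- p
  }

  genome <- stage("genome", read_fasta(config$genome_fa))

  orth <- stage("orthologs", {
    rbh <- reciprocal_best_hits(read_blast_tab(config$hits_ab),
                                read_blast_tab(config$hits_ba),
                                evalue_max = config$evalue_max)
    emit(rbh, "orthologs.tsv",
         paste0("evalue_max=", config$evalue_max))
    rbh
  })

  catalogs <- stage("events", {
    load_group <- function(files, prefix) {
      purrr::imap(
        stats::setNames(files,
                        paste0(prefix, "_", seq_along(files))),
        function(f, nm) {
          ex <- filter_multiexonic(read_gtf(f))
          enumerate_events(ex, library_id = nm)
        })
    }
    list(a = load_group(config$gtf_a, "A"), b = load_group(config$gtf_b, "B"))
  })
  merged_a <- merge_catalogs(catalogs$a)
  merged_b_raw <- merge_catalogs(catalogs$b)
  merged_b <- translate_gene_ids(merged_b_raw, orth)
  emit(dplyr::bind_rows(merged_a, merged_b_raw), "events.tsv")
  types_a <- summarize_types(merged_a)
  types_b <- summarize_types(merged_b_raw)

  junctions <- stage("junctions", {
    exons_a <- dplyr::bind_rows(purrr::map(config$gtf_a, read_gtf))
    exons_b <- dplyr::bind_rows(purrr::map(config$gtf_b, read_gtf))
    ja <- classify_dinucleotides(extract_junctions(exons_a), genome)
    jb <- classify_dinucleotides(extract_junctions(exons_b), genome)
    support <- readr::read_tsv(config$junction_support_tsv,
                               show_col_types = FALSE)
    ja_sup <- dplyr::left_join(
      ja, support[, c("chrom", "strand", "start", "end", "support")],
      by = c("chrom", "strand", "start", "end"))
    ja_kept <- filter_by_support(
      dplyr::mutate(ja_sup,
                    support = dplyr::coalesce(.data$support, 0L)),
      min_reads = config$min_reads)
    emit(ja_sup, "junctions.tsv")
    emit(summarize_dinucleotides(ja), "junction_classes_A.tsv")
    emit(summarize_dinucleotides(jb), "junction_classes_B.tsv")
    cmp <- compare_junction_sets(ja, jb)
    emit(cmp, "junction_comparison.tsv")
    list(a = ja, b = jb, kept = ja_kept, comparison = cmp,
         exons_a = exons_a, exons_b = exons_b)
  })

  aslevel <- stage("aslevel", {
    expr <- readr::read_tsv(config$expression_tsv, show_col_types = FALSE)
    de_genes <- if ("de_flag" %in% names(expr)) {
      expr$gene_id[expr$de_flag == 1]
    } else {
      NULL
    }
    matched <- expression_match(expr, de_genes = de_genes,
                                lfc_max = config$lfc_max)
    matched <- intersect(matched, orth$gene_id)
    cmp <- classify_altered_genes(
      dplyr::semi_join(merged_a, orth, by = "gene_id"),
      merged_b, matched, fold = config$fold)
    rec <- dplyr::left_join(cmp, expr, by = "gene_id")
    emit(rec, "aslevel.tsv",
         c(paste0("fold=", config$fold),
           paste0("as_level_A=", as_level(merged_a)$as_level),
           paste0("as_level_B=", as_level(merged_b_raw)$as_level)))
    cmp
  })

  feats <- stage("features", {
    exons_a <- junctions$exons_a
    fv <- compute_features(filter_multiexonic(exons_a), genome)
    counts <- dplyr::count(merged_a, .data$gene_id, name = "n_events")
    cors <- correlate_features(fv, counts)
    emit(fv, "features.tsv")
    emit(tidy(cors), "correlations.tsv")
    cors
  })

  te <- stage("te", {
    tes <- read_te_bed(config$te_bed)
    ri <- dplyr::distinct(retained_intron_table(merged_a),
                          .data$chrom, .data$start, .data$end)
    rep_ <- te_in_retained_introns(ri, tes)
    emit(rep_$by_type, "te_report.tsv",
         c(paste0("n_retained_introns=", rep_$n_retained_introns),
           paste0("n_introns_with_te=", rep_$n_introns_with_te),
           paste0("pct_introns_with_te=", rep_$pct_introns_with_te)))
    rep_
  })

  improved <- stage("sweeps", {
    sweeps <- read_bed(config$sweeps_bed)
    spans <- gene_spans(junctions$exons_a)
    hits <- intersect_with_regions(aslevel, spans, sweeps)
    emit(hits[, c("gene_id", "status", "fold", "region_start",
                  "region_end")], "improved_genes.tsv")
    hits
  })

  variants <- stage("variants", {
    v <- read_variants(config$variants_tsv)
    vs <- summarize_variants(v, exons = junctions$exons_a)
    emit(tibble::tibble(
      metric = c("n_snps", "n_indels", "n_transitions", "n_transversions",
                 "tstv"),
      value = c(vs$n_snps, vs$n_indels, vs$n_transitions,
                vs$n_transversions, vs$tstv)), "variant_summary.tsv")
    if (!is.null(vs$region_counts)) {
      emit(vs$region_counts, "variant_regions.tsv")
    }
    vs
  })

  sat <- stage("saturate", {
    support <- readr::read_tsv(config$junction_support_tsv,
                               show_col_types = FALSE)
    sc <- saturation_curve(support, n_replicates = 50,
                           detection_min_reads = config$min_reads + 1,
                           seed = config$seed)
    emit(sc, "saturation.tsv")
    sc
  })

  g_a <- as_level(merged_a); g_b <- as_level(merged_b_raw)
  cls <- tidy(aslevel)
  summary <- tibble::tibble(
    metric = c("n_orthologs", "n_as_genes_A", "n_unique_events_A",
               "as_level_A", "n_as_genes_B", "n_unique_events_B",
               "as_level_B", "pct_junctions_shared",
               "n_gained", "n_lost", "n_up_fourfold", "n_down_fourfold",
               "pct_retained_introns_with_te", "tstv"),
    value = c(nrow(orth), g_a$n_as_genes, g_a$n_events, g_a$as_level,
              g_b$n_as_genes, g_b$n_events, g_b$as_level,
              junctions$comparison$pct_shared,
              sum(cls$n_genes[cls$status == "gained"]),
              sum(cls$n_genes[cls$status == "lost"]),
              sum(cls$n_genes[cls$status == "up_fourfold"]),
              sum(cls$n_genes[cls$status == "down_fourfold"]),
              te$pct_introns_with_te, variants$tstv))
  emit(summary, "summary.tsv",
       c(paste0("seed=", config$seed),
         paste0("min_reads=", config$min_reads),
         paste0("evalue_max=", config$evalue_max),
         paste0("fold=", config$fold),
         paste0("lfc_max=", config$lfc_max)))

  res <- list(orthologs = orth, merged_a = merged_a, merged_b = merged_b_raw,
              types_a = types_a, types_b = types_b,
              junctions = junctions[c("comparison")], aslevel = aslevel,
              features = feats, te = te, improved = improved,
              variants = variants, saturation = sat, summary = summary)
  structure(invisible(out), results = res)
}
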