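# Bundle generation: plans gene structures and AS divergence, realizes
# coordinates and isoforms, writes the genome with planted junction
# dinucleotides, TEs, sweeps, expression, junction support, orthology hit
# tables, variants, and a ground-truth record.

#' Generate a complete synthetic input bundle
#'
#' Builds a desk-scale analogue of a two-species comparative AS study: one
#' genome shared by both groups (group B gene models sit at the orthologous
#' loci under their own ids), per-library GTFs with planted AS events,
#' junction dinucleotides written into the genome at the configured class
#' ratios, TEs embedded in a configured fraction of retained introns,
#' selection-sweep regions, an expression table with DE flags, a junction
#' read-support table, reciprocal orthology hit tables with decoys, a
#' variant table with a known transition/transversion composition, and a
#' ground-truth list recording every planted signal.
#'
#' @param config A [synthetic_config()].
#' @param outdir Output directory; when `NULL` nothing is written and the
#'   bundle is only returned in memory.
#' @return A list with the in-memory bundle: `genes`, `exons_a`/`exons_b`
#'   (named lists of per-library exon tables), `genome`, `te`, `sweeps`,
#'   `expression`, `junction_support`, `hits_ab`, `hits_ba`, `variants`,
#'   `truth`, and `manifest` (written file paths, or `NULL`).
#' @export
generate_bundle <- function(config = synthetic_config(), outdir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  plan <- plan_genes(config)
  real <- realize_isoforms(plan, config)
  plan <- real$plan
  libs <- assign_libraries(plan, real$isoforms, config)
  genome <- build_genome(plan, real$isoforms, libs, config)
  te <- plant_tes(real$truth_events, plan, config)
  sweeps <- make_sweeps(genome$chrom_len, config)
  expr <- make_expression(plan, config)
  support <- make_support(libs$all_exons_a, config)
  hits <- make_hit_tables(plan, real$isoforms, config)
  variants <- make_variants(genome$seqs, config)

  truth <- list(
    seed = config$seed,
    n_genes = config$n_genes,
    genes = plan[, c("gene_id", "gene_id_b", "chrom", "strand", "offset",
                     "gene_length", "n_exons", "group", "category",
                     "n_events_a", "n_events_b")],
    multiexonic_orthologs = sum(plan$n_exons >= 2L &
                                  plan$group == "ortholog"),
    events = real$truth_events,
    dinuc_counts = genome$dinuc_counts,
    te = te$truth,
    de_genes = expr$de_genes,
    ortholog_pairs = hits$pairs,
    decoy_pairs = hits$decoys,
    variant_truth = variants$truth
  )

  manifest <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outdir, f)
    write_fasta(genome$seqs, p("genome.fa"))
    for (nm in names(libs$exons_a)) write_gtf(libs$exons_a[[nm]],
                                              p(paste0(nm, ".gtf")))
    for (nm in names(libs$exons_b)) write_gtf(libs$exons_b[[nm]],
                                              p(paste0(nm, ".gtf")))
    write_bed(te$bed, p("te.bed"))
    write_bed(sweeps, p("sweeps.bed"))
    readr::write_tsv(expr$table, p("expression.tsv"))
    readr::write_tsv(support, p("junctions_support.tsv"))
    readr::write_tsv(hits$hits_ab, p("hits_AB.tsv"), col_names = FALSE)
    readr::write_tsv(hits$hits_ba, p("hits_BA.tsv"), col_names = FALSE)
    readr::write_tsv(variants$table, p("variants.tsv"))
    jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "columns")
    manifest <- list.files(outdir, full.names = TRUE)
  }

  list(genes = plan, exons_a = libs$exons_a, exons_b = libs$exons_b,
       genome = genome$seqs, te = te$bed, sweeps = sweeps,
       expression = expr$table, junction_support = support,
       hits_ab = hits$hits_ab, hits_ba = hits$hits_ba,
       variants = variants$table, truth = truth, manifest = manifest)
}

# ---- gene plan --------------------------------------------------------------

plan_genes <- function(cfg) {
  n <- cfg$n_genes
  n_orth <- round(cfg$ortholog_fraction * n)
  rest <- n - n_orth
  group <- sample(c(rep("ortholog", n_orth),
                    rep("A_only", ceiling(rest / 2)),
                    rep("B_only", floor(rest / 2))))
  n_exons <- pmin(1L + stats::rgeom(n, 1 / cfg$exon_count_mean), 12L)
  multi <- n_exons >= 2L

  category <- rep("none", n)
  p_shared <- cfg$as_gene_fraction_a - cfg$gain_fraction -
    cfg$fourfold_up_fraction
  sel <- which(group == "ortholog" & multi)
  category[sel] <- sample(
    c("gained", "up_fourfold", "shared", "none"), length(sel),
    replace = TRUE,
    prob = c(cfg$gain_fraction, cfg$fourfold_up_fraction, p_shared,
             1 - cfg$as_gene_fraction_a))
  sel_a <- which(group == "A_only" & multi)
  category[sel_a] <- ifelse(stats::runif(length(sel_a)) <
                              cfg$as_gene_fraction_a, "a_as", "none")
  sel_b <- which(group == "B_only" & multi)
  category[sel_b] <- ifelse(stats::runif(length(sel_b)) <
                              cfg$as_gene_fraction_b, "b_as", "none")

  pois1 <- function(k, mean) 1L + stats::rpois(k, max(mean - 1, 0))
  n_a <- integer(n); n_b <- integer(n)
  for (i in seq_len(n)) {
    switch(category[i],
      gained = { n_a[i] <- pois1(1, cfg$events_per_as_gene_a) },
      a_as = { n_a[i] <- pois1(1, cfg$events_per_as_gene_a) },
      up_fourfold = { n_b[i] <- 1L; n_a[i] <- 4L + stats::rpois(1, 0.5) },
      shared = { n_a[i] <- pois1(1, cfg$events_per_as_gene_b)
                 n_b[i] <- n_a[i] },
      b_as = { n_b[i] <- pois1(1, cfg$events_per_as_gene_b) })
  }

  tibble::tibble(
    idx = seq_len(n),
    gene_id = sprintf("zm_g%05d", seq_len(n)),
    gene_id_b = dplyr::if_else(group == "A_only", NA_character_,
                               sprintf("tb_g%05d", seq_len(n))),
    chrom = sprintf("chr%d", 1L + (seq_len(n) - 1L) %% cfg$n_chromosomes),
    strand = sample(c("+", "-"), n, replace = TRUE),
    n_exons = n_exons, group = group, category = category,
    n_events_a = n_a, n_events_b = n_b
  )
}

# ---- isoform realization ----------------------------------------------------

realize_isoforms <- function(plan, cfg) {
  n <- nrow(plan)
  isoforms <- vector("list", n)
  truth_rows <- vector("list", n)
  offsets <- stats::setNames(rep(1000L, cfg$n_chromosomes),
                             sprintf("chr%d", seq_len(cfg$n_chromosomes)))
  gene_offset <- integer(n); gene_len <- integer(n)
  for (i in seq_len(n)) {
    k <- max(plan$n_events_a[i], plan$n_events_b[i])
    types <- character(0)
    if (k > 0L) {
      types <- sample_event_type(k, cfg$as_type_mixture,
                                 allow_ir_alt = (k == 1L))
      need <- vapply(types, slots_needed, integer(1))
      # events are separated by an untouched spacer intron so that planted
      # events never interact; cap total gene size, dropping trailing events
      while (sum(need) + length(need) - 1L > 19L) {
        types <- types[-length(types)]
        need <- need[-length(need)]
      }
      k <- length(types)
      plan$n_events_a[i] <- min(plan$n_events_a[i], k)
      plan$n_events_b[i] <- min(plan$n_events_b[i], k)
      n_ex <- max(plan$n_exons[i], sum(need) + k)
    } else {
      n_ex <- plan$n_exons[i]
    }
    plan$n_exons[i] <- n_ex

    exon_len <- pmin(pmax(round(stats::rlnorm(n_ex, cfg$exon_len_meanlog,
                                              cfg$exon_len_sdlog)), 30L),
                     2000L)
    intron_len <- if (n_ex > 1L) {
      pmin(pmax(round(stats::rlnorm(n_ex - 1L, cfg$intron_len_meanlog,
                                    cfg$intron_len_sdlog)), 60L), 5000L)
    } else {
      integer(0)
    }
    starts <- cumsum(c(0L, utils::head(exon_len, -1L) + intron_len))
    base <- cbind(starts, starts + exon_len)

    iso <- list(t1 = base)
    ev_iso <- list()
    slot_ptr <- 1L
    slot_of <- integer(k)
    for (j in seq_len(k)) {
      mats <- plant_event_at(base, types[j], slot_ptr, plan$strand[i])
      nm <- if (length(mats) == 2L) paste0("e", j, c("a", "b")) else
        paste0("e", j)
      names(mats) <- nm
      ev_iso[[j]] <- nm
      iso <- c(iso, mats)
      slot_of[j] <- slot_ptr
      slot_ptr <- slot_ptr + slots_needed(types[j]) + 1L  # skip a spacer
    }
    # a gene whose single event is IR_ALT carries no fully spliced base
    drop_base <- k == 1L && length(types) == 1L && types[1] == "IR_ALT"
    if (drop_base) iso <- iso[names(iso) != "t1"]

    off <- offsets[[plan$chrom[i]]]
    gene_offset[i] <- off
    glen <- base[n_ex, 2]
    gene_len[i] <- glen
    offsets[[plan$chrom[i]]] <- off + glen + sample(300:1000, 1L)
    iso <- lapply(iso, function(m) m + off)

    isoforms[[i]] <- list(iso = iso, event_isoforms = ev_iso,
                          types = types, drop_base = drop_base)
    if (k > 0L) {
      ri <- lapply(seq_len(k), function(j) {
        s <- slot_of[j]
        ints <- cbind(base[, 2][s:(s + slots_needed(types[j]) - 1L)],
                      base[, 1][(s + 1L):(s + slots_needed(types[j]))]) + off
        switch(types[j],
          IR = ints[1, , drop = FALSE],
          IR_DOUBLE = ints[1:2, , drop = FALSE],
          IR_ALT = ints[1:2, , drop = FALSE],
          NULL)
      })
      truth_rows[[i]] <- tibble::tibble(
        gene_id = plan$gene_id[i],
        gene_id_b = plan$gene_id_b[i],
        event_index = seq_len(k),
        event_type = types,
        in_a = seq_len(k) <= plan$n_events_a[i],
        in_b = seq_len(k) <= plan$n_events_b[i],
        retained_introns = vapply(ri, function(m) {
          if (is.null(m)) NA_character_ else
            paste(paste0(m[, 1], "-", m[, 2]), collapse = ";")
        }, character(1)),
        clean = TRUE
      )
    }
  }
  plan$offset <- gene_offset
  plan$gene_length <- gene_len
  truth_events <- dplyr::bind_rows(truth_rows)
  if (nrow(truth_events) > 0L) {
    truth_events <- dplyr::left_join(
      truth_events,
      plan[, c("gene_id", "chrom", "strand")], by = "gene_id")
  }
  list(plan = plan, isoforms = isoforms, truth_events = truth_events)
}

# ---- libraries --------------------------------------------------------------

exon_tibble <- function(plan_row, iso, gene_id, keep) {
  mats <- iso$iso[keep]
  if (length(mats) == 0L) return(NULL)
  nr <- vapply(mats, nrow, integer(1))
  tibble::tibble(
    gene_id = gene_id,
    transcript_id = rep(paste0(gene_id, ".", names(mats)), nr),
    chrom = plan_row$chrom, strand = plan_row$strand,
    start = as.integer(unlist(lapply(mats, function(m) m[, 1]))),
    end = as.integer(unlist(lapply(mats, function(m) m[, 2])))
  )
}

assign_libraries <- function(plan, isoforms, cfg) {
  inclusion <- function(n_events, n_libs) {
    if (n_events == 0L) return(matrix(logical(), 0L, n_libs))
    m <- matrix(stats::runif(n_events * n_libs) < cfg$recurrence_prob,
                n_events, n_libs)
    for (j in seq_len(n_events)) {
      if (!any(m[j, ])) m[j, sample.int(n_libs, 1L)] <- TRUE
    }
    m
  }
  libs_a <- stats::setNames(
    vector("list", cfg$n_libs_a),
    sprintf("groupA_lib%d", seq_len(cfg$n_libs_a)))
  libs_b <- stats::setNames(
    vector("list", cfg$n_libs_b),
    sprintf("groupB_lib%d", seq_len(cfg$n_libs_b)))
  per_lib_a <- lapply(seq_len(cfg$n_libs_a), function(x) list())
  per_lib_b <- lapply(seq_len(cfg$n_libs_b), function(x) list())

  for (i in seq_len(nrow(plan))) {
    iso <- isoforms[[i]]
    in_a <- plan$group[i] %in% c("ortholog", "A_only")
    in_b <- plan$group[i] %in% c("ortholog", "B_only")
    inc_a <- inclusion(plan$n_events_a[i], cfg$n_libs_a)
    inc_b <- inclusion(plan$n_events_b[i], cfg$n_libs_b)
    if (in_a) {
      for (l in seq_len(cfg$n_libs_a)) {
        keep <- c(if (!iso$drop_base) "t1",
                  unlist(iso$event_isoforms[which(inc_a[, l])]))
        tb <- exon_tibble(plan[i, ], iso, plan$gene_id[i], keep)
        if (!is.null(tb)) per_lib_a[[l]][[length(per_lib_a[[l]]) + 1L]] <- tb
      }
    }
    if (in_b) {
      for (l in seq_len(cfg$n_libs_b)) {
        keep <- c(if (!iso$drop_base) "t1",
                  unlist(iso$event_isoforms[which(inc_b[, l])]))
        tb <- exon_tibble(plan[i, ], iso, plan$gene_id_b[i], keep)
        if (!is.null(tb)) per_lib_b[[l]][[length(per_lib_b[[l]]) + 1L]] <- tb
      }
    }
  }
  for (l in seq_along(libs_a)) libs_a[[l]] <- dplyr::bind_rows(per_lib_a[[l]])
  for (l in seq_along(libs_b)) libs_b[[l]] <- dplyr::bind_rows(per_lib_b[[l]])

  list(exons_a = libs_a, exons_b = libs_b,
       all_exons_a = dplyr::bind_rows(libs_a))
}

# ---- genome with planted junction dinucleotides -----------------------------

build_genome <- function(plan, isoforms, libs, cfg) {
  chrom_len <- tapply(plan$offset + plan$gene_length + 1000L, plan$chrom, max)
  chrom_len <- chrom_len[sprintf("chr%d", seq_len(cfg$n_chromosomes))]
  bases <- c("A", "C", "G", "T")
  probs <- c((1 - cfg$gc_content) / 2, cfg$gc_content / 2,
             cfg$gc_content / 2, (1 - cfg$gc_content) / 2)
  seqs <- vapply(chrom_len, function(L) {
    paste(sample(bases, L, replace = TRUE, prob = probs), collapse = "")
  }, character(1))

  # all junctions across both groups' isoforms
  all_ex <- dplyr::bind_rows(c(libs$exons_a, libs$exons_b))
  jx <- extract_junctions(all_ex)
  n <- nrow(jx)
  counts <- diff(round(cumsum(c(0, cfg$dinuc_ratios)) * n))
  names(counts) <- names(cfg$dinuc_ratios)

  # minority classes only on junctions sharing no boundary site with any
  # other junction, so planted bases never conflict
  donor_key <- paste(jx$chrom, jx$start)
  acc_key <- paste(jx$chrom, jx$end)
  lonely <- !(donor_key %in% donor_key[duplicated(donor_key)]) &
    !(acc_key %in% acc_key[duplicated(acc_key)])
  cls <- rep("GT-AG", n)
  minority <- setdiff(names(counts), "GT-AG")
  pool <- which(lonely)
  for (mc in minority) {
    take <- min(counts[[mc]], length(pool))
    if (take > 0L) {
      sel <- sample(pool, take)
      cls[sel] <- mc
      pool <- setdiff(pool, sel)
    }
  }
  jx$dinuc_class <- cls

  dinuc <- list("GT-AG" = c("GT", "AG"), "GC-AG" = c("GC", "AG"),
                "AT-AC" = c("AT", "AC"), other = c("CT", "GC"))
  seq_chars <- lapply(seqs, function(s) strsplit(s, NULL)[[1]])
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (r in seq_len(n)) {
    d <- dinuc[[cls[r]]]
    ch <- jx$chrom[r]
    s <- jx$start[r]; e <- jx$end[r]
    if (jx$strand[r] == "+") {
      seq_chars[[ch]][(s + 1):(s + 2)] <- strsplit(d[1], NULL)[[1]]
      seq_chars[[ch]][(e - 1):e] <- strsplit(d[2], NULL)[[1]]
    } else {
      seq_chars[[ch]][(s + 1):(s + 2)] <-
        rev(comp[strsplit(d[2], NULL)[[1]]])
      seq_chars[[ch]][(e - 1):e] <- rev(comp[strsplit(d[1], NULL)[[1]]])
    }
  }
  seqs <- vapply(seq_chars, paste, character(1), collapse = "")
  list(seqs = seqs, chrom_len = chrom_len,
       dinuc_counts = as.list(table(cls)))
}

# ---- TE / sweeps / expression / support -------------------------------------

te_type_weights <- tibble::tibble(
  te_class = c("I", "I", "I", "I", "II", "II", "II", "II", "II"),
  te_type = c("Copia", "Gypsy", "unknown_I", "LINE", "hAT", "Helitron",
              "En-spm", "Stowaway", "other_II"),
  w = c(11, 11, 2, 30, 14, 19, 5, 5, 6))

plant_tes <- function(truth_events, plan, cfg) {
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), name = character())
  if (nrow(truth_events) == 0L) {
    return(list(bed = empty, truth = list(n_te = 0L, straddle = 0L)))
  }
  ri <- truth_events |>
    dplyr::filter(!is.na(.data$retained_introns), .data$in_a | .data$in_b) |>
    dplyr::mutate(ri = strsplit(.data$retained_introns, ";")) |>
    tidyr::unnest_longer("ri") |>
    tidyr::separate_wider_delim("ri", "-", names = c("start", "end")) |>
    dplyr::transmute(.data$chrom,
                     start = as.integer(.data$start),
                     end = as.integer(.data$end)) |>
    dplyr::distinct()
  n_te <- round(cfg$te_in_ir_fraction * nrow(ri))
  rows <- list(); truth_te <- list()
  if (n_te > 0L) {
    sel <- ri[sample.int(nrow(ri), n_te), ]
    for (r in seq_len(nrow(sel))) {
      s <- sel$start[r]; e <- sel$end[r]
      max_len <- (e - 5L) - (s + 5L)
      te_len <- min(sample(20:40, 1L), max_len)
      te_s <- s + 5L + sample.int(max(1L, max_len - te_len + 1L), 1L) - 1L
      tt <- te_type_weights[sample.int(nrow(te_type_weights), 1L,
                                       prob = te_type_weights$w), ]
      rows[[r]] <- tibble::tibble(
        chrom = sel$chrom[r], start = te_s, end = te_s + te_len,
        name = paste0(tt$te_class, "/", tt$te_type))
      truth_te[[r]] <- tibble::tibble(
        intron_start = s, intron_end = e, chrom = sel$chrom[r],
        te_start = te_s, te_end = te_s + te_len,
        te_class = tt$te_class, te_type = tt$te_type)
    }
  }
  n_straddle <- 0L
  if (cfg$te_straddle && nrow(ri) > n_te) {
    left <- ri[setdiff(seq_len(nrow(ri)), seq_len(0)), ]
    pool <- left[sample.int(nrow(left), min(3L, nrow(left))), ]
    for (r in seq_len(nrow(pool))) {
      s <- pool$start[r]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        chrom = pool$chrom[r], start = s - 15L, end = s + 15L,
        name = "II/straddle")
      n_straddle <- n_straddle + 1L
    }
  }
  bed <- if (length(rows) > 0L) dplyr::bind_rows(rows) else empty
  list(bed = bed,
       truth = list(n_te = n_te, straddle = n_straddle,
                    n_retained_introns = nrow(ri),
                    records = dplyr::bind_rows(truth_te)))
}

make_sweeps <- function(chrom_len, cfg) {
  k <- cfg$n_sweep_regions
  chrom <- sample(names(chrom_len), k, replace = TRUE)
  len <- sample(2000:10000, k, replace = TRUE)
  start <- vapply(seq_len(k), function(i) {
    sample.int(max(1L, chrom_len[[chrom[i]]] - len[i]), 1L) - 1L
  }, integer(1))
  tibble::tibble(chrom = chrom, start = start, end = start + len,
                 name = sprintf("sweep%02d", seq_len(k))) |>
    dplyr::arrange(.data$chrom, .data$start)
}

make_expression <- function(plan, cfg) {
  orth <- dplyr::filter(plan, .data$group == "ortholog")
  n <- nrow(orth)
  base <- stats::rlnorm(n, cfg$expression_meanlog, cfg$expression_sdlog)
  fpkm_a <- round(base * stats::rlnorm(n, 0, 0.2), 3)
  fpkm_b <- round(base * stats::rlnorm(n, 0, 0.2), 3)
  de <- stats::runif(n) < cfg$de_fraction
  fpkm_a[de] <- round(fpkm_a[de] * 2^sample(2:4, sum(de), replace = TRUE), 3)
  list(
    table = tibble::tibble(gene_id = orth$gene_id, fpkm_a = fpkm_a,
                           fpkm_b = fpkm_b, de_flag = as.integer(de)),
    de_genes = orth$gene_id[de]
  )
}

make_support <- function(all_exons_a, cfg) {
  jx <- derive_introns(all_exons_a) |>
    dplyr::group_by(.data$chrom, .data$strand, .data$start, .data$end) |>
    dplyr::summarise(gene_id = dplyr::first(.data$gene_id),
                     .groups = "drop") |>
    dplyr::arrange(.data$chrom, .data$start, .data$end)
  jx$support <- stats::rnbinom(nrow(jx), mu = cfg$junction_support_mean,
                               size = cfg$junction_support_dispersion)
  jx
}

# ---- orthology hit tables ---------------------------------------------------

blast_row <- function(q, s, pid, len, ev) {
  tibble::tibble(
    query_id = q, subject_id = s, percent_identity = round(pid, 2),
    alignment_length = len, mismatches = round(len * (100 - pid) / 100),
    gap_opens = 0L, q_start = 1L, q_end = len, s_start = 1L, s_end = len,
    evalue = ev, bitscore = len * 2)
}

make_hit_tables <- function(plan, isoforms, cfg) {
  orth <- dplyr::filter(plan, .data$group == "ortholog")
  a_only <- dplyr::filter(plan, .data$group == "A_only")
  b_only <- dplyr::filter(plan, .data$group == "B_only")
  len_of <- function(i) {
    m <- isoforms[[i]]$iso[[1]]
    as.integer(sum(m[, 2] - m[, 1]))
  }
  lens <- vapply(plan$idx, len_of, integer(1))

  no <- nrow(orth)
  ab <- list(); ba <- list()
  if (no > 0L) {
    li <- lens[orth$idx]
    ev_fwd <- 10^-stats::runif(no, 30, 120)
    ab[[1]] <- blast_row(orth$gene_id, orth$gene_id_b,
                         stats::runif(no, 96, 99.9), li, ev_fwd)
    ba[[1]] <- blast_row(orth$gene_id_b, orth$gene_id,
                         stats::runif(no, 96, 99.9), li,
                         10^-stats::runif(no, 30, 120))
    # weaker secondary hits to wrong partners
    sec <- which(stats::runif(no) < 0.3)
    if (length(sec) > 0L && no > 1L) {
      other <- vapply(sec, function(r) {
        sample(setdiff(seq_len(no), r), 1L)
      }, integer(1))
      ab[[2]] <- blast_row(orth$gene_id[sec], orth$gene_id_b[other],
                           stats::runif(length(sec), 80, 90),
                           pmax(50L, li[sec] %/% 2L), ev_fwd[sec] * 1e6)
    }
  }
  # non-reciprocal decoys: one-directional best hits from group-specific
  # genes (the first A-only/B-only genes are reserved for the high-evalue
  # mutual pair below)
  a_dec <- a_only[-1, , drop = FALSE]
  b_dec <- b_only[-1, , drop = FALSE]
  if (nrow(a_dec) > 0L && no > 0L) {
    tgt <- sample.int(no, nrow(a_dec), replace = TRUE)
    ab[[length(ab) + 1L]] <- blast_row(
      a_dec$gene_id, orth$gene_id_b[tgt],
      stats::runif(nrow(a_dec), 90, 95), lens[a_dec$idx],
      10^-stats::runif(nrow(a_dec), 20, 40))
  }
  if (nrow(b_dec) > 0L && no > 0L) {
    tgt <- sample.int(no, nrow(b_dec), replace = TRUE)
    ba[[length(ba) + 1L]] <- blast_row(
      b_dec$gene_id_b, orth$gene_id[tgt],
      stats::runif(nrow(b_dec), 90, 95), lens[b_dec$idx],
      10^-stats::runif(nrow(b_dec), 20, 40))
  }
  # mutually-best pair above the e-value ceiling: must be rejected
  decoys <- NULL
  if (nrow(a_only) > 0L && nrow(b_only) > 0L) {
    qa <- a_only$gene_id[1]; qb <- b_only$gene_id_b[1]
    ab[[length(ab) + 1L]] <- blast_row(qa, qb, 85, 60L, 1e-6)
    ba[[length(ba) + 1L]] <- blast_row(qb, qa, 85, 60L, 1e-6)
    decoys <- tibble::tibble(gene_id = qa, unigene_id = qb,
                             reason = "evalue_above_threshold")
  }
  list(hits_ab = dplyr::bind_rows(ab), hits_ba = dplyr::bind_rows(ba),
       pairs = orth[, c("gene_id", "gene_id_b")] |>
         dplyr::rename(unigene_id = "gene_id_b"),
       decoys = decoys)
}

# ---- variants ---------------------------------------------------------------

make_variants <- function(seqs, cfg) {
  ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
  tv1 <- c(A = "C", G = "C", C = "A", T = "A")
  tv2 <- c(A = "T", G = "T", C = "G", T = "G")
  per_chrom <- lapply(names(seqs), function(ch) {
    L <- nchar(seqs[[ch]])
    n_var <- round(cfg$variant_rate * L / 1000)
    if (n_var == 0L) return(NULL)
    pos <- sort(sample.int(L - 100L, n_var)) - 1L  # 0-based
    ref1 <- substring(seqs[[ch]], pos + 1L, pos + 1L)
    hq <- stats::runif(n_var) < 0.75
    qual <- round(ifelse(hq, stats::runif(n_var, 20.5, 60),
                         stats::runif(n_var, 1, 20)), 1)
    depth <- ifelse(hq, sample(16:80, n_var, replace = TRUE),
                    sample(1:15, n_var, replace = TRUE))
    is_indel <- stats::runif(n_var) < cfg$indel_fraction
    is_ts <- !is_indel & stats::runif(n_var) < cfg$tstv / (1 + cfg$tstv)
    sz <- sample.int(20L, n_var, replace = TRUE) *
      sample(c(-1L, 1L), n_var, replace = TRUE)
    ref <- ref1
    alt <- ifelse(is_ts, ts_partner[ref1],
                  ifelse(stats::runif(n_var) < 0.5, tv1[ref1], tv2[ref1]))
    ins <- is_indel & sz > 0L
    del <- is_indel & sz < 0L
    if (any(ins)) {
      alt[ins] <- paste0(ref1[ins], vapply(sz[ins], function(k) {
        paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
              collapse = "")
      }, character(1)))
    }
    if (any(del)) {
      ref[del] <- substring(seqs[[ch]], pos[del] + 1L,
                            pos[del] + 1L - sz[del])
      alt[del] <- ref1[del]
    }
    list(table = tibble::tibble(chrom = ch, pos = pos, ref = ref, alt = alt,
                                qual = qual, depth = depth),
         n_ts = sum(is_ts & hq), n_tv = sum(!is_indel & !is_ts & hq),
         n_ind = sum(is_indel & hq))
  })
  per_chrom <- purrr::compact(per_chrom)
  list(table = dplyr::bind_rows(purrr::map(per_chrom, "table")),
       truth = list(
         n_transitions_hq = sum(purrr::map_int(per_chrom, "n_ts")),
         n_transversions_hq = sum(purrr::map_int(per_chrom, "n_tv")),
         n_indels_hq = sum(purrr::map_int(per_chrom, "n_ind"))))
}

#' Read a TE annotation BED whose name column encodes "class/type"
#'
#' @param path BED file with a name column like `"I/Copia"` or
#'   `"II/Helitron"`.
#' @return Tibble `chrom`, `start`, `end`, `te_class`, `te_type`.
#' @export
read_te_bed <- function(path) {
  bed <- read_bed(path)
  if (nrow(bed) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), te_class = character(),
                          te_type = character()))
  }
  if (!"name" %in% names(bed)) {
    stop("TE BED needs a name column encoding class/type", call. = FALSE)
  }
  tidyr::separate_wider_delim(bed, "name", "/",
                              names = c("te_class", "te_type"),
                              too_few = "align_start")
}
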