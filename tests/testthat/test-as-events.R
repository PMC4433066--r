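mk_tx <- function(starts, ends, id = "t1", gene = "g1", strand = "+",
                  chrom = "chr1") {
  tibble::tibble(gene_id = gene, transcript_id = id, chrom = chrom,
                 strand = strand, start = as.integer(starts),
                 end = as.integer(ends))
}

test_that("derive_introns returns the gaps between consecutive exons", {
  tx <- mk_tx(c(0, 200), c(100, 300))
  introns <- derive_introns(tx)
  expect_equal(introns$start, 100L)
  expect_equal(introns$end, 200L)

  expect_equal(nrow(derive_introns(mk_tx(0, 100))), 0L)

  # tiling: exons + introns cover the span exactly
  tx4 <- mk_tx(c(0, 150, 400, 900), c(100, 300, 800, 1000))
  introns4 <- derive_introns(tx4)
  expect_equal(nrow(introns4), 3L)
  covered <- sum(tx4$end - tx4$start) + sum(introns4$end - introns4$start)
  expect_equal(covered, 1000L)
})

test_that("filter_multiexonic keeps genes with any >= 2-exon transcript", {
  mono <- mk_tx(0, 100, gene = "mono")
  mixed <- dplyr::bind_rows(mk_tx(0, 100, id = "m1", gene = "mix"),
                            mk_tx(c(0, 200), c(100, 300), id = "m2",
                                  gene = "mix"))
  out <- filter_multiexonic(dplyr::bind_rows(mono, mixed))
  expect_identical(unique(out$gene_id), "mix")
})

test_that("identical transcripts yield no events; IR is called as defined", {
  two_same <- dplyr::bind_rows(mk_tx(c(0, 200), c(100, 300), id = "t1"),
                               mk_tx(c(0, 200), c(100, 300), id = "t2"))
  expect_equal(nrow(enumerate_gene_events(two_same)), 0L)

  ir <- dplyr::bind_rows(mk_tx(c(0, 200), c(100, 300), id = "t1"),
                         mk_tx(0, 300, id = "t2"))
  ev <- enumerate_gene_events(ir)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$event_type, "IR")
  expect_equal(ev$retained_introns, "100-200")
})

test_that("transcripts on different strands are rejected", {
  bad <- dplyr::bind_rows(mk_tx(c(0, 200), c(100, 300), id = "t1"),
                          mk_tx(0, 300, id = "t2", strand = "-"))
  expect_error(enumerate_gene_events(bad), "strand")
})

test_that("classify_event implements the two-chain rule table", {
  expect_equal(classify_event(list(".", "100-200")), "IR")
  expect_equal(classify_event(list("100-200", "100-210")), "AA")
  expect_equal(classify_event(list("100-200", "110-200")), "AD")
  expect_equal(classify_event(list("100-200,250-400", "100-400")), "ES")
  expect_equal(classify_event(list(".", "100-200,300-400")), "IR_DOUBLE")
  expect_equal(classify_event(list("100-200", "300-400")), "IR_ALT")
  expect_equal(classify_event(list("100-150,200-250,300-400", "100-400")),
               "ES_DOUBLE")
  expect_equal(classify_event(list("100-200", "110-190")), "OTHER")
})

test_that("donor/acceptor semantics mirror on the minus strand", {
  # same end, different start: donor difference on +, acceptor on -
  expect_equal(classify_event(list("100-200", "110-200"), strand = "+"), "AD")
  expect_equal(classify_event(list("100-200", "110-200"), strand = "-"), "AA")
  expect_equal(classify_event(list("100-200", "100-210"), strand = "-"), "AD")
})

test_that("three or more chains need unanimous simple pairwise calls", {
  expect_equal(classify_event(list("100-200", "100-210", "100-220")), "AA")
  expect_equal(classify_event(list(".", "100-200", "100-210")), "OTHER")
})

test_that("random chain pairs match an independent rule-table oracle", {
  set.seed(11)
  for (i in 1:200) {
    n1 <- sample(0:3, 1); n2 <- sample(1:3, 1)
    mk_chain <- function(n) {
      if (n == 0) return(data.frame(start = integer(0), end = integer(0)))
      s <- sort(sample(seq(100, 900, by = 10), 2 * n))
      data.frame(start = s[seq(1, 2 * n, 2)], end = s[seq(2, 2 * n, 2)])
    }
    c1 <- mk_chain(n1); c2 <- mk_chain(n2)
    ser <- function(d) if (nrow(d) == 0) "." else
      paste(paste0(d$start, "-", d$end), collapse = ",")
    if (ser(c1) == ser(c2)) next
    got <- classify_event(list(ser(c1), ser(c2)))
    expect_equal(got, oracle_classify_pair_plus(c1, c2),
                 label = paste(ser(c1), "vs", ser(c2)))
  }
})

test_that("gene event sets equal the brute-force pairwise oracle", {
  set.seed(23)
  for (i in 1:200) {
    g <- random_gene(n_iso = sample(2:5, 1))
    got <- enumerate_gene_events(g)
    want <- oracle_gene_events(g)
    if (nrow(got) == 0L) {
      expect_equal(nrow(want), 0L)
      next
    }
    key <- function(d) {
      sort(paste(d$flank_left, d$flank_right, d$chains, d$event_type))
    }
    expect_identical(key(got), key(want), label = paste("gene rep", i))
  }
})

test_that("event enumeration is invariant under coordinate translation and
           transcript order", {
  set.seed(5)
  g <- random_gene(n_iso = 4)
  ev <- enumerate_gene_events(g)
  shifted <- dplyr::mutate(g, start = start + 5000L, end = end + 5000L)
  ev_shift <- enumerate_gene_events(shifted)
  expect_equal(ev_shift$event_type, ev$event_type)
  expect_equal(ev_shift$flank_left, ev$flank_left + 5000L)

  reord <- dplyr::arrange(g, dplyr::desc(transcript_id), start)
  expect_setequal(enumerate_gene_events(reord)$signature, ev$signature)
})

test_that("merge_catalogs unions by signature and tracks totals", {
  g <- dplyr::bind_rows(mk_tx(c(0, 200), c(100, 300), id = "t1"),
                        mk_tx(0, 300, id = "t2"))
  c1 <- enumerate_events(g, "lib1")
  c2 <- enumerate_events(g, "lib2")
  m <- merge_catalogs(c1, c2)
  expect_equal(attr(m, "n_unique"), 1L)
  expect_equal(attr(m, "n_total"), 2L)

  # disjoint catalogs add up
  g2 <- dplyr::bind_rows(
    mk_tx(c(0, 200), c(100, 300), id = "t1", gene = "g2"),
    mk_tx(c(0, 210), c(100, 300), id = "t2", gene = "g2"))
  m2 <- merge_catalogs(c1, enumerate_events(g2, "lib2"))
  expect_equal(attr(m2, "n_unique"), 2L)

  # random catalogs: merged size equals a brute-force signature union
  set.seed(31)
  cats <- lapply(1:4, function(l) {
    genes <- dplyr::bind_rows(lapply(1:6, function(i) {
      random_gene(gene_id = sprintf("g%d", i))
    }))
    enumerate_events(genes, paste0("lib", l))
  })
  merged <- merge_catalogs(cats)
  brute <- unique(unlist(lapply(cats, function(cc) {
    paste(cc$gene_id, cc$signature)
  })))
  expect_equal(attr(merged, "n_unique"), length(brute))
})

test_that("summarize_types reports percentages and events per gene", {
  teo <- tibble::tibble(
    event_type = c("IR", "ES", "AD", "AA", "IR_ALT", "IR_DOUBLE",
                   "ES_DOUBLE", "OTHER"),
    n = c(5424L, 2482L, 2602L, 6129L, 558L, 148L, 249L, 1467L))
  s <- summarize_types(teo)
  expect_equal(s$pct[s$event_type == "AA"], 32.16)
  expect_equal(attr(s, "n_events"), 19059L)

  one <- summarize_types(tibble::tibble(event_type = "IR", n = 7L))
  expect_equal(one$pct, 100)

  empty <- summarize_types(tibble::tibble(event_type = character(),
                                          n = integer()))
  expect_equal(nrow(empty), 0L)

  expect_equal(events_per_gene(22574, 5479), 4.12)
})
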