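mk_tx <- function(starts, ends, id = "t1", gene = "g1", strand = "+",
                  chrom = "chr1") {
  tibble::tibble(gene_id = gene, transcript_id = id, chrom = chrom,
                 strand = strand, start = as.integer(starts),
                 end = as.integer(ends))
}

test_that("junctions deduplicate across isoforms and genes", {
  ex <- dplyr::bind_rows(
    mk_tx(c(0, 200), c(100, 300), id = "t1"),
    mk_tx(c(0, 200), c(100, 320), id = "t2"),
    mk_tx(c(0, 200), c(100, 300), id = "t3", gene = "g2"))
  j <- extract_junctions(ex)
  expect_equal(nrow(j), 1L)
  expect_equal(j$start, 100L)

  expect_equal(nrow(extract_junctions(mk_tx(0, 100))), 0L)

  # set oracle on a random bundle
  set.seed(3)
  genes <- dplyr::bind_rows(lapply(1:10, function(i) {
    random_gene(gene_id = sprintf("g%d", i))
  }))
  j2 <- extract_junctions(genes)
  brute <- unique(apply(as.data.frame(derive_introns(genes)), 1,
                        function(r) paste(r["chrom"], r["strand"],
                                          r["start"], r["end"])))
  expect_equal(nrow(j2), length(brute))
})

test_that("dinucleotide classes follow the strand-aware boundary rule", {
  #            0123456789...
  genome <- c(chr1 = "AAAGTTTTTTAGAAA")  # intron [3,12) = GTTTTTTAG? no:
  # intron [3,12): bases 4..12 -> GTTTTTTAG; first two GT, last two AG
  j_plus <- tibble::tibble(chrom = "chr1", strand = "+", start = 3L,
                           end = 12L)
  expect_equal(classify_dinucleotides(j_plus, genome)$dinuc_class, "GT-AG")

  # minus strand: genomic CT..AC reads GT..AG after reverse complement
  genome2 <- c(chr1 = "AAACTTTTTTACAAA")
  j_minus <- dplyr::mutate(j_plus, strand = "-")
  expect_equal(classify_dinucleotides(j_minus, genome2)$dinuc_class, "GT-AG")

  # GC-AG, AT-AC and fallthrough
  expect_equal(
    classify_dinucleotides(j_plus, c(chr1 = "AAAGCTTTTTAGAAA"))$dinuc_class,
    "GC-AG")
  expect_equal(
    classify_dinucleotides(j_plus, c(chr1 = "AAAATTTTTTACAAA"))$dinuc_class,
    "AT-AC")
  expect_equal(
    classify_dinucleotides(j_plus, c(chr1 = "AAACCTTTTTCCAAA"))$dinuc_class,
    "other")

  expect_error(
    classify_dinucleotides(dplyr::mutate(j_plus, end = 99L), genome),
    "beyond")
})

test_that("classification is mirror-consistent under strand flip", {
  set.seed(9)
  for (i in 1:20) {
    L <- 40L
    seq_fwd <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                     collapse = "")
    j <- tibble::tibble(chrom = "c", strand = "+", start = 10L, end = 30L)
    cls_fwd <- classify_dinucleotides(j, c(c = seq_fwd))$dinuc_class
    # flip the genome and the junction
    seq_rev <- revcomp(seq_fwd)
    j_rev <- tibble::tibble(chrom = "c", strand = "-",
                            start = L - 30L, end = L - 10L)
    cls_rev <- classify_dinucleotides(j_rev, c(c = seq_rev))$dinuc_class
    expect_equal(cls_rev, cls_fwd)
  }
})

test_that("planted dinucleotide classes are recovered exactly", {
  b <- small_bundle()
  exons <- dplyr::bind_rows(c(b$exons_a, b$exons_b))
  j <- classify_dinucleotides(extract_junctions(exons), b$genome)
  got <- table(j$dinuc_class)
  want <- b$truth$dinuc_counts
  for (cls in names(want)) {
    expect_equal(unname(got[[cls]]), want[[cls]], label = cls)
  }
})

test_that("support filter is strictly greater-than", {
  js <- tibble::tibble(chrom = "c", strand = "+", start = c(0, 10, 20),
                       end = c(8, 18, 28), support = c(10L, 11L, 0L))
  kept <- filter_by_support(js)
  expect_equal(kept$support, 11L)
  expect_error(filter_by_support(dplyr::select(js, -support)), "support")

  set.seed(2)
  js2 <- tibble::tibble(chrom = "c", strand = "+",
                        start = seq(0, 990, 10), end = seq(5, 995, 10),
                        support = rpois(100, 12))
  expect_equal(nrow(filter_by_support(js2, 10)), sum(js2$support > 10))
})

test_that("junction set comparison percentages are over the union", {
  a <- tibble::tibble(chrom = "c", strand = "+", start = c(0, 10),
                      end = c(8, 18))
  expect_equal(compare_junction_sets(a, a)$pct_shared, 100)

  b <- tibble::tibble(chrom = "c", strand = "+", start = 100, end = 108)
  cmp <- compare_junction_sets(a, b)
  expect_equal(cmp$pct_shared, 0)
  expect_equal(cmp$n_union, cmp$n_shared + cmp$n_a_only + cmp$n_b_only)
})

test_that("class percentages sum to 100 within rounding", {
  b <- small_bundle()
  exons <- dplyr::bind_rows(b$exons_a)
  s <- summarize_dinucleotides(
    classify_dinucleotides(extract_junctions(exons), b$genome))
  expect_lt(abs(sum(s$pct) - 100), 0.05)
})
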