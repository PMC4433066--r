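mk_catalog <- function(gene_ids) {
  # one synthetic event record per entry; repeated gene ids = several events
  tibble::tibble(
    gene_id = gene_ids, chrom = "chr1", strand = "+",
    flank_left = seq_along(gene_ids) * 100L,
    flank_right = seq_along(gene_ids) * 100L + 50L,
    event_type = "IR", chains = ".",
    retained_introns = NA_character_,
    signature = paste0("sig", seq_along(gene_ids)),
    library_id = "lib1")
}

test_that("as_level is unique events over AS genes, 2 decimals", {
  cat1 <- mk_catalog(c("g1", "g1", "g1", "g2"))
  lvl <- as_level(cat1)
  expect_equal(lvl$as_level, 2)
  expect_equal(as_level(mk_catalog("g1"))$as_level, 1)
  expect_true(is.na(as_level(mk_catalog(character()))$as_level))

  # brute-force average on random catalogs
  set.seed(8)
  ids <- sample(paste0("g", 1:20), 100, replace = TRUE)
  expect_equal(as_level(mk_catalog(ids))$as_level,
               round(100 / length(unique(ids)), 2))

  expect_equal(events_per_gene(22574, 5479), 4.12)
})

test_that("expression matching excludes DE genes or large fold changes", {
  expr <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                         fpkm_a = c(10, 100, 5), fpkm_b = c(10, 1, 4))
  expect_setequal(expression_match(expr), c("g1", "g3"))
  expect_setequal(expression_match(expr, de_genes = "g3"), c("g1", "g2"))
  expect_error(expression_match(dplyr::mutate(expr, fpkm_a = -1)), ">= 0")

  b <- small_bundle()
  matched <- expression_match(b$expression, de_genes = b$truth$de_genes)
  expect_setequal(matched, setdiff(b$expression$gene_id, b$truth$de_genes))
})

test_that("altered-gene statuses follow presence/absence and fold rules", {
  ca <- mk_catalog(c(rep("gained", 3), rep("up", 8), rep("flat", 3)))
  cb <- mk_catalog(c(rep("up", 2), rep("flat", 1)))
  rec <- classify_altered_genes(ca, cb, c("gained", "up", "flat", "noas"))
  st <- stats::setNames(rec$status, rec$gene_id)
  expect_equal(unname(st["gained"]), "gained")
  expect_equal(unname(st["up"]), "up_fourfold")      # 8 vs 2
  expect_equal(unname(st["flat"]), "unchanged")      # 3 vs 1, below 4-fold
  expect_equal(unname(st["noas"]), "unchanged")

  # below-threshold ratio stays unchanged; non-matched genes are excluded
  rec2 <- classify_altered_genes(mk_catalog(rep("g", 3)),
                                 mk_catalog("g"), character())
  expect_equal(rec2$status, "excluded_expression")
})

test_that("every matched gene gets exactly one status and counts add up", {
  b <- small_bundle()
  cats_a <- purrr::imap(b$exons_a,
                        ~ enumerate_events(filter_multiexonic(.x), .y))
  cats_b <- purrr::imap(b$exons_b,
                        ~ enumerate_events(filter_multiexonic(.x), .y))
  orth <- reciprocal_best_hits(b$hits_ab, b$hits_ba)
  ma <- dplyr::semi_join(merge_catalogs(cats_a), orth, by = "gene_id")
  mb <- translate_gene_ids(merge_catalogs(cats_b), orth)
  matched <- expression_match(b$expression, de_genes = b$truth$de_genes)
  rec <- classify_altered_genes(ma, mb, matched)
  expect_equal(anyDuplicated(rec$gene_id), 0L)
  g <- glance(rec)
  expect_equal(g$n_gained + g$n_lost + g$n_up_fourfold + g$n_down_fourfold +
                 g$n_unchanged, g$n_matched)
  expect_equal(g$n_matched, length(intersect(matched, rec$gene_id)))
})

test_that("swapping the two groups maps gained<->lost and up<->down", {
  b <- small_bundle()
  cats_a <- purrr::imap(b$exons_a,
                        ~ enumerate_events(filter_multiexonic(.x), .y))
  cats_b <- purrr::imap(b$exons_b,
                        ~ enumerate_events(filter_multiexonic(.x), .y))
  orth <- reciprocal_best_hits(b$hits_ab, b$hits_ba)
  ma <- dplyr::semi_join(merge_catalogs(cats_a), orth, by = "gene_id")
  mb <- translate_gene_ids(merge_catalogs(cats_b), orth)
  matched <- expression_match(b$expression, de_genes = b$truth$de_genes)
  fwd <- classify_altered_genes(ma, mb, matched)
  rev <- classify_altered_genes(mb, ma, matched)
  map <- c(gained = "lost", lost = "gained", up_fourfold = "down_fourfold",
           down_fourfold = "up_fourfold", unchanged = "unchanged",
           excluded_expression = "excluded_expression")
  joined <- dplyr::inner_join(fwd, rev, by = "gene_id",
                              suffix = c("_f", "_r"))
  expect_equal(unname(map[joined$status_f]), joined$status_r)
})

test_that("classification is invariant to library and merge order", {
  b <- small_bundle()
  cats_a <- purrr::imap(b$exons_a,
                        ~ enumerate_events(filter_multiexonic(.x), .y))
  orth <- reciprocal_best_hits(b$hits_ab, b$hits_ba)
  matched <- expression_match(b$expression, de_genes = b$truth$de_genes)
  mb <- translate_gene_ids(
    merge_catalogs(purrr::imap(b$exons_b,
                               ~ enumerate_events(filter_multiexonic(.x),
                                                  .y))), orth)
  m1 <- dplyr::semi_join(merge_catalogs(cats_a), orth, by = "gene_id")
  m2 <- dplyr::semi_join(merge_catalogs(rev(cats_a)), orth, by = "gene_id")
  r1 <- classify_altered_genes(m1, mb, matched)
  r2 <- classify_altered_genes(m2, mb, matched)
  expect_equal(dplyr::as_tibble(r1[, c("gene_id", "status")]),
               dplyr::as_tibble(r2[, c("gene_id", "status")]))
})

test_that("gene-region overlap is >= 1 bp of the gene span", {
  rec <- classify_altered_genes(mk_catalog(c("g1", "g2")),
                                mk_catalog(character()), c("g1", "g2"))
  spans <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1",
                          start = c(100L, 1000L), end = c(200L, 1100L))
  regions <- tibble::tibble(chrom = "chr1", start = 150L, end = 400L)
  hit <- intersect_with_regions(rec, spans, regions)
  expect_equal(hit$gene_id, "g1")

  # brute-force oracle on random spans/regions
  set.seed(12)
  genes <- sprintf("g%03d", 1:60)
  spans2 <- tibble::tibble(
    gene_id = genes, chrom = sample(c("c1", "c2"), 60, TRUE),
    start = sample(0:5000, 60), end = 0L)
  spans2$end <- spans2$start + sample(100:800, 60, TRUE)
  regions2 <- tibble::tibble(chrom = sample(c("c1", "c2"), 15, TRUE),
                             start = sample(0:5000, 15), end = 0L)
  regions2$end <- regions2$start + sample(200:1500, 15, TRUE)
  rec2 <- classify_altered_genes(mk_catalog(genes),
                                 mk_catalog(character()), genes)
  got <- intersect_with_regions(rec2, spans2, regions2)$gene_id
  brute <- genes[vapply(seq_len(60), function(i) {
    any(regions2$chrom == spans2$chrom[i] &
          regions2$start < spans2$end[i] &
          regions2$end > spans2$start[i])
  }, logical(1))]
  expect_setequal(got, brute)
})

test_that("planted gain and fourfold fractions are recovered", {
  b <- small_bundle()
  cats_a <- purrr::imap(b$exons_a,
                        ~ enumerate_events(filter_multiexonic(.x), .y))
  cats_b <- purrr::imap(b$exons_b,
                        ~ enumerate_events(filter_multiexonic(.x), .y))
  orth <- reciprocal_best_hits(b$hits_ab, b$hits_ba)
  ma <- dplyr::semi_join(merge_catalogs(cats_a), orth, by = "gene_id")
  mb <- translate_gene_ids(merge_catalogs(cats_b), orth)
  rec <- classify_altered_genes(ma, mb, b$expression$gene_id)
  truth <- b$genes[b$genes$group == "ortholog", ]
  expect_setequal(rec$gene_id[rec$status == "gained"],
                  truth$gene_id[truth$category == "gained" &
                                  truth$n_events_a > 0])
  expect_setequal(rec$gene_id[rec$status == "up_fourfold"],
                  truth$gene_id[truth$category == "up_fourfold"])
  expect_setequal(rec$gene_id[rec$status == "unchanged"],
                  truth$gene_id[truth$category %in% c("shared", "none")])
})
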