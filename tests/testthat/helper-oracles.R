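# Independent naive reimplementations used as oracles. These deliberately
# share no code with the package internals: plain loops, explicit case
# analysis, string-free interval handling.

# introns of one transcript as a data.frame(start, end), from an exon df
oracle_introns <- function(ex) {
  ex <- ex[order(ex$start), ]
  n <- nrow(ex)
  if (n < 2) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = ex$end[1:(n - 1)], end = ex$start[2:n])
}

# classify one pair of intron data.frames (plus-oriented already)
oracle_classify_pair_plus <- function(i1, i2) {
  key <- function(d) paste(d$start, d$end, sep = "_")
  shared <- intersect(key(i1), key(i2))
  r1 <- i1[!key(i1) %in% shared, , drop = FALSE]
  r2 <- i2[!key(i2) %in% shared, , drop = FALSE]
  if (nrow(r1) > nrow(r2)) { tmp <- r1; r1 <- r2; r2 <- tmp }
  a <- nrow(r1); b <- nrow(r2)
  if (a == 0 && b == 1) return("IR")
  if (a == 0 && b == 2) return("IR_DOUBLE")
  if (a == 1 && b == 1) {
    if (r1$end == r2$end && r1$start != r2$start) return("AD")
    if (r1$start == r2$start && r1$end != r2$end) return("AA")
    if (r1$end < r2$start || r2$end < r1$start) return("IR_ALT")
    return("OTHER")
  }
  if (a == 1 && b == 2) {
    if (r2$start[1] == r1$start && r2$end[2] == r1$end &&
        r2$end[1] < r2$start[2]) return("ES")
    return("OTHER")
  }
  if (a == 1 && b == 3) {
    if (r2$start[1] == r1$start && r2$end[3] == r1$end &&
        r2$end[1] < r2$start[2] && r2$end[2] < r2$start[3]) {
      return("ES_DOUBLE")
    }
    return("OTHER")
  }
  "OTHER"
}

mirror_df <- function(d) {
  out <- data.frame(start = -d$end, end = -d$start)
  out[order(out$start), , drop = FALSE]
}

# all events between two transcripts of one gene, naive version
oracle_pair_events <- function(ex1, ex2, strand) {
  i1 <- oracle_introns(ex1); i2 <- oracle_introns(ex2)
  w_lo <- max(min(ex1$start), min(ex2$start))
  w_hi <- min(max(ex1$end), max(ex2$end))
  if (w_lo >= w_hi) return(NULL)
  sites1 <- unique(c(i1$start, i1$end))
  sites2 <- unique(c(i2$start, i2$end))
  cuts <- sort(intersect(sites1, sites2))
  cuts <- cuts[cuts > w_lo & cuts < w_hi]
  bounds <- c(w_lo, cuts, w_hi)
  events <- list()
  for (s in seq_len(length(bounds) - 1)) {
    lo <- bounds[s]; hi <- bounds[s + 1]
    grab <- function(d) {
      touching <- d$start < hi & d$end > lo
      inside <- d$start >= lo & d$end <= hi
      if (any(touching & !inside)) return("straddle")
      d[inside, , drop = FALSE]
    }
    c1 <- grab(i1); c2 <- grab(i2)
    if (identical(c1, "straddle") || identical(c2, "straddle")) next
    ser <- function(d) {
      if (nrow(d) == 0) "." else
        paste(paste0(d$start, "-", d$end), collapse = ",")
    }
    if (ser(c1) == ser(c2)) next
    p1 <- if (strand == "-") mirror_df(c1) else c1
    p2 <- if (strand == "-") mirror_df(c2) else c2
    events[[length(events) + 1]] <- list(
      flank_left = lo, flank_right = hi,
      chains = paste(sort(c(ser(c1), ser(c2))), collapse = "|"),
      type = oracle_classify_pair_plus(p1, p2))
  }
  events
}

# full-gene event set: loop over all transcript pairs, union by
# (flanks, chains) key
oracle_gene_events <- function(exons) {
  txs <- split(as.data.frame(exons), exons$transcript_id)
  strand <- exons$strand[1]
  seen <- new.env()
  out <- list()
  ids <- names(txs)
  if (length(ids) < 2) return(data.frame())
  for (i in 1:(length(ids) - 1)) {
    for (j in (i + 1):length(ids)) {
      evs <- oracle_pair_events(txs[[ids[i]]], txs[[ids[j]]], strand)
      for (e in evs) {
        k <- paste(e$flank_left, e$flank_right, e$chains)
        if (!is.null(seen[[k]])) next
        seen[[k]] <- TRUE
        out[[length(out) + 1]] <- data.frame(
          flank_left = e$flank_left, flank_right = e$flank_right,
          chains = e$chains, event_type = e$type)
      }
    }
  }
  if (length(out) == 0) return(data.frame())
  do.call(rbind, out)
}

# random multi-isoform gene for property tests
random_gene <- function(gene_id = "g1", n_iso = sample(2:5, 1),
                        n_exons = sample(3:7, 1), chrom = "chr1",
                        strand = sample(c("+", "-"), 1)) {
  exon_len <- sample(50:200, n_exons, replace = TRUE)
  intron_len <- sample(60:300, n_exons - 1, replace = TRUE)
  starts <- cumsum(c(100, head(exon_len, -1) + intron_len))
  base <- data.frame(start = starts, end = starts + exon_len)
  isoforms <- list(base)
  types <- c("IR", "ES", "AD", "AA", "IR_DOUBLE", "ES_DOUBLE", "OTHER")
  for (k in seq_len(n_iso - 1)) {
    ty <- sample(types, 1)
    tb <- tibble::tibble(gene_id = gene_id, transcript_id = "b",
                         chrom = chrom, strand = strand,
                         start = base$start, end = base$end)
    iso <- tryCatch(plant_event(tb, ty)[[1]],
                    error = function(e) NULL)
    if (is.null(iso)) next
    isoforms[[length(isoforms) + 1]] <- data.frame(start = iso$start,
                                                   end = iso$end)
  }
  dplyr::bind_rows(purrr::imap(isoforms, function(d, k) {
    tibble::tibble(gene_id = gene_id,
                   transcript_id = paste0(gene_id, ".t", k),
                   chrom = chrom, strand = strand,
                   start = d$start, end = d$end)
  }))
}

# small deterministic bundle shared by several test files
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(seed = 42L, n_genes = 150L, n_libs_a = 3L,
                              n_libs_b = 2L)
      cache <<- generate_bundle(cfg)
    }
    cache
  }
})
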