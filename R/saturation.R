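#' Binomially thin read-support counts
#'
#' Models a shallower sequencing run by retaining each supporting read
#' independently with probability `fraction`; `fraction = 1` returns the
#' input unchanged.
#'
#' @param support Tibble with a `support` count column (typically also
#'   `gene_id` and an event/junction key).
#' @param fraction Retention probability in (0, 1].
#' @return The table with `support` replaced by the thinned counts.
#' @export
subsample_support <- function(support, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  if (fraction == 1) return(support)
  dplyr::mutate(support,
                support = stats::rbinom(dplyr::n(), .data$support, fraction))
}

#' Saturation of AS detection with sequencing depth
#'
#' For every depth fraction and replicate, the per-event read support is
#' binomially thinned, an event counts as detected iff its thinned support
#' reaches `detection_min_reads` (default 11, i.e. the "more than 10 reads"
#' junction screen), and the detected AS genes are the genes with at least
#' one detected event. Depth is modelled as read thinning of the full-depth
#' support table rather than re-running assembly per sub-library.
#'
#' @param support Tibble `gene_id`, `support` (one row per event or
#'   junction).
#' @param fractions Grid of depth fractions; the default's nine points play
#'   the role of 0.5-4.5 Gb sub-libraries of a 4.5 Gb run.
#' @param n_replicates Replicates per fraction (default 50).
#' @param detection_min_reads Minimal thinned support for detection.
#' @param seed Optional integer seed for reproducibility.
#' @return Tibble of class `saturation_curve`: `depth_fraction`,
#'   `replicate`, `n_as_genes`, `n_as_events`, `mean_gene_coverage`
#'   (thinned reads per gene), ordered by fraction then replicate.
#' @export
saturation_curve <- function(support, fractions = (1:9) / 9,
                             n_replicates = 50, detection_min_reads = 11,
                             seed = NULL) {
  if (any(fractions <= 0 | fractions > 1)) {
    stop("fractions must be in (0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  grid <- tidyr::expand_grid(depth_fraction = sort(fractions),
                             replicate = seq_len(n_replicates))
  res <- purrr::pmap(grid, function(depth_fraction, replicate) {
    thinned <- subsample_support(support, depth_fraction)
    det <- thinned$support >= detection_min_reads
    tibble::tibble(
      n_as_genes = dplyr::n_distinct(thinned$gene_id[det]),
      n_as_events = sum(det),
      mean_gene_coverage = sum(thinned$support) /
        max(1L, dplyr::n_distinct(thinned$gene_id))
    )
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(res))
  class(out) <- c("saturation_curve", class(out))
  attr(out, "detection_min_reads") <- detection_min_reads
  out
}

#' @export
tidy.saturation_curve <- function(x, ...) {
  dplyr::as_tibble(x) |>
    dplyr::group_by(.data$depth_fraction) |>
    dplyr::summarise(
      mean_as_genes = mean(.data$n_as_genes),
      sd_as_genes = stats::sd(.data$n_as_genes),
      mean_as_events = mean(.data$n_as_events),
      sd_as_events = stats::sd(.data$n_as_events),
      .groups = "drop")
}

#' @export
glance.saturation_curve <- function(x, ...) {
  means <- tidy.saturation_curve(x)
  top2 <- utils::tail(means$mean_as_events, 2)
  tibble::tibble(
    n_fractions = nrow(means),
    n_replicates = max(x$replicate),
    max_mean_events = max(means$mean_as_events),
    plateau_relative_gain = if (length(top2) == 2 && top2[1] > 0) {
      (top2[2] - top2[1]) / top2[1]
    } else {
      NA_real_
    }
  )
}
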