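# Single-stranded transcribing (SST) enhancer classification. An active
# enhancer is SST when its ssDNA density is at least fold_min times the
# pooled density of its equal-width flanking shores AND a one-way ANOVA
# across the three regions (enhancer, left shore, right shore), with
# per-bin RPKM values as observations, gives p <= alpha. Elongation
# pass-through signal is uniform across element and shores and fails both.

#' Classical one-way fixed-effects ANOVA
#'
#' Computed from the between/within sums of squares:
#' `F = (SSB / (k - 1)) / (SSW / (N - k))`, p from the F distribution.
#' Degenerate cases: all observations identical gives `F = 0, p = 1`;
#' perfect separation (SSW = 0, SSB > 0) gives `F = Inf, p = 0`.
#'
#' @param groups List of >= 2 numeric vectors, each of length >= 2.
#' @return One-row tibble: `f`, `p`, `df_between`, `df_within`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) abort("one_way_anova: need at least 2 groups")
  if (any(lengths(groups) < 2)) abort("one_way_anova: every group needs >= 2 observations")
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(unlist(groups)) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (ssb == 0 && ssw == 0) {
    return(tibble(f = 0, p = 1, df_between = k - 1, df_within = N - k))
  }
  if (ssw == 0) {
    return(tibble(f = Inf, p = 0, df_between = k - 1, df_within = N - k))
  }
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  tibble(f = f, p = pf(f, k - 1, N - k, lower.tail = FALSE),
         df_between = k - 1, df_within = N - k)
}

# per-bin RPKM observations inside [start, end): bins tiled from start at
# density_bin bp; a short trailing bin keeps its actual width (RPKM
# normalizes by width so groups stay comparable after clipping)
region_bin_densities <- function(tags_gr, chrom, start, end, density_bin, library_size) {
  bs <- seq(start, end - 1, by = density_bin)
  be <- pmin(bs + density_bin, end)
  bins <- GenomicRanges::GRanges(chrom, IRanges::IRanges(bs + 1L, be))
  counts <- GenomicRanges::countOverlaps(bins, tags_gr, ignore.strand = TRUE)
  counts * 1e9 / ((be - bs) * library_size)
}

#' Call SST enhancers against their shores
#'
#' For each pre-defined active enhancer: build equal-width shores
#' ([make_shores()]), take per-`density_bin` RPKM values in the enhancer
#' and each shore as the three ANOVA groups, compute the fold enrichment
#' (enhancer mean over pooled shore mean), and label the enhancer `SST`
#' when `fold >= fold_min` and ANOVA `p <= alpha` with both shores usable;
#' otherwise `non-SST`. Enhancers narrower than two bins or with an
#' unusable shore are labeled `unusable`.
#'
#' @param enhancers Enhancer interval tibble (distal H3K27ac peaks or
#'   similar).
#' @param tags Tag tibble.
#' @param chrom_sizes Chromosome sizes tibble.
#' @param library_size Library size for RPKM (default `nrow(tags)`).
#' @param density_bin Observation bin width in bp (default 50).
#' @param fold_min Fold-enrichment threshold (default 1.5).
#' @param alpha ANOVA p-value threshold (default 0.05).
#' @return Tibble with enhancer and shore coordinates, `d_enhancer`,
#'   `d_left`, `d_right`, `fold_enrichment`, `f_stat`, `p_value`, `label`.
#' @export
call_sst_enhancers <- function(enhancers, tags, chrom_sizes, library_size = nrow(tags),
                               density_bin = 50, fold_min = 1.5, alpha = 0.05) {
  enhancers <- validate_intervals(enhancers, chrom_sizes = chrom_sizes, what = "enhancers")
  if (library_size <= 0) abort("call_sst_enhancers: library size must be positive")
  sh <- make_shores(enhancers[c("chrom", "start", "end")], chrom_sizes)
  tags_gr <- as_granges(validate_intervals(tags, what = "tags"))

  res <- purrr::pmap(sh, function(chrom, start, end, left_start, left_end, left_usable,
                                  right_start, right_end, right_usable, ...) {
    width <- end - start
    row <- tibble(
      chrom = chrom, start = start, end = end,
      left_start = left_start, left_end = left_end,
      right_start = right_start, right_end = right_end,
      d_enhancer = NA_real_, d_left = NA_real_, d_right = NA_real_,
      fold_enrichment = NA_real_, f_stat = NA_real_, p_value = NA_real_,
      label = "unusable"
    )
    if (width < 2 * density_bin || !left_usable || !right_usable) return(row)
    g_enh <- region_bin_densities(tags_gr, chrom, start, end, density_bin, library_size)
    g_left <- region_bin_densities(tags_gr, chrom, left_start, left_end, density_bin, library_size)
    g_right <- region_bin_densities(tags_gr, chrom, right_start, right_end, density_bin, library_size)
    if (length(g_left) < 2 || length(g_right) < 2) return(row)
    an <- one_way_anova(list(g_enh, g_left, g_right))
    row$d_enhancer <- mean(g_enh)
    row$d_left <- mean(g_left)
    row$d_right <- mean(g_right)
    shore_mean <- mean(c(g_left, g_right))
    row$fold_enrichment <- if (shore_mean > 0) mean(g_enh) / shore_mean else Inf
    row$f_stat <- an$f
    row$p_value <- an$p
    row$label <- if (row$fold_enrichment >= fold_min && an$p <= alpha) "SST" else "non-SST"
    row
  })
  dplyr::bind_rows(res)
}
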