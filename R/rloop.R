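# R-loop detection from strand-specific (spKAS-seq) tags. Windows tiled
# over spKAS peaks are tested for strand imbalance: with replicates, a
# negative-binomial Wald test (median-of-ratios size factors,
# method-of-moments dispersion shrunk toward a mean-dispersion trend);
# with a single replicate, an exact binomial test. Significant windows
# (BH-adjusted p <= alpha) are merged per dominant strand into R-loop
# regions, which can then be screened for RNase H sensitivity.

#' Tile fixed-size windows over peaks
#'
#' Windows are tiled from each peak start at `step` bp and truncated at the
#' peak end; a trailing window is kept iff its width is at least `size / 2`.
#' Windows duplicated across overlapping peaks are emitted once.
#'
#' @param peaks Peak interval tibble.
#' @param size Window size in bp (default 500).
#' @param step Step in bp, `0 < step <= size` (default 500, non-overlapping).
#' @return Window tibble (`chrom`, `start`, `end`), sorted.
#' @export
tile_windows <- function(peaks, size = 500, step = 500) {
  stopifnot(size > 0, step > 0, step <= size)
  peaks <- validate_intervals(peaks, what = "peaks")
  if (nrow(peaks) == 0) return(tibble(chrom = character(), start = integer(), end = integer()))
  parts <- purrr::pmap(peaks[c("chrom", "start", "end")], function(chrom, start, end) {
    ws <- seq(start, end - 1, by = step)
    we <- pmin(ws + size, end)
    keep <- (we - ws) >= size / 2
    tibble(chrom = chrom, start = ws[keep], end = we[keep])
  })
  out <- dplyr::distinct(dplyr::bind_rows(parts))
  out[order(out$chrom, out$start, out$end), ]
}

#' Per-window strand-specific replicate counts
#'
#' Counts, for each window, the tags overlapping it by >= 1 bp, separately
#' per strand and per replicate.
#'
#' @param windows Window tibble.
#' @param plus_tags,minus_tags Lists of tag tibbles, one element per
#'   replicate (same replicate count on both strands).
#' @return A `kas_stranded_windows` tibble: window coordinates plus
#'   `plus_1..plus_r` and `minus_1..minus_r` count columns. Per-replicate
#'   library sizes (plus + minus tags) are stored in the `lib_sizes`
#'   attribute.
#' @export
count_strands <- function(windows, plus_tags, minus_tags) {
  if (!is.list(plus_tags) || is.data.frame(plus_tags)) plus_tags <- list(plus_tags)
  if (!is.list(minus_tags) || is.data.frame(minus_tags)) minus_tags <- list(minus_tags)
  if (length(plus_tags) != length(minus_tags)) {
    abort("count_strands: replicate count mismatch between strands")
  }
  windows <- validate_intervals(windows, what = "windows")
  wgr <- as_granges(windows[c("chrom", "start", "end")])
  count_one <- function(tags) {
    if (nrow(tags) == 0) return(integer(length(wgr)))
    GenomicRanges::countOverlaps(wgr, as_granges(tags), ignore.strand = TRUE)
  }
  out <- windows[c("chrom", "start", "end")]
  for (i in seq_along(plus_tags)) out[[paste0("plus_", i)]] <- count_one(plus_tags[[i]])
  for (i in seq_along(minus_tags)) out[[paste0("minus_", i)]] <- count_one(minus_tags[[i]])
  attr(out, "n_reps") <- length(plus_tags)
  attr(out, "lib_sizes") <- list(
    plus = vapply(plus_tags, nrow, numeric(1)),
    minus = vapply(minus_tags, nrow, numeric(1))
  )
  class(out) <- c("kas_stranded_windows", class(out))
  out
}

#' Median-of-ratios size factors
#'
#' Per-window geometric mean across samples (windows containing any zero
#' are excluded); each sample's size factor is the median over windows of
#' its count divided by that geometric mean.
#'
#' @param counts Numeric matrix, windows x samples.
#' @return Positive size factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  all_pos <- rowSums(counts <= 0) == 0
  if (!any(all_pos)) {
    abort("size_factors: no window with all-positive counts; consider adding a pseudo-count")
  }
  log_geo <- rowMeans(log(counts[all_pos, , drop = FALSE]))
  apply(counts[all_pos, , drop = FALSE], 2, function(col) median(exp(log(col) - log_geo)))
}

#' Exact binomial strand-imbalance test for one window
#'
#' Two-sided exact binomial test of the pooled plus count against the
#' pooled total, under the library-size-adjusted expected plus fraction.
#' The log2 fold change uses a half-integer pseudo-count and is centred on
#' the expected fraction. Used when only one replicate is available (the
#' NB dispersion is unidentifiable).
#'
#' @param plus,minus Pooled raw counts (scalars or parallel vectors).
#' @param expected_plus_fraction Null plus-strand share (default 0.5).
#' @return Tibble `p_value`, `log2fc`, `tested` (FALSE when the total is 0,
#'   with `p = 1`).
#' @export
binomial_imbalance_test <- function(plus, minus, expected_plus_fraction = 0.5) {
  stopifnot(length(plus) == length(minus))
  ef <- expected_plus_fraction
  p <- vapply(seq_along(plus), function(i) {
    tot <- plus[i] + minus[i]
    if (tot == 0) return(1)
    binom.test(plus[i], tot, p = ef, alternative = "two.sided")$p.value
  }, numeric(1))
  lfc <- log2((plus + 0.5) / (minus + 0.5)) - log2(ef / (1 - ef))
  tibble(p_value = p, log2fc = lfc, tested = (plus + minus) > 0)
}

# Method-of-moments NB dispersions pooled across the two strand conditions,
# shrunk 50/50 in log space toward a fitted trend alpha(mu) = a1/mu + a0.
# The trend is least squares on the raw (possibly negative) MoM values;
# fitted values are floored at 1e-8. Windows whose MoM estimate is
# non-positive take the trend value directly.
shrink_dispersions <- function(mu_bar, alpha_mom, min_windows = 10) {
  floor_alpha <- 1e-8
  ok <- is.finite(alpha_mom) & is.finite(mu_bar) & mu_bar > 0
  if (sum(ok) < min_windows) {
    warn("dispersion trend: too few windows; using raw method-of-moments dispersions")
    return(pmax(alpha_mom, floor_alpha))
  }
  fit <- lm(alpha_mom[ok] ~ I(1 / mu_bar[ok]))
  a0 <- coef(fit)[1]; a1 <- coef(fit)[2]
  alpha_trend <- pmax(a0 + a1 / mu_bar, floor_alpha)
  pos <- is.finite(alpha_mom) & alpha_mom > 0
  out <- alpha_trend
  out[pos] <- exp((log(alpha_mom[pos]) + log(alpha_trend[pos])) / 2)
  out
}

#' Negative-binomial Wald test for strand imbalance
#'
#' With >= 2 replicates per strand: counts are normalized by
#' median-of-ratios size factors; per-window dispersion is estimated by
#' method of moments pooled across the two strands and shrunk 50/50 in log
#' space toward a fitted mean-dispersion trend `alpha(mu) = a1/mu + a0`;
#' the Wald statistic is the log2 fold change over its delta-method
#' standard error under NB variance `mu + alpha * mu^2`, with a two-sided
#' normal p-value and Benjamini-Hochberg adjustment across windows. With a
#' single replicate the exact binomial test is used instead.
#'
#' @param sw A `kas_stranded_windows` from [count_strands()], or a tibble
#'   with `chrom`, `start`, `end` and `plus_i`/`minus_i` count columns.
#' @param sf Optional size factors (plus replicates then minus replicates);
#'   computed from the count matrix when `NULL`.
#' @param alpha Significance threshold on the adjusted p (default 0.05).
#' @return A `kas_imbalance` tibble: window coordinates, `base_mean`,
#'   `log2fc`, `p_value`, `padj`, `dominant_strand`, `significant`.
#' @export
nb_imbalance_test <- function(sw, sf = NULL, alpha = 0.05) {
  plus_cols <- grep("^plus_", names(sw), value = TRUE)
  minus_cols <- grep("^minus_", names(sw), value = TRUE)
  r <- length(plus_cols)
  if (r == 0 || length(minus_cols) != r) abort("nb_imbalance_test: malformed count columns")
  counts <- as.matrix(as_tibble(sw)[c(plus_cols, minus_cols)])
  storage.mode(counts) <- "double"

  if (r == 1) {
    libs <- attr(sw, "lib_sizes")
    ef <- if (!is.null(libs)) {
      libs$plus / (libs$plus + libs$minus)
    } else {
      sum(counts[, 1]) / max(sum(counts), 1)
    }
    bt <- binomial_imbalance_test(counts[, 1], counts[, 2], ef)
    p <- bt$p_value
    lfc <- bt$log2fc
  } else {
    if (is.null(sf)) sf <- size_factors(counts)
    if (length(sf) != 2 * r) abort("nb_imbalance_test: need one size factor per sample")
    norm <- sweep(counts, 2, sf, "/")
    plus <- norm[, seq_len(r), drop = FALSE]
    minus <- norm[, r + seq_len(r), drop = FALSE]
    m_p <- rowMeans(plus); m_m <- rowMeans(minus)
    v_p <- apply(plus, 1, var); v_m <- apply(minus, 1, var)
    mu_bar <- (m_p + m_m) / 2
    alpha_mom <- ((v_p + v_m) / 2 - mu_bar) / mu_bar^2
    disp <- shrink_dispersions(mu_bar, alpha_mom)
    lfc <- log2((m_p + 0.5) / (m_m + 0.5))
    se2 <- ((m_p + disp * m_p^2) / r / (m_p + 0.5)^2 +
            (m_m + disp * m_m^2) / r / (m_m + 0.5)^2) / log(2)^2
    z <- lfc / sqrt(se2)
    p <- 2 * pnorm(-abs(z))
    p[m_p + m_m == 0] <- 1
  }
  out <- as_tibble(sw)[c("chrom", "start", "end")]
  out$base_mean <- rowMeans(counts)
  out$log2fc <- lfc
  out$p_value <- p
  out$padj <- bh_adjust(p)
  out$dominant_strand <- ifelse(lfc >= 0, "+", "-")
  out$significant <- out$padj <= alpha
  class(out) <- c("kas_imbalance", class(out))
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjustment with monotonicity enforcement, capped at 1.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("bh_adjust: p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Merge significant windows into R-loop regions
#'
#' Significant windows are partitioned by dominant strand and merged
#' within each strand ([interval_merge()] with `merge_gap`). Each region
#' records its member-window count and, when per-window densities are
#' available, their mean.
#'
#' @param results A `kas_imbalance` tibble from [nb_imbalance_test()].
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param merge_gap Maximum gap in bp between windows to merge (default 0).
#' @param window_density Optional per-window density vector parallel to
#'   `results` (e.g. absolute strand RPKM difference).
#' @return Region tibble: `chrom`, `start`, `end`, `dominant_strand`,
#'   `n_windows`, `mean_density`.
#' @export
call_rloops <- function(results, alpha = 0.05, merge_gap = 0, window_density = NULL) {
  sig <- results[results$padj <= alpha, , drop = FALSE]
  if (!is.null(window_density)) {
    window_density <- window_density[results$padj <= alpha]
  }
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  dominant_strand = character(), n_windows = integer(),
                  mean_density = double())
  if (nrow(sig) == 0) return(empty)
  per_strand <- lapply(c("+", "-"), function(s) {
    idx <- sig$dominant_strand == s
    if (!any(idx)) return(NULL)
    wins <- sig[idx, c("chrom", "start", "end")]
    dens <- if (!is.null(window_density)) window_density[idx] else rep(NA_real_, sum(idx))
    regions <- interval_merge(wins, max_gap = merge_gap)
    hit <- GenomicRanges::findOverlaps(as_granges(regions), as_granges(wins),
                                       ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hit); sh <- S4Vectors::subjectHits(hit)
    regions$dominant_strand <- s
    regions$n_windows <- as.integer(tabulate(qh, nbins = nrow(regions)))
    regions$mean_density <- vapply(seq_len(nrow(regions)), function(i) {
      mean(dens[sh[qh == i]])
    }, numeric(1))
    regions
  })
  out <- dplyr::bind_rows(per_strand)
  out[order(out$chrom, out$start), ]
}

#' Absolute strand-difference density track
#'
#' Per-bin `|plus - minus|` of two equally binned, equally normalized
#' strand tracks: the R-loop density signal.
#'
#' @param plus_track,minus_track `kas_track`s sharing bin size and
#'   normalization.
#' @return A `kas_track` of absolute differences.
#' @export
rloop_density_track <- function(plus_track, minus_track) {
  if (!identical(attr(plus_track, "bin_size"), attr(minus_track, "bin_size"))) {
    abort("rloop_density_track: bin sizes differ")
  }
  if (!identical(attr(plus_track, "normalization"), attr(minus_track, "normalization"))) {
    abort("rloop_density_track: normalizations differ")
  }
  if (nrow(plus_track) != nrow(minus_track) ||
      !all(plus_track$chrom == minus_track$chrom & plus_track$start == minus_track$start)) {
    abort("rloop_density_track: bin grids differ")
  }
  out <- plus_track
  out$value <- abs(plus_track$value - minus_track$value)
  attr(out, "total_tags") <- NA_real_
  out
}

# width-weighted mean track value over a region set
region_track_mean <- function(track, regions) {
  tgr <- as_granges(as_tibble(track)[c("chrom", "start", "end")])
  rgr <- as_granges(regions[c("chrom", "start", "end")])
  hits <- GenomicRanges::findOverlaps(rgr, tgr)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(rgr[qh], tgr[sh]))
  vapply(seq_len(nrow(regions)), function(i) {
    sel <- qh == i
    if (!any(sel)) return(NA_real_)
    sum(track$value[sh[sel]] * ov[sel]) / sum(ov[sel])
  }, numeric(1))
}

#' Filter R-loop regions for RNase H sensitivity
#'
#' A region is RNase H-sensitive when its mean R-loop density in the
#' treated condition drops to at most the wild-type mean divided by
#' `fc_min` (equivalently WT / treated >= `fc_min`); signal loss after
#' RNase H treatment is the gold-standard evidence for a true R-loop. The
#' treated denominator is floored at the RPKM of a single fragment in the
#' region.
#'
#' @param rloops R-loop region tibble (from [call_rloops()]).
#' @param wt_density,treated_density R-loop density `kas_track`s computed
#'   identically for the two conditions.
#' @param fc_min Fold-change threshold (default 1.5).
#' @return `rloops` with added `wt_density`, `treated_density`, `ratio`,
#'   and logical `sensitive` columns.
#' @export
rnaseh_filter <- function(rloops, wt_density, treated_density, fc_min = 1.5) {
  rloops <- validate_intervals(rloops, what = "rloops")
  wt <- region_track_mean(wt_density, rloops)
  tr <- region_track_mean(treated_density, rloops)
  if (any(is.na(wt)) || any(is.na(tr))) {
    abort("rnaseh_filter: region absent from a density track")
  }
  lib <- attr(treated_density, "total_tags")
  width <- rloops$end - rloops$start
  delta <- if (!is.null(lib) && is.finite(lib) && lib > 0) {
    single_fragment_rpkm(width, lib)
  } else {
    # density tracks without a recorded library: tiny positive guard
    rep(.Machine$double.eps, length(width))
  }
  ratio <- wt / pmax(tr, delta)
  rloops$wt_density <- wt
  rloops$treated_density <- tr
  rloops$ratio <- ratio
  rloops$sensitive <- ratio >= fc_min
  rloops
}
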