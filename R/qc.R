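# Library-level quality metrics for KAS-seq samples: FRiP, complexity
# (NRF/PBC), fingerprint and saturation curves, replicate correlation, and
# the pass/warn recommendation (>= 50,000 peaks and FRiP > 40% for live
# human/mouse cell lines).

#' Fraction of reads in peaks
#'
#' Peaks are merged first so a tag overlapping two bookended peaks is
#' counted once.
#'
#' @param tags Deduplicated tag tibble.
#' @param peaks Peak interval tibble.
#' @return FRiP in `[0, 1]`.
#' @export
qc_frip <- function(tags, peaks) {
  tags <- validate_intervals(tags, what = "tags")
  if (nrow(tags) == 0) abort("qc_frip: no tags")
  if (nrow(peaks) == 0) return(0)
  merged <- interval_merge(peaks)
  universe <- union(unique(tags$chrom), unique(merged$chrom))
  gr_tags <- as_granges(tags)
  gr_peaks <- as_granges(merged)
  GenomeInfoDb::seqlevels(gr_tags) <- universe
  GenomeInfoDb::seqlevels(gr_peaks) <- universe
  hits <- GenomicRanges::countOverlaps(gr_tags, gr_peaks, ignore.strand = TRUE)
  sum(hits > 0) / nrow(tags)
}

#' Library complexity metrics (NRF, PBC1, PBC2)
#'
#' Operates on the raw (pre-deduplication) tag list. Tags are grouped by
#' their 5' position `(chrom, pos, strand)`:
#' * NRF  = distinct positions / total tags
#' * PBC1 = positions seen exactly once / distinct positions
#' * PBC2 = positions seen exactly once / positions seen exactly twice
#'
#' When no position is seen exactly twice, PBC2 is reported as `Inf` with
#' `pbc2_infinite = TRUE` (legitimate for perfectly complex libraries).
#'
#' @param raw_tags Tag tibble before deduplication (strand `+` or `-`).
#' @return One-row tibble: `nrf`, `pbc1`, `pbc2`, `pbc2_infinite`.
#' @export
qc_complexity <- function(raw_tags) {
  raw_tags <- validate_intervals(raw_tags, what = "raw tags")
  if (nrow(raw_tags) == 0) abort("qc_complexity: no tags")
  strand <- if ("strand" %in% names(raw_tags)) raw_tags$strand else "."
  pos5 <- ifelse(strand == "-", raw_tags$end, raw_tags$start)
  key <- paste(raw_tags$chrom, pos5, strand, sep = ":")
  counts <- table(key)
  n_total <- nrow(raw_tags)
  n_distinct <- length(counts)
  n_once <- sum(counts == 1)
  n_twice <- sum(counts == 2)
  tibble(
    nrf = n_distinct / n_total,
    pbc1 = n_once / n_distinct,
    pbc2 = if (n_twice == 0) Inf else n_once / n_twice,
    pbc2_infinite = n_twice == 0
  )
}

#' Fingerprint (signal concentration) curve
#'
#' Sorts raw bin counts ascending and accumulates: point i is
#' `(i / N, cumulative count through rank i / total count)`. A sample whose
#' signal is concentrated in few bins hugs the x axis; uniform background
#' lies on the diagonal. Returned with the `(0, 0)` origin, N + 1 points.
#'
#' @param track A raw `kas_track` (conventionally 500 bp bins genome-wide).
#' @return Tibble `x`, `y`, monotone from (0,0) to (1,1).
#' @export
fingerprint_curve <- function(track) {
  counts <- track$value
  if (length(counts) < 2) abort("fingerprint_curve: need at least 2 bins")
  if (sum(counts) == 0) abort("fingerprint_curve: all-zero track")
  sorted <- sort(counts)
  n <- length(sorted)
  tibble(x = (0:n) / n, y = c(0, cumsum(sorted)) / sum(sorted))
}

#' Sequencing-saturation curve
#'
#' Subsamples the tag list without replacement at each fraction (seeded)
#' and recomputes FRiP against the fixed full-data peak set.
#'
#' @param tags Tag tibble.
#' @param peaks Peak tibble (full-data peaks, held fixed).
#' @param fractions Subsample fractions in (0, 1] (default 0.1..1.0).
#' @param seed Integer seed for the subsampling RNG.
#' @return Tibble `fraction`, `frip`.
#' @export
saturation_curve <- function(tags, peaks, fractions = seq(0.1, 1, by = 0.1), seed = 1) {
  if (any(fractions <= 0 | fractions > 1)) abort("saturation_curve: fractions must be in (0, 1]")
  tags <- validate_intervals(tags, what = "tags")
  fractions <- sort(fractions)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  frips <- vapply(fractions, function(f) {
    n <- max(1L, round(f * nrow(tags)))
    sub <- if (n >= nrow(tags)) tags else tags[sample.int(nrow(tags), n), ]
    qc_frip(sub, peaks)
  }, numeric(1))
  tibble(fraction = fractions, frip = frips)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Pearson correlation of replicate densities
#'
#' Computed on `log2(RPKM + 1)`-transformed region densities (peak-based
#' log-scale scatter convention).
#'
#' @param densities_a,densities_b Matched numeric RPKM vectors (length >= 3).
#' @return Pearson r.
#' @export
replicate_correlation <- function(densities_a, densities_b) {
  if (length(densities_a) != length(densities_b)) abort("replicate_correlation: length mismatch")
  if (length(densities_a) < 3) abort("replicate_correlation: need at least 3 regions")
  a <- log2(densities_a + 1)
  b <- log2(densities_b + 1)
  if (var(a) == 0 || var(b) == 0) abort("replicate_correlation: zero variance")
  cor(a, b)
}

#' QC pass/warn recommendation
#'
#' Pass requires at least `min_peaks` combined sharp + broad peaks and
#' FRiP strictly greater than `min_frip`; otherwise warn (never a hard
#' failure). Defaults reflect live human/mouse cell lines and are
#' overridable.
#'
#' @param n_peaks Number of called peaks.
#' @param frip FRiP value in `[0, 1]`.
#' @param min_peaks Peak-count threshold (default 50000).
#' @param min_frip FRiP threshold, strict (default 0.40).
#' @return `"pass"` or `"warn"`.
#' @export
qc_verdict <- function(n_peaks, frip, min_peaks = 50000, min_frip = 0.40) {
  if (n_peaks >= min_peaks && frip > min_frip) "pass" else "warn"
}

#' Assemble a full QC report
#'
#' Runs FRiP, complexity, fingerprint, saturation, and the verdict on one
#' sample.
#'
#' @param raw_tags Tags before deduplication (for complexity).
#' @param tags Deduplicated, extended tags.
#' @param peaks Called peak set.
#' @param chrom_sizes Chromosome sizes tibble.
#' @param fingerprint_bin Fingerprint bin size in bp (default 500).
#' @param seed Seed for the saturation subsampling.
#' @param min_peaks,min_frip Verdict thresholds (see [qc_verdict()]).
#' @return A `kas_qc_report` list: scalar metrics plus curve tibbles.
#' @export
qc_report <- function(raw_tags, tags, peaks, chrom_sizes, fingerprint_bin = 500,
                      seed = 1, min_peaks = 50000, min_frip = 0.40) {
  frip <- qc_frip(tags, peaks)
  cx <- qc_complexity(raw_tags)
  fp_track <- bin_counts(tags, chrom_sizes, bin_size = fingerprint_bin)
  out <- list(
    frip = frip,
    n_peaks = nrow(peaks),
    nrf = cx$nrf, pbc1 = cx$pbc1, pbc2 = cx$pbc2, pbc2_infinite = cx$pbc2_infinite,
    fingerprint = fingerprint_curve(fp_track),
    saturation = saturation_curve(tags, peaks, seed = seed),
    verdict = qc_verdict(nrow(peaks), frip, min_peaks, min_frip)
  )
  class(out) <- "kas_qc_report"
  out
}

#' @export
print.kas_qc_report <- function(x, ...) {
  cat("KAS-seq QC report\n")
  cat(sprintf("  peaks: %d   FRiP: %.3f   verdict: %s\n", x$n_peaks, x$frip, x$verdict))
  cat(sprintf("  NRF: %.3f   PBC1: %.3f   PBC2: %s\n", x$nrf, x$pbc1,
              if (x$pbc2_infinite) "Inf" else sprintf("%.3f", x$pbc2)))
  invisible(x)
}

#' @rdname qc_report
#' @param x A `kas_qc_report`.
#' @param ... Unused.
#' @export
glance.kas_qc_report <- function(x, ...) {
  tibble(frip = x$frip, n_peaks = x$n_peaks, nrf = x$nrf, pbc1 = x$pbc1,
         pbc2 = x$pbc2, verdict = x$verdict)
}
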