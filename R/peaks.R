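# Integration of externally called sharp (MACS2-style) and broad
# (epic2-style) candidate peaks into a unified KAS-seq peak set, plus
# genomic-feature annotation of the result.

# RPKM equivalent of a single fragment in a region: the scale-aware
# zero-denominator guard used wherever a density ratio is formed.
single_fragment_rpkm <- function(width, library_size) {
  1e9 / (width * library_size)
}

#' Re-screen sharp candidate peaks by fold change vs Input and shores
#'
#' Candidates (already peak-called upstream at q <= 0.01 and >= 1.5x vs
#' Input) are kept when the case RPKM density is at least `fc_input_min`
#' times the Input density and at least `fc_shore_min` times the mean case
#' density of the usable flanking shores (equal-width flanks from
#' [make_shores()]). Zero denominators are floored at the RPKM of a single
#' fragment in the region for the relevant library. Candidates with no
#' usable shore are dropped with a reason.
#'
#' @param candidates Sharp candidate peak tibble.
#' @param case_tags,input_tags Tag tibbles for the KAS-seq sample and its
#'   Input control.
#' @param chrom_sizes Chromosome sizes tibble.
#' @param fc_input_min Fold-change threshold vs Input (default 5).
#' @param fc_shore_min Fold-change threshold vs shores (default 2).
#' @return Tibble of kept peaks with columns `fc_input`, `fc_shore`,
#'   `peak_class = "sharp"`, `source = "macs-like"`. Dropped candidates are
#'   recorded in the `dropped` attribute with reasons.
#' @export
filter_sharp <- function(candidates, case_tags, input_tags, chrom_sizes,
                         fc_input_min = 5, fc_shore_min = 2) {
  candidates <- validate_intervals(candidates, chrom_sizes = chrom_sizes, what = "candidates")
  if (nrow(case_tags) == 0 || nrow(input_tags) == 0) {
    abort("filter_sharp: case and Input tag sets must be non-empty")
  }
  case_lib <- nrow(case_tags)
  input_lib <- nrow(input_tags)
  if (nrow(candidates) == 0) {
    out <- candidates
    out$fc_input <- numeric(0); out$fc_shore <- numeric(0)
    out$peak_class <- character(0); out$source <- character(0)
    return(out)
  }
  sh <- make_shores(candidates[c("chrom", "start", "end")], chrom_sizes)
  d_case <- region_density(case_tags, candidates[c("chrom", "start", "end")], case_lib)$density
  d_input <- region_density(input_tags, candidates[c("chrom", "start", "end")], input_lib)$density

  shore_density <- function(s_start, s_end, usable) {
    ok <- usable & (s_end - s_start) > 0
    dens <- rep(NA_real_, length(s_start))
    if (any(ok)) {
      regs <- tibble(chrom = candidates$chrom[ok], start = s_start[ok], end = s_end[ok])
      dens[ok] <- region_density(case_tags, regs, case_lib)$density
    }
    dens
  }
  d_left <- shore_density(sh$left_start, sh$left_end, sh$left_usable)
  d_right <- shore_density(sh$right_start, sh$right_end, sh$right_usable)
  n_usable <- sh$left_usable + sh$right_usable
  d_shore <- rowMeans(cbind(d_left, d_right), na.rm = TRUE)
  d_shore[n_usable == 0] <- NA_real_
  mean_shore_width <- rowMeans(cbind(
    ifelse(sh$left_usable, sh$left_end - sh$left_start, NA_real_),
    ifelse(sh$right_usable, sh$right_end - sh$right_start, NA_real_)
  ), na.rm = TRUE)

  width <- candidates$end - candidates$start
  delta_input <- single_fragment_rpkm(width, input_lib)
  delta_shore <- single_fragment_rpkm(mean_shore_width, case_lib)
  fc_input <- d_case / pmax(d_input, delta_input)
  fc_shore <- d_case / pmax(d_shore, delta_shore)

  no_shore <- n_usable == 0
  keep <- !no_shore & fc_input >= fc_input_min & fc_shore >= fc_shore_min
  if (any(no_shore)) {
    inform(sprintf("filter_sharp: %d candidate(s) dropped (no usable shore)", sum(no_shore)))
  }
  out <- candidates[keep, , drop = FALSE]
  out$fc_input <- fc_input[keep]
  out$fc_shore <- fc_shore[keep]
  out$peak_class <- "sharp"
  out$source <- "macs-like"
  dropped <- candidates[!keep, , drop = FALSE]
  dropped$reason <- ifelse(no_shore[!keep], "no_usable_shore",
                           ifelse(fc_input[!keep] < fc_input_min, "fc_input", "fc_shore"))
  attr(out, "dropped") <- dropped
  out
}

#' Derive broad peaks by subtracting sharp peaks from broad candidates
#'
#' Broad candidates (epic2-style calls, already FDR <= 0.05 and >= 1.5x vs
#' Input) have the accepted sharp peaks subtracted; remaining fragments
#' shorter than `min_broad_width` (one read length) are discarded.
#'
#' @param epic_candidates Broad candidate peak tibble.
#' @param sharp Accepted sharp peak tibble (from [filter_sharp()]).
#' @param min_broad_width Minimum fragment width in bp (default 150).
#' @return Tibble of broad peaks, `peak_class = "broad"`,
#'   `source = "derived"`.
#' @export
derive_broad <- function(epic_candidates, sharp, min_broad_width = 150) {
  epic_candidates <- validate_intervals(epic_candidates, what = "broad candidates")
  pieces <- interval_subtract(epic_candidates[c("chrom", "start", "end")],
                              if (nrow(sharp) > 0) sharp[c("chrom", "start", "end")] else sharp)
  pieces <- pieces[pieces$end - pieces$start >= min_broad_width, , drop = FALSE]
  pieces$peak_class <- rep("broad", nrow(pieces))
  pieces$source <- rep("derived", nrow(pieces))
  pieces
}

#' Assign each peak to a genomic feature by its midpoint
#'
#' Priority: promoter (TSS +/- `promoter_flank`) > terminator (TES to
#' TES + `term_flank`, strand-aware) > gene body (remaining transcribed
#' span) > intergenic.
#'
#' @param peaks Peak tibble.
#' @param genes Gene tibble with `strand` (+/-) and `name`.
#' @param promoter_flank Promoter half-width in bp (default 2000).
#' @param term_flank Terminator extent past the TES in bp (default 3000).
#' @return `peaks` with an added `feature` column.
#' @export
assign_peak_features <- function(peaks, genes, promoter_flank = 2000, term_flank = 3000) {
  peaks <- validate_intervals(peaks, what = "peaks")
  genes <- validate_intervals(genes, what = "genes")
  if (nrow(genes) == 0) abort("assign_peak_features: gene set is empty")
  if (!all(genes$strand %in% c("+", "-"))) abort("assign_peak_features: genes need strand + or -")
  mid <- floor((peaks$start + peaks$end) / 2)
  midpoints <- GenomicRanges::GRanges(peaks$chrom, IRanges::IRanges(mid + 1L, width = 1L))
  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  tes <- ifelse(genes$strand == "+", genes$end, genes$start)
  mk <- function(start, end) {
    ok <- end > start
    GenomicRanges::GRanges(genes$chrom[ok],
                           IRanges::IRanges(pmax(start[ok], 0) + 1L, pmax(end[ok], start[ok] + 1L)))
  }
  promoters <- mk(tss - promoter_flank, tss + promoter_flank)
  terminators <- mk(ifelse(genes$strand == "+", tes, tes - term_flank),
                    ifelse(genes$strand == "+", tes + term_flank, tes))
  bodies <- mk(genes$start, genes$end)
  feature <- rep("intergenic", nrow(peaks))
  hit <- function(gr) GenomicRanges::countOverlaps(midpoints, gr, ignore.strand = TRUE) > 0
  feature[hit(bodies)] <- "gene_body"
  feature[hit(terminators)] <- "terminator"
  feature[hit(promoters)] <- "promoter"
  peaks$feature <- feature
  peaks
}

#' Genomic-feature distribution of a peak set
#'
#' Counts and percentages of peaks per feature category (promoter,
#' gene body, terminator, intergenic), assigned by [assign_peak_features()].
#' Percentages sum to 100.
#'
#' @inheritParams assign_peak_features
#' @return Tibble `feature`, `n`, `percent` (all four categories always
#'   present).
#' @export
annotate_peaks <- function(peaks, genes, promoter_flank = 2000, term_flank = 3000) {
  assigned <- assign_peak_features(peaks, genes, promoter_flank, term_flank)
  levels <- c("promoter", "gene_body", "terminator", "intergenic")
  n <- vapply(levels, function(f) sum(assigned$feature == f), numeric(1))
  tibble(feature = levels, n = as.integer(n), percent = 100 * n / max(sum(n), 1))
}
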