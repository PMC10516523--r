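# Read tags -> density tracks, region densities, metagene profiles.
#
# Density semantics follow read-count coverage: a tag contributes once to
# every bin or region it overlaps by >= 1 bp. RPKM for a region of width w
# bp with c overlapping tags and library size N is c * 1e9 / (w * N).

#' Extend short read tags to a fixed fragment length
#'
#' Each tag shorter than `target_length` is extended from its 5' end in the
#' direction of its strand; tags already at least `target_length` long are
#' left unchanged (extension compensates for short reads, it is not a
#' resizing). Results are clipped to chromosome bounds.
#'
#' @param tags Interval tibble with a `strand` column (`+` or `-`).
#' @param chrom_sizes Chromosome sizes tibble.
#' @param target_length Fragment length in bp (default 150).
#' @return Extended tag tibble.
#' @export
extend_reads <- function(tags, chrom_sizes, target_length = 150) {
  stopifnot(target_length > 0)
  tags <- validate_intervals(tags, chrom_sizes = chrom_sizes, what = "tags")
  if (nrow(tags) == 0) return(tags)
  if (!"strand" %in% names(tags) || any(!tags$strand %in% c("+", "-"))) {
    abort("extend_reads: every tag needs strand + or -")
  }
  sizes <- chrom_size_lookup(chrom_sizes)
  clen <- unname(sizes[tags$chrom])
  short <- (tags$end - tags$start) < target_length
  plus <- tags$strand == "+"
  new_end <- ifelse(short & plus, pmin(tags$start + target_length, clen), tags$end)
  new_start <- ifelse(short & !plus, pmax(tags$end - target_length, 0), tags$start)
  tags$start <- as.integer(new_start)
  tags$end <- as.integer(new_end)
  tags
}

#' Combine properly paired mates into fragments
#'
#' Each fragment spans `[min(starts), max(ends))` of a mate pair; the
#' fragment strand is taken from the first mate. Mates must be on the same
#' chromosome with the leftmost mate on the plus strand (proper
#' orientation).
#'
#' @param mates1,mates2 Parallel interval tibbles (one row per pair);
#'   `mates1` carries the strand of read 1.
#' @return Fragment tibble with `chrom`, `start`, `end`, `strand`.
#' @export
pair_to_fragment <- function(mates1, mates2) {
  mates1 <- validate_intervals(mates1, what = "mates1")
  mates2 <- validate_intervals(mates2, what = "mates2")
  if (nrow(mates1) != nrow(mates2)) abort("pair_to_fragment: mate sets differ in length")
  if (any(mates1$chrom != mates2$chrom)) abort("pair_to_fragment: mates on different chromosomes")
  left_strand <- ifelse(mates1$start <= mates2$start, mates1$strand, mates2$strand)
  if (any(left_strand != "+")) abort("pair_to_fragment: inverted mate orientation (leftmost mate must be +)")
  tibble(
    chrom = mates1$chrom,
    start = pmin(mates1$start, mates2$start),
    end = pmax(mates1$end, mates2$end),
    strand = mates1$strand
  )
}

new_track <- function(x, bin_size, normalization, total_tags) {
  x <- as_tibble(x)
  attr(x, "bin_size") <- bin_size
  attr(x, "normalization") <- normalization
  attr(x, "total_tags") <- total_tags
  class(x) <- c("kas_track", class(x))
  x
}

#' @export
print.kas_track <- function(x, ...) {
  cat(sprintf("# KAS coverage track: %d bp bins, %s, library %s tags\n",
              attr(x, "bin_size"), attr(x, "normalization"),
              format(attr(x, "total_tags"), big.mark = ",")))
  NextMethod()
}

# genome-wide bin scaffold as GRanges (last bin of a chromosome may be short)
genome_bins <- function(chrom_sizes, bin_size) {
  sizes <- chrom_size_lookup(chrom_sizes)
  GenomicRanges::tileGenome(sizes, tilewidth = bin_size,
                            cut.last.tile.in.chrom = TRUE)
}

#' Count tags per fixed-width genomic bin
#'
#' Tiles every chromosome into `bin_size` bp bins (the last bin may be
#' short) and counts, for each bin, the tags overlapping it by at least
#' 1 bp. A tag spanning a bin boundary is counted in every bin it touches.
#'
#' @param tags Tag tibble.
#' @param chrom_sizes Chromosome sizes tibble.
#' @param bin_size Bin width in bp (default 50).
#' @return A `kas_track` tibble (`chrom`, `start`, `end`, `value`) with raw
#'   counts; the library size (`nrow(tags)`) is stored for normalization.
#' @export
bin_counts <- function(tags, chrom_sizes, bin_size = 50) {
  stopifnot(bin_size > 0)
  tags <- validate_intervals(tags, chrom_sizes = chrom_sizes, what = "tags")
  bins <- genome_bins(chrom_sizes, bin_size)
  counts <- if (nrow(tags) == 0) integer(length(bins)) else {
    GenomicRanges::countOverlaps(bins, as_granges(tags), ignore.strand = TRUE)
  }
  out <- granges_to_tibble(bins)
  out$strand <- NULL
  out$value <- as.numeric(counts)
  new_track(out, bin_size, "raw", nrow(tags))
}

#' RPKM-normalize a raw coverage track
#'
#' Converts raw per-bin counts to reads per kilobase per million mapped
#' reads: `value * 1e9 / (bin_width * total_tags)`. Short terminal bins use
#' their actual width.
#'
#' @param track A raw `kas_track` from [bin_counts()].
#' @param total_tags Library size; defaults to the tag count recorded on
#'   the track.
#' @return An RPKM `kas_track`.
#' @export
rpkm_normalize <- function(track, total_tags = attr(track, "total_tags")) {
  if (is.null(total_tags) || total_tags <= 0) abort("rpkm_normalize: total_tags must be positive")
  if (!identical(attr(track, "normalization"), "raw")) abort("rpkm_normalize: track is not raw")
  width <- track$end - track$start
  track$value <- track$value * 1e9 / (width * total_tags)
  attr(track, "normalization") <- "RPKM"
  attr(track, "total_tags") <- total_tags
  track
}

#' RPKM density of tags over regions
#'
#' For each region, counts tags overlapping by >= 1 bp and converts to
#' RPKM: `count * 1e9 / (region_width * library_size)`.
#'
#' @param tags Tag tibble.
#' @param regions Interval tibble of query regions.
#' @param total_tags Library size (default `nrow(tags)`).
#' @return `regions` with added columns `tag_count` and `density`.
#' @export
region_density <- function(tags, regions, total_tags = nrow(tags)) {
  regions <- validate_intervals(regions, what = "regions")
  if (total_tags <= 0) abort("region_density: library size must be positive")
  if (any(regions$end <= regions$start)) abort("region_density: empty region")
  counts <- if (nrow(tags) == 0) integer(nrow(regions)) else {
    GenomicRanges::countOverlaps(as_granges(regions[c("chrom", "start", "end")]),
                                 as_granges(tags), ignore.strand = TRUE)
  }
  regions$tag_count <- as.integer(counts)
  regions$density <- counts * 1e9 / ((regions$end - regions$start) * total_tags)
  regions
}

# mean track value per bp interval [start, end) on one chromosome,
# pooled into n_out equal output bins
pool_track_values <- function(track_chr, start, end, n_out) {
  # per-bp values from the track's bins restricted to [start, end)
  bs <- track_chr$start
  be <- track_chr$end
  vals <- track_chr$value
  width <- end - start
  pos <- start:(end - 1)
  idx <- findInterval(pos, bs)
  v <- rep(0, width)
  ok <- idx >= 1 & idx <= length(bs)
  inbin <- ok & pos < be[pmax(idx, 1)]
  v[inbin] <- vals[idx[inbin]]
  # mean-pool into n_out bins
  cuts <- round(seq(0, width, length.out = n_out + 1))
  out <- numeric(n_out)
  for (i in seq_len(n_out)) {
    lo <- cuts[i] + 1; hi <- cuts[i + 1]
    out[i] <- if (hi >= lo) mean(v[lo:hi]) else NA_real_
  }
  out
}

#' Metagene profile matrix over genes
#'
#' Builds a per-gene profile from a coverage track in one of two layouts:
#'
#' * `scale-regions`: `flank/bin_size` bins upstream of the TSS, the gene
#'   body resampled to `body_bins` bins by mean pooling, and
#'   `flank/bin_size` bins downstream of the TES.
#' * `reference-point`: `2 * flank/bin_size` bins centered on the TSS.
#'
#' Minus-strand rows are reversed so column 1 is always 5'-most. In
#' scale-regions mode genes with a body shorter than `body_bins` bp are
#' skipped with a warning. Flank bins beyond chromosome ends read as 0.
#'
#' @param track A `kas_track` (raw or RPKM).
#' @param genes Gene tibble (`chrom`, `start`, `end`, `name`, `strand`).
#' @param mode `"scale-regions"` or `"reference-point"`.
#' @param flank Flank size in bp (default 3000).
#' @param body_bins Number of body bins in scale-regions mode (default 100).
#' @param bin_size Output bin width for the flanks (default 50).
#' @return A `kas_profile` tibble in long form: `gene`, `bin`, `value`,
#'   with profile geometry stored in attributes.
#' @export
metagene_profile <- function(track, genes, mode = c("scale-regions", "reference-point"),
                             flank = 3000, body_bins = 100, bin_size = 50) {
  mode <- match.arg(mode)
  genes <- validate_intervals(genes, what = "genes")
  if (nrow(genes) == 0) abort("metagene_profile: no genes")
  if (!all(genes$strand %in% c("+", "-"))) abort("metagene_profile: genes need strand + or -")
  n_flank <- as.integer(flank / bin_size)
  track_by_chr <- split(as_tibble(track)[c("start", "end", "value")], track$chrom)

  rows <- purrr::pmap(
    list(genes$chrom, genes$start, genes$end, genes$strand, genes$name),
    function(chrom, start, end, strand, name) {
      tc <- track_by_chr[[chrom]]
      if (is.null(tc)) return(NULL)
      chrom_end <- max(tc$end)
      grab <- function(lo, hi, n) {
        # regions outside [0, chrom_end) contribute zeros
        lo_c <- max(lo, 0); hi_c <- min(hi, chrom_end)
        if (hi_c <= lo_c) return(rep(0, n))
        full <- pool_track_values(tc, lo_c, hi_c, n)
        # approximate edge handling: clipped flanks keep their pooled values
        full
      }
      if (mode == "scale-regions") {
        if (end - start < body_bins) {
          warn(sprintf("metagene_profile: gene %s body (%d bp) shorter than body_bins; skipped",
                       name, end - start))
          return(NULL)
        }
        if (strand == "+") {
          vals <- c(grab(start - flank, start, n_flank),
                    pool_track_values(tc, start, end, body_bins),
                    grab(end, end + flank, n_flank))
        } else {
          vals <- rev(c(grab(start - flank, start, n_flank),
                        pool_track_values(tc, start, end, body_bins),
                        grab(end, end + flank, n_flank)))
        }
      } else {
        anchor <- if (strand == "+") start else end
        vals <- grab(anchor - flank, anchor + flank, 2L * n_flank)
        if (strand == "-") vals <- rev(vals)
      }
      tibble(gene = name, bin = seq_along(vals), value = vals)
    }
  )
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) abort("metagene_profile: no usable genes")
  attr(out, "mode") <- mode
  attr(out, "n_flank") <- n_flank
  attr(out, "body_bins") <- if (mode == "scale-regions") body_bins else 0L
  class(out) <- c("kas_profile", class(out))
  out
}

#' Column means of a metagene profile
#'
#' @param profile A `kas_profile`.
#' @return Tibble `bin`, `value` giving the metagene curve.
#' @export
profile_summary <- function(profile) {
  dplyr::summarise(dplyr::group_by(as_tibble(profile), .data$bin),
                   value = mean(.data$value), .groups = "drop")
}

#' Split tags by strand
#'
#' @param tags Tag tibble; every tag must have strand `+` or `-`.
#' @return Named list with elements `plus` and `minus`.
#' @export
strand_split <- function(tags) {
  tags <- validate_intervals(tags, what = "tags")
  if (!"strand" %in% names(tags) || any(!tags$strand %in% c("+", "-"))) {
    abort("strand_split: every tag needs strand + or - for strand-specific analysis")
  }
  list(plus = tags[tags$strand == "+", ], minus = tags[tags$strand == "-", ])
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal value are collapsed into single lines; coordinates are
#' 0-based half-open (UCSC bedGraph dialect, 4 columns, no header).
#'
#' @param track A `kas_track`.
#' @param path Output path.
#' @param suppress_zero Drop zero-value runs (default FALSE).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, suppress_zero = FALSE) {
  x <- as_tibble(track)
  parts <- lapply(split(x, factor(x$chrom, levels = unique(x$chrom))), function(tc) {
    tc <- tc[order(tc$start), ]
    r <- rle(tc$value)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1
    tibble(chrom = tc$chrom[idx_start], start = tc$start[idx_start],
           end = tc$end[idx_end], value = r$values)
  })
  runs <- dplyr::bind_rows(parts)
  if (suppress_zero) runs <- runs[runs$value != 0, ]
  if (nrow(runs) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  # per-element fixed-notation formatting: byte-deterministic, no vector-
  # common padding, no scientific notation
  val <- trimws(formatC(runs$value, format = "fg", digits = 6))
  lines <- paste(runs$chrom,
                 format(as.integer(runs$start), scientific = FALSE, trim = TRUE),
                 format(as.integer(runs$end), scientific = FALSE, trim = TRUE),
                 val, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph file
#'
#' @param path bedGraph path (4 columns, 0-based half-open).
#' @return Tibble `chrom`, `start`, `end`, `value` (runs, not fixed bins).
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) abort(paste0("bedGraph file not found: ", path))
  lines <- readLines(path)
  lines <- lines[!(grepl("^(track|browser|#)", lines) | lines == "")]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(), value = double()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4)) abort("bedGraph: every line needs 4 columns")
  tibble(
    chrom = vapply(fields, `[`, character(1), 1),
    start = as.integer(vapply(fields, `[`, character(1), 2)),
    end = as.integer(vapply(fields, `[`, character(1), 3)),
    value = as.numeric(vapply(fields, `[`, character(1), 4))
  )
}

#' Expand bedGraph runs back onto a fixed bin grid
#'
#' Reconstructs a `kas_track` from run-length bedGraph data, given the bin
#' size and chromosome sizes it was written with. Uncovered bins read 0.
#'
#' @param runs Tibble from [read_bedgraph()].
#' @param chrom_sizes Chromosome sizes tibble.
#' @param bin_size Original bin width in bp.
#' @param normalization Normalization label to record.
#' @param total_tags Library size to record (optional).
#' @return A `kas_track`.
#' @export
bedgraph_to_track <- function(runs, chrom_sizes, bin_size,
                              normalization = "RPKM", total_tags = NA_real_) {
  bins <- genome_bins(chrom_sizes, bin_size)
  out <- granges_to_tibble(bins)
  out$strand <- NULL
  out$value <- 0
  if (nrow(runs) > 0) {
    hits <- GenomicRanges::findOverlaps(bins, as_granges(runs[c("chrom", "start", "end")]))
    out$value[S4Vectors::queryHits(hits)] <- runs$value[S4Vectors::subjectHits(hits)]
  }
  new_track(out, bin_size, normalization, total_tags)
}
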