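# Genomic interval plumbing. All coordinates are 0-based half-open, the BED
# convention, both internally and in every file the package reads or writes.
# Intervals travel as tibbles with columns chrom/start/end and optionally
# name/score/strand; chromosome name matching is exact (no "chr" aliasing).

VALID_STRANDS <- c("+", "-", ".")

#' Validate an interval tibble
#'
#' Checks the basic interval invariants: required columns present,
#' `0 <= start < end`, non-empty chromosome names, and (when `chrom_sizes`
#' is supplied) `end` within the chromosome length.
#'
#' @param x A data frame with at least `chrom`, `start`, `end` columns.
#' @param chrom_sizes Optional chromosome sizes tibble (see
#'   [read_chrom_sizes()]); when given, every interval must lie on a known
#'   chromosome and end within its length.
#' @param what Label used in error messages.
#' @return `x` as a tibble, invisibly usable downstream.
#' @export
validate_intervals <- function(x, chrom_sizes = NULL, what = "intervals") {
  x <- as_tibble(x)
  missing_cols <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(missing_cols) > 0) {
    abort(paste0(what, " must have columns chrom/start/end; missing: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) == 0) return(x)
  if (any(is.na(x$chrom) | x$chrom == "")) abort(paste0(what, ": empty chromosome name"))
  if (any(x$start < 0)) abort(paste0(what, ": negative start coordinate"))
  bad <- which(x$start >= x$end)
  if (length(bad) > 0) {
    abort(sprintf("%s: start >= end at record %d (%s:%d-%d)",
                  what, bad[1], x$chrom[bad[1]], x$start[bad[1]], x$end[bad[1]]))
  }
  if ("strand" %in% names(x) && !all(x$strand %in% VALID_STRANDS)) {
    abort(paste0(what, ": strand must be one of +, -, ."))
  }
  if (!is.null(chrom_sizes)) {
    sizes <- chrom_size_lookup(chrom_sizes)
    unknown <- setdiff(unique(x$chrom), names(sizes))
    if (length(unknown) > 0) {
      abort(paste0(what, ": chromosome(s) not in chrom sizes: ",
                   paste(unknown, collapse = ", ")))
    }
    if (any(x$end > sizes[x$chrom])) {
      abort(paste0(what, ": interval extends beyond chromosome end"))
    }
  }
  x
}

# named vector chrom -> length
chrom_size_lookup <- function(chrom_sizes) {
  if (is.numeric(chrom_sizes) && !is.null(names(chrom_sizes))) return(chrom_sizes)
  setNames(as.numeric(chrom_sizes$size), chrom_sizes$chrom)
}

# interval tibble -> GRanges (1-based closed internally, as IRanges expects)
as_granges <- function(x, chrom_sizes = NULL) {
  strand <- if ("strand" %in% names(x)) ifelse(x$strand == ".", "*", x$strand) else "*"
  seqlengths <- NULL
  seqnames <- unique(x$chrom)
  if (!is.null(chrom_sizes)) {
    sizes <- chrom_size_lookup(chrom_sizes)
    seqnames <- union(names(sizes), seqnames)
    seqlengths <- sizes[seqnames]
  }
  GenomicRanges::GRanges(
    seqnames = factor(x$chrom, levels = seqnames),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand,
    seqlengths = seqlengths
  )
}

granges_to_tibble <- function(gr) {
  strand <- as.character(GenomicRanges::strand(gr))
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = ifelse(strand == "*", ".", strand)
  )
}

#' Read a BED file into an interval tibble
#'
#' Reads BED3/BED6/narrowPeak-style files. `track`/`browser`/`#` header
#' lines and blank lines are skipped. Records are validated (`start < end`,
#' known strand symbols); a malformed line raises an error naming the line
#' number. Columns beyond the sixth are preserved verbatim in an `extra`
#' character column (tab-joined).
#'
#' @param path Path to a tab-separated BED file.
#' @param expected_columns Optional integer; error if any data line has
#'   fewer columns.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (defaults `"."`, `0`, `"."` when absent from the file) and
#'   `extra` when the file has more than six columns. Record order is
#'   preserved.
#' @export
read_bed <- function(path, expected_columns = NULL) {
  if (!file.exists(path)) abort(paste0("BED file not found: ", path))
  lines <- readLines(path)
  keep <- !(grepl("^(track|browser)\\b", lines) | grepl("^#", lines) | lines == "")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = double(), strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("BED parse error at line %d: fewer than 3 columns", lineno[which(nf < 3)[1]]))
  }
  if (!is.null(expected_columns) && any(nf < expected_columns)) {
    abort(sprintf("BED parse error at line %d: expected %d columns, found %d",
                  lineno[which(nf < expected_columns)[1]], expected_columns,
                  nf[which(nf < expected_columns)[1]]))
  }
  col <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, character(1))
  }
  start <- suppressWarnings(as.integer(col(2, NA)))
  end <- suppressWarnings(as.integer(col(3, NA)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    abort(sprintf("BED parse error at line %d: non-integer coordinate", lineno[bad[1]]))
  }
  bad <- which(start < 0 | start >= end)
  if (length(bad) > 0) {
    abort(sprintf("BED parse error at line %d: invalid interval [%d, %d)",
                  lineno[bad[1]], start[bad[1]], end[bad[1]]))
  }
  strand <- col(6, ".")
  bad <- which(!strand %in% VALID_STRANDS)
  if (length(bad) > 0) {
    abort(sprintf("BED parse error at line %d: unknown strand symbol '%s'",
                  lineno[bad[1]], strand[bad[1]]))
  }
  score <- suppressWarnings(as.numeric(col(5, "0")))
  score[is.na(score)] <- 0
  out <- tibble(
    chrom = col(1, NA), start = start, end = end,
    name = col(4, "."), score = score, strand = strand
  )
  if (any(nf > 6)) {
    out$extra <- vapply(fields, function(f) {
      if (length(f) > 6) paste(f[7:length(f)], collapse = "\t") else NA_character_
    }, character(1))
  }
  out
}

#' Write an interval tibble as BED
#'
#' Emits tab-separated BED, 0-based half-open, no header. Coordinates are
#' formatted as plain integers (never scientific notation), so output is
#' byte-deterministic. Writes BED6 when any of `name`/`score`/`strand` is
#' present, BED3 otherwise; extra columns are dropped.
#'
#' @param x Interval tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- validate_intervals(x, what = "write_bed input")
  bed6 <- any(c("name", "score", "strand") %in% names(x))
  if (nrow(x) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  start <- format(as.integer(x$start), scientific = FALSE, trim = TRUE)
  end <- format(as.integer(x$end), scientific = FALSE, trim = TRUE)
  if (bed6) {
    name <- if ("name" %in% names(x)) as.character(x$name) else rep(".", nrow(x))
    score <- if ("score" %in% names(x)) format(x$score, scientific = FALSE, trim = TRUE) else rep("0", nrow(x))
    strand <- if ("strand" %in% names(x)) x$strand else rep(".", nrow(x))
    lines <- paste(x$chrom, start, end, name, score, strand, sep = "\t")
  } else {
    lines <- paste(x$chrom, start, end, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a UCSC chrom.sizes file
#'
#' @param path Two-column tab-separated file: chromosome name, length in bp.
#' @return Tibble with columns `chrom` and `size`.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) abort(paste0("chrom.sizes file not found: ", path))
  lines <- readLines(path)
  lines <- lines[lines != ""]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2)) abort("chrom.sizes: every line needs two tab-separated columns")
  chrom <- vapply(fields, `[`, character(1), 1)
  size <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2)))
  if (any(is.na(size) | size != floor(size))) abort("chrom.sizes: non-integer length")
  if (any(size <= 0)) abort("chrom.sizes: lengths must be positive")
  if (anyDuplicated(chrom)) {
    abort(paste0("chrom.sizes: duplicate chromosome '", chrom[duplicated(chrom)][1], "'"))
  }
  tibble(chrom = chrom, size = size)
}

#' Subtract one interval set from another (bedtools subtract semantics)
#'
#' For each interval in `a`, returns the maximal sub-intervals not covered
#' by any interval in `b`. Strand is ignored for overlap purposes; metadata
#' columns of `a` (name/score/strand) are carried onto the surviving
#' fragments of the corresponding source interval.
#'
#' @param a,b Interval tibbles.
#' @return Tibble of remaining fragments, in source order, sub-intervals
#'   sorted within each source interval.
#' @export
interval_subtract <- function(a, b) {
  a <- validate_intervals(a, what = "a")
  b <- validate_intervals(b, what = "b")
  if (nrow(a) == 0) return(a)
  if (nrow(b) == 0) return(a)
  # shared seqlevel universe so disjoint chromosome sets subtract cleanly
  universe <- union(unique(a$chrom), unique(b$chrom))
  with_universe <- function(x) {
    gr <- as_granges(x[c("chrom", "start", "end")])
    GenomeInfoDb::seqlevels(gr) <- universe
    gr
  }
  gr_a <- with_universe(a)
  gr_b <- GenomicRanges::reduce(with_universe(b), ignore.strand = TRUE)
  pieces <- GenomicRanges::subtract(gr_a, gr_b, ignore.strand = TRUE)
  n_per <- lengths(pieces)
  flat <- unlist(pieces, use.names = FALSE)
  out <- granges_to_tibble(flat)
  out$strand <- NULL
  src <- rep(seq_len(nrow(a)), n_per)
  for (colname in intersect(c("name", "score", "strand"), names(a))) {
    out[[colname]] <- a[[colname]][src]
  }
  out
}

#' Merge intervals within a maximum gap
#'
#' Intervals on the same chromosome whose gap is `<= max_gap` bp are
#' unioned (strand-blind). Output is sorted and disjoint.
#'
#' @param x Interval tibble.
#' @param max_gap Maximum gap in bp to bridge (default 0: touching or
#'   overlapping intervals merge).
#' @return Tibble with columns `chrom`, `start`, `end`.
#' @export
interval_merge <- function(x, max_gap = 0) {
  stopifnot(max_gap >= 0)
  x <- validate_intervals(x, what = "intervals")
  if (nrow(x) == 0) return(tibble(chrom = character(), start = integer(), end = integer()))
  gr <- GenomicRanges::reduce(as_granges(x[c("chrom", "start", "end")]),
                              min.gapwidth = max_gap + 1, ignore.strand = TRUE)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  out <- granges_to_tibble(gr)
  out$strand <- NULL
  out
}

#' Build flanking shores of width equal to each element
#'
#' For an element `[start, end)` of width w, the left shore is
#' `[start - w, start)` and the right shore `[end, end + w)`, each clipped
#' to the chromosome. A shore clipped to less than 50% of the element
#' width is flagged unusable (edge elements would make density ratios
#' unstable).
#'
#' @param x Interval tibble of elements.
#' @param chrom_sizes Chromosome sizes tibble.
#' @return `x` with added columns `left_start`, `left_end`, `left_usable`,
#'   `right_start`, `right_end`, `right_usable`.
#' @export
make_shores <- function(x, chrom_sizes) {
  x <- validate_intervals(x, chrom_sizes = chrom_sizes, what = "elements")
  sizes <- chrom_size_lookup(chrom_sizes)
  width <- x$end - x$start
  clen <- unname(sizes[x$chrom])
  x$left_start <- pmax(x$start - width, 0)
  x$left_end <- x$start
  x$left_usable <- (x$left_end - x$left_start) >= width / 2
  x$right_start <- x$end
  x$right_end <- pmin(x$end + width, clen)
  x$right_usable <- (x$right_end - x$right_start) >= width / 2
  x
}
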