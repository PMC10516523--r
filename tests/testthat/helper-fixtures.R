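# Shared fixture builders and brute-force oracles. Oracles work per-base
# on small chromosomes and are deliberately independent of the package's
# interval machinery.

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_len = 10000,
                             min_width = 1, max_width = 500) {
  chrom <- sample(chroms, n, replace = TRUE)
  width <- sample(min_width:max_width, n, replace = TRUE)
  start <- vapply(width, function(w) sample(0:(max_len - w), 1), numeric(1))
  tibble::tibble(chrom = chrom, start = start, end = start + width)
}

random_tags <- function(n, chrom_len = 10000, width = 50, chrom = "chr1") {
  start <- sample(0:(chrom_len - width), n, replace = TRUE)
  tibble::tibble(chrom = chrom, start = start, end = start + width,
                 name = ".", score = 0,
                 strand = sample(c("+", "-"), n, replace = TRUE))
}

# per-base occupancy of an interval set, one logical vector per chromosome
base_set <- function(x, chroms, max_len = 10000) {
  out <- lapply(chroms, function(ch) {
    v <- rep(FALSE, max_len)
    rows <- x[x$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      if (rows$end[i] > rows$start[i]) v[(rows$start[i] + 1):rows$end[i]] <- TRUE
    }
    v
  })
  names(out) <- chroms
  out
}

# brute-force merge oracle: per-base union, gaps <= max_gap bridged
merge_oracle <- function(x, max_gap = 0, chroms = unique(x$chrom), max_len = 10000) {
  occ <- base_set(x, chroms, max_len)
  out <- list()
  for (ch in chroms) {
    v <- occ[[ch]]
    if (max_gap > 0) {
      filled <- v
      idx <- which(v)
      if (length(idx) > 1) {
        for (j in seq_len(length(idx) - 1)) {
          if (idx[j + 1] - idx[j] - 1 <= max_gap) filled[idx[j]:idx[j + 1]] <- TRUE
        }
      }
      v <- filled
    }
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (any(keep)) {
      out[[ch]] <- tibble::tibble(chrom = ch, start = starts[keep], end = ends[keep])
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  res[order(res$chrom, res$start), ]
}

# brute-force two-sided exact binomial p-value by enumeration
binom_p_oracle <- function(k, n, p0) {
  probs <- dbinom(0:n, n, p0)
  sum(probs[probs <= dbinom(k, n, p0) * (1 + 1e-7)])
}

# brute-force BH: sort, scale by n/rank, cumulative min from the right
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  scaled <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(scaled)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# independent reimplementation of the impulse curve used as a formula oracle
impulse_oracle <- function(t, beta, h0, h1, h2, t1, t2) {
  sig <- function(x) 1 / (1 + exp(-x))
  vapply(t, function(ti) {
    rise <- h0 + (h1 - h0) * sig(beta * (ti - t1))
    fall <- h2 + (h1 - h2) * sig(-beta * (ti - t2))
    rise * fall / h1
  }, numeric(1))
}

# place n tags entirely inside [start, end) so every tag overlaps exactly
# this region (deterministic layout)
contained_tags <- function(chrom, start, end, n, width = 10, strand = "+") {
  if (n == 0) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer(),
                          name = character(), score = double(), strand = character()))
  }
  pos <- start + (seq_len(n) - 1) %% max(end - start - width, 1)
  tibble::tibble(chrom = chrom, start = pos, end = pos + width,
                 name = ".", score = 0, strand = strand)
}

expect_same_intervals <- function(a, b) {
  key <- function(x) paste(x$chrom, x$start, x$end)
  expect_setequal(key(a), key(b))
}
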