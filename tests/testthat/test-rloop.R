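test_that("window tiling truncates at peak ends and keeps half-size trailers", {
  p1 <- tibble::tibble(chrom = "chr1", start = 0, end = 1600)
  w1 <- tile_windows(p1)
  expect_equal(w1$start, c(0L, 500L, 1000L))
  expect_equal(w1$end, c(500L, 1000L, 1500L))  # trailing 100 bp dropped
  w2 <- tile_windows(tibble::tibble(chrom = "chr1", start = 0, end = 1750))
  expect_equal(tail(w2, 1)$start, 1500L)
  expect_equal(tail(w2, 1)$end, 1750L)  # 250 >= 250 kept

  set.seed(171)
  peaks <- random_intervals(20, chroms = "chr1", max_len = 50000,
                            min_width = 300, max_width = 3000)
  win <- tile_windows(peaks, size = 500, step = 250)
  expect_true(all(win$end - win$start >= 250 & win$end - win$start <= 500))
  inside <- vapply(seq_len(nrow(win)), function(i) {
    any(peaks$start <= win$start[i] & peaks$end >= win$end[i])
  }, logical(1))
  expect_true(all(inside))
  expect_false(any(duplicated(paste(win$chrom, win$start, win$end))))
})

test_that("strand counting matches brute-force overlap counts per replicate", {
  win <- tibble::tibble(chrom = "chr1", start = c(0, 500), end = c(500, 1000))
  plus <- contained_tags("chr1", 10, 480, 7, strand = "+")
  minus <- contained_tags("chr1", 20, 480, 2, strand = "-")
  sw <- count_strands(win, list(plus), list(minus))
  expect_equal(sw$plus_1, c(7L, 0L))
  expect_equal(sw$minus_1, c(2L, 0L))
  expect_error(count_strands(win, list(plus, plus), list(minus)), "mismatch")

  set.seed(181)
  rw <- random_intervals(10, chroms = "chr1", min_width = 200, max_width = 800)
  p1 <- random_tags(200); p2 <- random_tags(150)
  m1 <- random_tags(180); m2 <- random_tags(120)
  sw2 <- count_strands(rw, list(p1, p2), list(m1, m2))
  for (i in sample(nrow(rw), 5)) {
    expect_equal(sw2$plus_2[i], sum(p2$start < rw$end[i] & p2$end > rw$start[i]))
    expect_equal(sw2$minus_1[i], sum(m1$start < rw$end[i] & m1$end > rw$start[i]))
  }
})

test_that("size factors follow the median-of-ratios definition", {
  base <- matrix(c(10, 20, 30, 40), ncol = 1)
  two <- cbind(base, 2 * base)
  sf <- size_factors(two)
  expect_equal(sf, c(1 / sqrt(2), sqrt(2)))
  expect_equal(size_factors(base), 1)
  set.seed(191)
  m <- matrix(rnbinom(400, mu = 50, size = 10) + 1, ncol = 4)
  got <- size_factors(m)
  logg <- rowMeans(log(m))
  manual <- apply(m, 2, function(col) median(col / exp(logg)))
  expect_equal(got, manual, tolerance = 1e-12)
  expect_error(size_factors(matrix(c(0, 1, 1, 0), ncol = 2)), "pseudo-count")
})

test_that("exact binomial imbalance p-values equal exhaustive enumeration", {
  bal <- binomial_imbalance_test(15, 15)
  expect_equal(bal$p_value, 1)
  expect_equal(bal$log2fc, 0)
  for (case in list(c(30, 10, 0.5), c(30, 10, 0.75), c(5, 0, 0.5), c(12, 25, 0.4))) {
    got <- binomial_imbalance_test(case[1], case[2], case[3])
    expect_equal(got$p_value, binom_p_oracle(case[1], case[1] + case[2], case[3]),
                 tolerance = 1e-12)
  }
  zero <- binomial_imbalance_test(0, 0)
  expect_equal(zero$p_value, 1)
  expect_false(zero$tested)
})

test_that("BH adjustment equals its brute-force definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  set.seed(201)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-15)
  }
})

test_that("NB Wald test is centred under exact balance and flips with strand swap", {
  set.seed(211)
  n <- 600
  counts <- matrix(rnbinom(4 * n, mu = 50, size = 20), ncol = 4)
  counts[1, ] <- c(50, 50, 50, 50)
  sw <- tibble::tibble(chrom = "chr1", start = 500 * (0:(n - 1)),
                       end = 500 * (1:n),
                       plus_1 = counts[, 1], plus_2 = counts[, 2],
                       minus_1 = counts[, 3], minus_2 = counts[, 4])
  res <- nb_imbalance_test(sw, sf = rep(1, 4))
  expect_equal(res$log2fc[1], 0)
  expect_gt(res$p_value[1], 0.99)
  # swapping strands negates log2fc, keeps p
  swapped <- dplyr::rename(sw, plus_1 = "minus_1", plus_2 = "minus_2",
                           minus_1 = "plus_1", minus_2 = "plus_2")
  res2 <- nb_imbalance_test(swapped, sf = rep(1, 4))
  expect_equal(res2$log2fc, -res$log2fc)
  expect_equal(res2$p_value, res$p_value, tolerance = 1e-9)
  expect_true(all(res2$dominant_strand[res$log2fc > 0] == "-"))
})

test_that("single-replicate windows fall back to the exact binomial test", {
  sw <- tibble::tibble(chrom = "chr1", start = c(0, 500), end = c(500, 1000),
                       plus_1 = c(30, 20), minus_1 = c(10, 20))
  res <- nb_imbalance_test(sw)
  ef <- 50 / 80  # plus share of all counted tags
  expect_equal(res$p_value[1], binom_p_oracle(30, 40, ef), tolerance = 1e-12)
})

test_that("R-loop regions merge significant windows by dominant strand", {
  mk_res <- function(start, padj, strand) {
    tibble::tibble(chrom = "chr1", start = start, end = start + 500,
                   base_mean = 50, log2fc = ifelse(strand == "+", 2, -2),
                   p_value = padj, padj = padj, dominant_strand = strand,
                   significant = padj <= 0.05)
  }
  three <- mk_res(c(0, 500, 1000), c(0.01, 0.01, 0.01), c("+", "+", "+"))
  rl <- call_rloops(three)
  expect_equal(nrow(rl), 1)
  expect_equal(c(rl$start, rl$end), c(0, 1500))
  expect_equal(rl$n_windows, 3L)

  mixed <- mk_res(c(0, 500), c(0.01, 0.01), c("+", "-"))
  rl2 <- call_rloops(mixed)
  expect_equal(nrow(rl2), 2)
  expect_setequal(rl2$dominant_strand, c("+", "-"))

  set.seed(221)
  for (i in 1:20) {
    starts <- 500 * sort(sample(0:40, 15))
    padj <- ifelse(runif(15) < 0.4, 0.01, 0.5)
    strand <- sample(c("+", "-"), 15, replace = TRUE)
    res <- mk_res(starts, padj, strand)
    rl3 <- call_rloops(res)
    for (s in c("+", "-")) {
      sig <- res[res$significant & res$dominant_strand == s, ]
      if (nrow(sig) > 0) {
        expect_same_intervals(rl3[rl3$dominant_strand == s, c("chrom", "start", "end")],
                              merge_oracle(sig, 0, "chr1", 25000))
      }
    }
  }
})

test_that("R-loop density is the absolute per-bin strand difference", {
  cs <- tibble::tibble(chrom = "chr1", size = 150)
  base <- bin_counts(tibble::tibble(chrom = "chr1", start = 0, end = 10, strand = "+"), cs, 50)
  p <- base; p$value <- c(10, 4, 0)
  m <- base; m$value <- c(4, 4, 3)
  d <- rloop_density_track(p, m)
  expect_equal(d$value, c(6, 0, 3))
  expect_equal(rloop_density_track(m, p)$value, d$value)
  p2 <- bin_counts(tibble::tibble(chrom = "chr1", start = 0, end = 10, strand = "+"), cs, 25)
  expect_error(rloop_density_track(p, p2), "bin size")
})

test_that("RNase H filter returns exactly the regions losing >= 1.5-fold density", {
  cs <- tibble::tibble(chrom = "chr1", size = 10000)
  n <- 8
  regions <- tibble::tibble(chrom = "chr1", start = 1000 * (0:(n - 1)),
                            end = 1000 * (0:(n - 1)) + 500)
  ratios <- c(0.5, 1, 1.4, 1.5, 2, 3, 10, 1.49)
  grid <- bin_counts(tibble::tibble(chrom = "chr1", start = 0, end = 10, strand = "+"), cs, 50)
  wt <- grid; wt$value <- 0; tr <- grid; tr$value <- 0
  for (i in seq_len(n)) {
    sel <- wt$start >= regions$start[i] & wt$end <= regions$end[i]
    wt$value[sel] <- 6
    tr$value[sel] <- 6 / ratios[i]
  }
  attr(wt, "normalization") <- "RPKM"; attr(tr, "normalization") <- "RPKM"
  attr(wt, "total_tags") <- NA_real_; attr(tr, "total_tags") <- NA_real_
  res <- rnaseh_filter(regions, wt, tr)
  expect_equal(res$ratio, ratios, tolerance = 1e-9)
  expect_equal(res$sensitive, ratios >= 1.5)
})
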