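cs10k <- tibble::tibble(chrom = "chr1", size = 10000)

test_that("extend_reads extends from the 5' end, strand-aware, with clipping", {
  cs <- tibble::tibble(chrom = "chr1", size = 100000)
  tags <- tibble::tibble(chrom = "chr1", start = c(100, 500, 30, 2000),
                         end = c(136, 536, 66, 2400),
                         strand = c("+", "-", "-", "+"))
  out <- extend_reads(tags, cs, 150)
  expect_equal(out$start, c(100L, 386L, 0L, 2000L))
  expect_equal(out$end, c(250L, 536L, 66L, 2400L))  # long read untouched
})

test_that("pair_to_fragment spans mates and rejects improper pairs", {
  m1 <- tibble::tibble(chrom = "chr1", start = 100, end = 150, strand = "+")
  m2 <- tibble::tibble(chrom = "chr1", start = 300, end = 350, strand = "-")
  fr <- pair_to_fragment(m1, m2)
  expect_equal(c(fr$start, fr$end), c(100, 350))
  expect_equal(fr$strand, "+")
  same <- pair_to_fragment(m1, dplyr::mutate(m1, strand = "-"))
  expect_equal(c(same$start, same$end), c(100, 150))
  expect_error(pair_to_fragment(m1, dplyr::mutate(m2, chrom = "chr2")), "chromosome")
  expect_error(pair_to_fragment(dplyr::mutate(m1, strand = "-"), m2), "orientation")

  set.seed(41)
  a_start <- sample(0:5000, 1000, replace = TRUE)
  a <- tibble::tibble(chrom = "chr1", start = a_start, end = a_start + 50, strand = "+")
  b_start <- a_start + sample(0:300, 1000, replace = TRUE)
  b <- tibble::tibble(chrom = "chr1", start = b_start, end = b_start + 50, strand = "-")
  fr <- pair_to_fragment(a, b)
  expect_true(all(fr$end - fr$start == pmax(a$end, b$end) - pmin(a$start, b$start)))
})

test_that("bin_counts counts a tag once per overlapped bin", {
  tags <- tibble::tibble(chrom = "chr1", start = 0, end = 150, strand = "+")
  tr <- bin_counts(tags, cs10k, 50)
  expect_equal(tr$value[1:4], c(1, 1, 1, 0))
  three <- tibble::tibble(chrom = "chr1", start = c(210, 220, 230),
                          end = c(240, 240, 240), strand = "+")
  expect_equal(bin_counts(three, cs10k, 50)$value[5], 3)

  set.seed(51)
  tags <- random_tags(300)
  tr <- bin_counts(tags, cs10k, 64)
  # brute-force per-bin overlap count
  for (i in sample(nrow(tr), 25)) {
    expect_equal(tr$value[i],
                 sum(tags$start < tr$end[i] & tags$end > tr$start[i]))
  }
  expect_true(sum(tr$value) >= nrow(tags))
})

test_that("rpkm_normalize applies the RPKM formula and scales with library size", {
  tags <- tibble::tibble(chrom = "chr1", start = 0, end = 49, strand = "+")
  tr <- bin_counts(tags, cs10k, 50)
  tr$value[1] <- 5
  rp <- rpkm_normalize(tr, 1e6)
  expect_equal(rp$value[1], 100)  # 5 / (0.05 kb * 1 M)
  expect_equal(rp$value[2], 0)
  rp2 <- rpkm_normalize(tr, 2e6)
  expect_equal(rp2$value, rp$value / 2)
  expect_error(rpkm_normalize(tr, 0), "positive")
})

test_that("region_density matches the RPKM invariant and the binned track", {
  region <- tibble::tibble(chrom = "chr1", start = 1000, end = 3000)
  tags <- contained_tags("chr1", 1200, 2800, 40)
  rd <- region_density(tags, region, total_tags = 1e6)
  expect_equal(rd$tag_count, 40L)
  expect_equal(rd$density, 20)  # 40 / (2 kb * 1 M)
  expect_equal(region_density(tags, tibble::tibble(chrom = "chr1", start = 5000, end = 6000),
                              1e6)$density, 0)
  # bin-aligned region with bin-contained tags: mean of RPKM bins equals density
  tags2 <- contained_tags("chr1", 1000, 1040, 12, width = 5)
  track <- rpkm_normalize(bin_counts(tags2, cs10k, 50), 1e6)
  region2 <- tibble::tibble(chrom = "chr1", start = 1000, end = 1050)
  expect_equal(region_density(tags2, region2, 1e6)$density,
               mean(track$value[track$start >= 1000 & track$end <= 1050]))
})

test_that("metagene_profile places signal correctly and mirrors minus-strand genes", {
  cs <- tibble::tibble(chrom = "chr1", size = 50000)
  # uniform field: every cell equals the constant
  utags <- tibble::tibble(chrom = "chr1", start = seq(0, 49950, by = 50),
                          end = seq(50, 50000, by = 50), strand = "+")
  utrack <- bin_counts(utags, cs, 50)
  genes <- tibble::tibble(chrom = "chr1", start = 20000, end = 30000,
                          name = "g", score = 0, strand = "+")
  prof <- metagene_profile(utrack, genes)
  expect_true(all(prof$value == 1))
  expect_equal(max(prof$bin), 2 * 60 + 100)

  # spike in the first body bin of a plus gene
  sp_track <- utrack
  sp_track$value[sp_track$start >= 20000 & sp_track$end <= 20100] <- 99
  prof_sp <- metagene_profile(sp_track, genes)
  expect_gt(prof_sp$value[prof_sp$bin == 61], 50)
  expect_equal(prof_sp$value[prof_sp$bin == 80], 1)

  # strand symmetry: mirrored signal on a minus gene gives identical rows
  L <- 50000
  mir_track <- utrack
  mir_track$value <- rev(sp_track$value)
  gene_minus <- tibble::tibble(chrom = "chr1", start = L - 30000, end = L - 20000,
                               name = "g", score = 0, strand = "-")
  prof_m <- metagene_profile(mir_track, gene_minus)
  expect_equal(prof_m$value, prof_sp$value)

  # short gene skipped with a warning
  short <- tibble::tibble(chrom = "chr1", start = 100, end = 150,
                          name = "tiny", score = 0, strand = "+")
  expect_warning(metagene_profile(utrack, dplyr::bind_rows(genes, short)), "skipped")
})

test_that("strand_split partitions tags exactly", {
  set.seed(61)
  tags <- random_tags(200)
  sp <- strand_split(tags)
  expect_equal(nrow(sp$plus) + nrow(sp$minus), nrow(tags))
  expect_true(all(sp$plus$strand == "+"))
  expect_true(all(sp$minus$strand == "-"))
  expect_error(strand_split(dplyr::mutate(tags, strand = ".")), "strand")
})

test_that("bedGraph output collapses runs and round-trips bin values", {
  tr <- bin_counts(tibble::tibble(chrom = "chr1", start = 0, end = 100, strand = "+"),
                   tibble::tibble(chrom = "chr1", size = 150), 50)
  tr$value <- c(1, 1, 2)
  path <- withr::local_tempfile()
  write_bedgraph(tr, path)
  expect_equal(readLines(path), c("chr1\t0\t100\t1", "chr1\t100\t150\t2"))
  # zero suppression
  tr0 <- tr; tr0$value <- 0
  write_bedgraph(tr0, path, suppress_zero = TRUE)
  expect_equal(readLines(path), character(0))
  # round trip on a random RPKM track
  set.seed(71)
  big <- rpkm_normalize(bin_counts(random_tags(500), cs10k, 50), 500)
  write_bedgraph(big, path)
  back <- bedgraph_to_track(read_bedgraph(path), cs10k, 50)
  expect_equal(back$value, big$value, tolerance = 1e-6)
})
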