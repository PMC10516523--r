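cs100k <- tibble::tibble(chrom = "chr1", size = 100000)

test_that("gene_regions builds strand-aware promoter/body/termination windows", {
  plus <- tibble::tibble(chrom = "chr1", start = 10000, end = 20000,
                         name = "gp", score = 0, strand = "+")
  rp <- gene_regions(plus, cs100k)
  expect_equal(c(rp$promoter_start, rp$promoter_end), c(9500, 10500))
  expect_equal(c(rp$body_start, rp$body_end), c(10500, 20000))
  expect_equal(c(rp$term_start, rp$term_end), c(20000, 23000))

  minus <- dplyr::mutate(plus, strand = "-")
  rm <- gene_regions(minus, cs100k)
  expect_equal(c(rm$promoter_start, rm$promoter_end), c(19500, 20500))
  expect_equal(c(rm$body_start, rm$body_end), c(10000, 19500))
  expect_equal(c(rm$term_start, rm$term_end), c(7000, 10000))

  tiny <- tibble::tibble(chrom = "chr1", start = 1000, end = 1400,
                         name = "gt", score = 0, strand = "+")
  rt <- gene_regions(tiny, cs100k)
  expect_true(is.na(rt$body_start))  # promoter swallows the body
})

test_that("PI/EI/TI follow their defining formulas on planted densities", {
  # plant counts so promoter:body:termination RPKM = 10:2:4
  gene <- tibble::tibble(chrom = "chr1", start = 10000, end = 20000,
                         name = "g", score = 0, strand = "+")
  tags <- dplyr::bind_rows(
    contained_tags("chr1", 9500, 10500, 20),    # 1 kb at 20 tags
    contained_tags("chr1", 10500, 20000, 38),   # 9.5 kb at 4/kb
    contained_tags("chr1", 20000, 23000, 24)    # 3 kb at 8/kb
  )
  lib <- nrow(tags)
  idx <- compute_indices(tags, gene, cs100k, library_size = lib)
  d <- function(n, w) n * 1e9 / (w * lib)
  expect_equal(idx$d_promoter, d(20, 1000))
  expect_equal(idx$d_body, d(38, 9500))
  expect_equal(idx$d_termination, d(24, 3000))
  expect_equal(idx$pi, 5)
  expect_equal(idx$ti, 2)
  expect_equal(idx$ei, (d(20, 1000) + d(38, 9500)) / 2)
  # zero body: pi/ti null, ei still defined
  tags2 <- contained_tags("chr1", 9500, 10500, 6)
  idx2 <- compute_indices(tags2, gene, cs100k, library_size = 6)
  expect_true(is.na(idx2$pi) && is.na(idx2$ti))
  expect_equal(idx2$ei, idx2$d_promoter / 2)
  expect_equal(idx2$reason, "zero_body")
  # short gene excluded with reason
  shortg <- tibble::tibble(chrom = "chr1", start = 1000, end = 1800,
                           name = "s", score = 0, strand = "+")
  idx3 <- compute_indices(tags, shortg, cs100k, library_size = lib)
  expect_equal(idx3$reason, "short_gene")
  expect_true(all(is.na(c(idx3$pi, idx3$ei, idx3$ti))))
})

test_that("indices are scale-invariant (pi, ti) and depth-linear (ei)", {
  gene <- tibble::tibble(chrom = "chr1", start = 10000, end = 20000,
                         name = "g", score = 0, strand = "+")
  tags <- dplyr::bind_rows(
    contained_tags("chr1", 9500, 10500, 20),
    contained_tags("chr1", 10500, 20000, 38),
    contained_tags("chr1", 20000, 23000, 24)
  )
  i1 <- compute_indices(tags, gene, cs100k, library_size = 100)
  i2 <- compute_indices(tags, gene, cs100k, library_size = 400)
  expect_equal(i1$pi, i2$pi)
  expect_equal(i1$ti, i2$ti)
  expect_equal(i1$ei, 4 * i2$ei)
})

test_that("simulated region rates are recovered by the index estimators", {
  spec <- sim_spec(seed = 42, depth = 1e5, n_enhancers = 0)
  ann <- simulate_annotation(spec)
  sim <- simulate_kas_tags(spec, ann)
  tags <- extend_reads(sim$tags, ann$chrom_sizes, 150)
  idx <- compute_indices(tags, ann$genes, ann$chrom_sizes)
  expect_gt(sum(!is.na(idx$pi)), 90)
  expect_lt(abs(median(idx$pi, na.rm = TRUE) - 5), 0.5)
  expect_lt(abs(median(idx$ti, na.rm = TRUE) - 2), 0.2)
})

test_that("independent replicates of a heterogeneous cohort give concordant PI", {
  # two tag simulations over the SAME annotation (same per-gene true rates),
  # different noise: per-gene pausing indices must correlate strongly
  spec1 <- sim_spec(seed = 101, depth = 2e5, n_enhancers = 0, gene_rate_sdlog = 0.5)
  ann <- simulate_annotation(spec1)
  sim_a <- simulate_kas_tags(spec1, ann)
  spec2 <- sim_spec(seed = 202, depth = 2e5, n_enhancers = 0, gene_rate_sdlog = 0.5)
  sim_b <- simulate_kas_tags(spec2, ann)
  idx_a <- compute_indices(extend_reads(sim_a$tags, ann$chrom_sizes, 150),
                           ann$genes, ann$chrom_sizes)
  idx_b <- compute_indices(extend_reads(sim_b$tags, ann$chrom_sizes, 150),
                           ann$genes, ann$chrom_sizes)
  ok <- !is.na(idx_a$pi) & !is.na(idx_b$pi)
  expect_gt(sum(ok), 90)
  expect_gt(cor(log2(idx_a$pi[ok]), log2(idx_b$pi[ok])), 0.9)
  # and the estimates track the planted per-gene rates
  truth_pi <- sim_a$truth$gene_rates$rate_promoter / sim_a$truth$gene_rates$rate_body
  expect_gt(cor(log2(idx_a$pi[ok]), log2(truth_pi[ok])), 0.9)
})

test_that("tertile grouping partitions genes evenly with stable ties", {
  x <- tibble::tibble(name = letters[1:9], value = c(9, 8, 7, 6, 5, 4, 3, 2, 1))
  g <- tertile_groups(x)
  expect_equal(as.integer(table(g$group)[c("low", "medium", "high")]), c(3L, 3L, 3L))
  expect_setequal(g$name[g$group == "high"], c("a", "b", "c"))
  expect_warning(g2 <- tertile_groups(tibble::tibble(name = letters[1:4], value = rep(1, 4))),
                 "equal")
  expect_true(all(g2$group == "medium"))
  expect_error(tertile_groups(tibble::tibble(name = "a", value = 1)), "at least 3")

  set.seed(151)
  big <- tibble::tibble(name = sprintf("g%04d", 1:1000),
                        value = c(rnorm(990), rep(NA, 10)))
  gb <- tertile_groups(big)
  expect_equal(nrow(gb), 990)
  expect_lte(diff(range(table(gb$group))), 1)
})
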