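# Fixtures plant exact tag counts in candidate peaks, their shores, and the
# Input library so every fold change is hand-computable.

build_peak_fixture <- function() {
  cs <- tibble::tibble(chrom = "chr1", size = 100000)
  # three 500 bp candidates with 500 bp shores each side
  cand <- tibble::tibble(chrom = "chr1", start = c(10000, 30000, 50000),
                         end = c(10500, 30500, 50500))
  case_lib_filler <- contained_tags("chr1", 90000, 95000, 940)
  input_filler <- contained_tags("chr1", 90000, 95000, 980)
  # candidate 1: case 25, input 4, shores 5 each -> FC_input 6.25, FC_shore 2.5 (kept)
  # candidate 2: case 20, input 5, shores 2 each -> FC_input 4 (dropped)
  # candidate 3: case 20, input 0 -> delta rule, shores 2 each
  case <- dplyr::bind_rows(
    case_lib_filler,
    contained_tags("chr1", 10000, 10500, 25),
    contained_tags("chr1", 9500, 10000, 5), contained_tags("chr1", 10500, 11000, 5),
    contained_tags("chr1", 30000, 30500, 20),
    contained_tags("chr1", 29500, 30000, 2), contained_tags("chr1", 30500, 31000, 2),
    contained_tags("chr1", 50000, 50500, 20),
    contained_tags("chr1", 49500, 50000, 2), contained_tags("chr1", 50500, 51000, 2)
  )
  input <- dplyr::bind_rows(
    input_filler,
    contained_tags("chr1", 10000, 10500, 4),
    contained_tags("chr1", 30000, 30500, 5)
  )
  list(cs = cs, cand = cand, case = case, input = input,
       case_lib = nrow(case), input_lib = nrow(input))
}

test_that("filter_sharp applies the 5x Input and 2x shore rules with the delta guard", {
  fx <- build_peak_fixture()
  kept <- filter_sharp(fx$cand, fx$case, fx$input, fx$cs)
  # hand computation: densities are counts / width / lib (common 1e9 scale cancels)
  d <- function(n, lib, w = 500) n * 1e9 / (w * lib)
  # candidate 1: FC_input = 25/caselib over 4/inputlib
  expect_equal(sort(kept$start), c(10000, 50000))
  fc1_input <- d(25, fx$case_lib) / d(4, fx$input_lib)
  fc1_shore <- d(25, fx$case_lib) / d(5, fx$case_lib)
  expect_equal(kept$fc_input[kept$start == 10000], fc1_input)
  expect_equal(kept$fc_shore[kept$start == 10000], fc1_shore)
  # candidate 2 fails FC_input = (20/caselib)/(5/inputlib) < 5
  expect_false(30000 %in% kept$start)
  # candidate 3: input 0 -> denominator is delta = one fragment's RPKM
  fc3_input <- d(20, fx$case_lib) / d(1, fx$input_lib)
  expect_equal(kept$fc_input[kept$start == 50000], fc3_input)
  expect_true(all(kept$peak_class == "sharp"))
})

test_that("filter_sharp is monotone in the Input fold-change threshold", {
  fx <- build_peak_fixture()
  kept5 <- filter_sharp(fx$cand, fx$case, fx$input, fx$cs, fc_input_min = 5)
  kept8 <- filter_sharp(fx$cand, fx$case, fx$input, fx$cs, fc_input_min = 8)
  kept100 <- filter_sharp(fx$cand, fx$case, fx$input, fx$cs, fc_input_min = 100)
  expect_true(all(kept8$start %in% kept5$start))
  expect_true(all(kept100$start %in% kept8$start))
})

test_that("candidates with no usable shore are dropped with a reason", {
  cs <- tibble::tibble(chrom = "chr1", size = 1000)
  cand <- tibble::tibble(chrom = "chr1", start = 100, end = 900)  # both shores clipped
  case <- contained_tags("chr1", 100, 900, 50, width = 20)
  input <- contained_tags("chr1", 0, 1000, 10, width = 20)
  expect_message(kept <- filter_sharp(cand, case, input, cs), "no usable shore")
  expect_equal(nrow(kept), 0)
  expect_equal(attr(kept, "dropped")$reason, "no_usable_shore")
})

test_that("derive_broad subtracts sharp peaks and drops slivers", {
  epic <- tibble::tibble(chrom = "chr1", start = 0, end = 10000)
  sharp <- tibble::tibble(chrom = "chr1", start = 2000, end = 2500)
  broad <- derive_broad(epic, sharp)
  expect_equal(broad$start, c(0L, 2500L))
  expect_equal(broad$end, c(2000L, 10000L))
  expect_true(all(broad$source == "derived"))
  # epic peak fully inside a sharp peak -> nothing
  expect_equal(nrow(derive_broad(tibble::tibble(chrom = "chr1", start = 2100, end = 2400),
                                 sharp)), 0)
  # sliver below one read length dropped
  sliver <- derive_broad(tibble::tibble(chrom = "chr1", start = 1900, end = 2600), sharp)
  expect_equal(nrow(sliver), 0)

  set.seed(141)
  for (i in 1:25) {
    e <- random_intervals(6, chroms = "chr1")
    s <- random_intervals(4, chroms = "chr1")
    b <- derive_broad(e, s, min_broad_width = 1)
    occ <- base_set(b, "chr1")[[1]] & base_set(s, "chr1")[[1]]
    expect_false(any(occ))
  }
})

test_that("peak annotation assigns midpoints by promoter > terminator > body priority", {
  genes <- tibble::tibble(chrom = "chr1",
                          start = c(10000, 13500), end = c(13000, 40000),
                          name = c("gA", "gB"), score = 0, strand = c("+", "+"))
  peaks <- tibble::tibble(chrom = "chr1",
                          start = c(10900, 90000, 20000, 15600, 13400),
                          end = c(11100, 90200, 20200, 15800, 13600))
  assigned <- assign_peak_features(peaks, genes)
  # midpoint 11000: 1 kb downstream of gA TSS -> promoter
  expect_equal(assigned$feature[1], "promoter")
  expect_equal(assigned$feature[2], "intergenic")
  expect_equal(assigned$feature[3], "gene_body")
  # midpoint 15700 is in gA terminator (13000..16000) AND gB body -> terminator wins over body
  expect_equal(assigned$feature[4], "terminator")
  # midpoint 13500 is in gB promoter (11500..15500) and gA terminator -> promoter wins
  expect_equal(assigned$feature[5], "promoter")
  dist <- annotate_peaks(peaks, genes)
  expect_equal(sum(dist$percent), 100, tolerance = 0.01)
  expect_equal(sum(dist$n), nrow(peaks))
})
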