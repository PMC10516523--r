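# Seeded generators for annotations, KAS tag sets, strand-specific window
# counts, and time-course count matrices with the statistical structure the
# analysis modules assume, so the whole pipeline is testable offline.
# All randomness flows from spec$seed through fixed per-generator offsets,
# so the same spec yields byte-identical files.

#' Simulation specification
#'
#' Bundles every knob of the synthetic-data generators with defaults that
#' describe a small but realistic mammalian-like study: two chromosomes,
#' 100 non-overlapping genes of 5-20 kb, KAS tag rates of 10/2/4 tags per
#' kb in promoter/body/termination regions over a 0.1 per kb background,
#' 1 kb enhancers at 80 tags/kb (4 per 50 bp bin) with 4-fold shore
#' contrast for the paused class, strand-imbalance windows of 500 bp at
#' negative-binomial mean 50 and dispersion 0.05 with 2 replicates, and a
#' 6-timepoint (0-12 h) x 2-replicate time course at dispersion 0.05.
#'
#' @param seed Integer master seed.
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param n_genes,gene_width Gene count and width range in bp.
#' @param rate_promoter,rate_body,rate_termination,rate_background Expected
#'   tags per kb per region class.
#' @param gene_rate_sdlog When positive, per-gene log-normal multipliers
#'   (sdlog on this scale) are applied to the promoter and termination
#'   rates, emulating gene-to-gene variation in pausing and termination
#'   efficiency; 0 (default) gives a homogeneous cohort.
#' @param depth Optional total tag count; when given, all rates are scaled
#'   so the expected total equals `depth`; when `NULL` rates are absolute.
#' @param read_length Raw tag width in bp before extension.
#' @param n_enhancers,enhancer_width,paused_fraction Enhancer cohort.
#' @param enhancer_rate Tags per kb inside enhancers.
#' @param enhancer_fold Enhancer/shore rate ratio for the paused class
#'   (pass-through enhancers use the enhancer rate in their shores too).
#' @param n_windows,window_size spKAS window grid.
#' @param window_mu,window_dispersion,n_reps NB count model per strand.
#' @param n_rloop_regions,rloop_log2fc,rloop_region_windows Planted
#'   imbalanced regions (consecutive-window blocks, alternating strand).
#' @param rnaseh_deflation Count deflation in planted regions for the
#'   simulated RNase H-treated condition.
#' @param timepoints,tc_reps,tc_dispersion,tc_genes_per_class Time-course
#'   design (timepoints in hours).
#' @param tc_class_counts Optional named vector overriding the per-class
#'   feature counts, e.g. `c(constant = 200, monotone = 0, pulse = 0)` for
#'   an all-null cohort.
#' @return A `kas_sim_spec` list.
#' @export
sim_spec <- function(seed = 1,
                     chrom_lengths = c(chrS1 = 2e6, chrS2 = 2e6),
                     n_genes = 100, gene_width = c(5000, 20000),
                     rate_promoter = 10, rate_body = 2,
                     rate_termination = 4, rate_background = 0.1,
                     gene_rate_sdlog = 0,
                     depth = NULL, read_length = 36,
                     n_enhancers = 100, enhancer_width = 1000,
                     paused_fraction = 0.5, enhancer_rate = 80,
                     enhancer_fold = 4,
                     n_windows = 5000, window_size = 500,
                     window_mu = 50, window_dispersion = 0.05, n_reps = 2,
                     n_rloop_regions = 0, rloop_log2fc = 2,
                     rloop_region_windows = 2, rnaseh_deflation = 4,
                     timepoints = c(0, 0.5, 1.5, 3, 6, 12), tc_reps = 2,
                     tc_dispersion = 0.05, tc_genes_per_class = 200,
                     tc_class_counts = NULL) {
  spec <- as.list(environment())
  class(spec) <- "kas_sim_spec"
  spec
}

#' Simulate a genome annotation
#'
#' Places non-overlapping genes (both strands represented) and distal
#' enhancers at least 5 kb from every gene, walking left to right along
#' each chromosome with seeded random gaps.
#'
#' @param spec A `kas_sim_spec`.
#' @return List: `chrom_sizes` tibble, `genes` tibble, `enhancers` tibble.
#' @export
simulate_annotation <- function(spec) {
  set.seed(spec$seed + 1L)
  chroms <- names(spec$chrom_lengths)
  n_chrom <- length(chroms)
  genes_per_chrom <- diff(round(seq(0, spec$n_genes, length.out = n_chrom + 1)))
  enh_per_chrom <- diff(round(seq(0, spec$n_enhancers, length.out = n_chrom + 1)))
  genes <- list(); enhancers <- list()
  for (ci in seq_along(chroms)) {
    L <- spec$chrom_lengths[ci]
    cursor <- 5000
    g <- list()
    for (i in seq_len(genes_per_chrom[ci])) {
      w <- round(runif(1, spec$gene_width[1], spec$gene_width[2]))
      # gap > 2 x term_flank so termination regions of convergent gene
      # pairs never overlap (the region-rate model is per gene)
      cursor <- cursor + round(runif(1, 6500, 9500))
      if (cursor + w + 5000 > L) abort("simulate_annotation: infeasible gene packing")
      g[[i]] <- tibble(chrom = chroms[ci], start = cursor, end = cursor + w)
      cursor <- cursor + w
    }
    g <- dplyr::bind_rows(g)
    cursor <- cursor + 10000  # distal margin before the enhancer block
    e <- list()
    for (i in seq_len(enh_per_chrom[ci])) {
      cursor <- cursor + round(runif(1, 3000, 5000))
      if (cursor + spec$enhancer_width + 2000 > L) {
        abort("simulate_annotation: infeasible enhancer packing")
      }
      e[[i]] <- tibble(chrom = chroms[ci], start = cursor,
                       end = cursor + spec$enhancer_width)
      cursor <- cursor + spec$enhancer_width
    }
    genes[[ci]] <- g
    enhancers[[ci]] <- dplyr::bind_rows(e)
  }
  empty <- tibble(chrom = character(), start = integer(), end = integer())
  genes <- dplyr::bind_rows(c(list(empty), genes))
  genes$name <- sprintf("gene_%03d", seq_len(nrow(genes)))
  genes$score <- rep(0, nrow(genes))
  genes$strand <- rep_len(c("+", "-"), nrow(genes))[sample.int(max(nrow(genes), 1))[seq_len(nrow(genes))]]
  # per-gene pausing/termination efficiency multipliers (1 when homogeneous)
  genes$promoter_factor <- if (spec$gene_rate_sdlog > 0) {
    exp(stats::rnorm(nrow(genes), 0, spec$gene_rate_sdlog))
  } else rep(1, nrow(genes))
  genes$termination_factor <- if (spec$gene_rate_sdlog > 0) {
    exp(stats::rnorm(nrow(genes), 0, spec$gene_rate_sdlog))
  } else rep(1, nrow(genes))
  enhancers <- dplyr::bind_rows(c(list(empty), enhancers))
  if (nrow(enhancers) > 0) {
    enhancers$name <- sprintf("enh_%03d", seq_len(nrow(enhancers)))
    enhancers$score <- 0
    enhancers$strand <- "."
    cls <- rep("pass_through", nrow(enhancers))
    cls[seq_len(round(spec$paused_fraction * nrow(enhancers)))] <- "paused"
    enhancers$class <- sample(cls)
  }
  list(
    chrom_sizes = tibble(chrom = chroms, size = unname(spec$chrom_lengths)),
    genes = genes[c("chrom", "start", "end", "name", "score", "strand",
                    "promoter_factor", "termination_factor")],
    enhancers = enhancers
  )
}

# Poisson tag placement: n ~ Pois(rate_kb * width/1000 * scale), 5'
# positions uniform in the region, random strand, read_length width.
place_tags <- function(chrom, start, end, rate_kb, scale, read_length, chrom_len) {
  width <- end - start
  n <- rpois(1, rate_kb * width / 1000 * scale)
  if (n == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = double(), strand = character()))
  }
  strand <- sample(c("+", "-"), n, replace = TRUE)
  pos5 <- start + floor(runif(n) * width)
  s <- ifelse(strand == "+", pos5, pmax(pos5 - read_length + 1, 0))
  e <- ifelse(strand == "+", pmin(pos5 + read_length, chrom_len), pos5 + 1)
  tibble(chrom = chrom, start = as.integer(s), end = as.integer(pmax(e, s + 1)),
         name = ".", score = 0, strand = strand)
}

#' Simulate a KAS-seq tag set over an annotation
#'
#' Places Poisson tags region by region: promoter/body/termination regions
#' of every gene at the spec's per-kb rates, enhancers (and, for the
#' pass-through class, their shores) at the enhancer rate, paused-enhancer
#' shores at `enhancer_rate / enhancer_fold`, and a uniform genome-wide
#' background. Raw tags are `read_length` bp; run [extend_reads()] before
#' analysis, as with real data.
#'
#' @param spec A `kas_sim_spec`.
#' @param annotation Result of [simulate_annotation()].
#' @return List: `tags` tibble (shuffled into coordinate-sorted order),
#'   `truth` list with per-gene rates and per-enhancer classes, `scale`
#'   the depth scaling applied.
#' @export
simulate_kas_tags <- function(spec, annotation) {
  set.seed(spec$seed + 2L)
  sizes <- chrom_size_lookup(annotation$chrom_sizes)
  genes <- annotation$genes
  enh <- annotation$enhancers
  regions <- gene_regions(genes, annotation$chrom_sizes)

  pf <- genes$promoter_factor %||% rep(1, nrow(genes))
  tf <- genes$termination_factor %||% rep(1, nrow(genes))
  genome_kb <- sum(sizes) / 1000
  expected <- sum(
    (regions$promoter_end - regions$promoter_start) / 1000 * spec$rate_promoter * pf,
    (regions$body_end - regions$body_start) / 1000 * spec$rate_body,
    (regions$term_end - regions$term_start) / 1000 * spec$rate_termination * tf,
    na.rm = TRUE
  ) + genome_kb * spec$rate_background
  if (nrow(enh) > 0) {
    shore_rate <- spec$enhancer_rate / spec$enhancer_fold
    enh_kb <- (enh$end - enh$start) / 1000
    expected <- expected + sum(enh_kb * spec$enhancer_rate) +
      sum(ifelse(enh$class == "paused", 2 * enh_kb * shore_rate, 2 * enh_kb * spec$enhancer_rate))
  }
  scale <- if (is.null(spec$depth)) 1 else spec$depth / expected

  out <- list()
  add <- function(chrom, start, end, rate) {
    place_tags(chrom, start, end, rate, scale, spec$read_length, sizes[chrom])
  }
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    out[[length(out) + 1]] <- add(r$chrom, r$promoter_start, r$promoter_end,
                                  spec$rate_promoter * pf[i])
    out[[length(out) + 1]] <- add(r$chrom, r$body_start, r$body_end, spec$rate_body)
    out[[length(out) + 1]] <- add(r$chrom, r$term_start, r$term_end,
                                  spec$rate_termination * tf[i])
  }
  if (nrow(enh) > 0) {
    sh <- make_shores(enh[c("chrom", "start", "end")], annotation$chrom_sizes)
    shore_rate <- spec$enhancer_rate / spec$enhancer_fold
    for (i in seq_len(nrow(enh))) {
      rate_sh <- if (enh$class[i] == "paused") shore_rate else spec$enhancer_rate
      out[[length(out) + 1]] <- add(enh$chrom[i], enh$start[i], enh$end[i], spec$enhancer_rate)
      out[[length(out) + 1]] <- add(enh$chrom[i], sh$left_start[i], sh$left_end[i], rate_sh)
      out[[length(out) + 1]] <- add(enh$chrom[i], sh$right_start[i], sh$right_end[i], rate_sh)
    }
  }
  for (chrom in names(sizes)) {
    out[[length(out) + 1]] <- add(chrom, 0, sizes[chrom], spec$rate_background)
  }
  tags <- dplyr::bind_rows(out)
  tags <- tags[order(tags$chrom, tags$start, tags$end, tags$strand), ]
  truth <- list(
    gene_rates = tibble(name = genes$name,
                        rate_promoter = spec$rate_promoter * pf,
                        rate_body = spec$rate_body,
                        rate_termination = spec$rate_termination * tf),
    enhancer_class = if (nrow(enh) > 0) enh[c("name", "class")] else NULL
  )
  list(tags = tags, truth = truth, scale = scale)
}

#' Simulate strand-specific window counts and tag files
#'
#' Builds a window grid (blocks of 10 windows form the parent "peaks"),
#' draws per-replicate negative-binomial counts for each strand -- balanced
#' at `window_mu` except in planted R-loop regions, where the strand means
#' are `mu * 2^(+-log2fc / 2)` with alternating dominant strand -- and
#' materializes the counts as 150 bp tags contained in their window, so
#' window re-counting reproduces the simulated matrix exactly. A treated
#' condition (planted-region counts divided by `rnaseh_deflation`, other
#' windows untouched) emulates RNase H.
#'
#' @param spec A `kas_sim_spec` (`n_rloop_regions > 0` to plant regions).
#' @return List: `chrom_sizes`, `peaks`, `windows`, count matrices
#'   (`counts`, `treated_counts`; columns plus_1..r, minus_1..r),
#'   per-replicate tag tibbles (`plus_tags`, `minus_tags`,
#'   `treated_plus_tags`, `treated_minus_tags`), and `truth` region tibble.
#' @export
simulate_spkas_tags <- function(spec) {
  set.seed(spec$seed + 3L)
  n <- spec$n_windows
  size <- spec$window_size
  block <- 10L
  gap <- 1000L
  n_blocks <- ceiling(n / block)
  block_starts <- 5000 + (seq_len(n_blocks) - 1) * (block * size + gap)
  chrom_len <- max(block_starts) + block * size + 10000
  chrom_sizes <- tibble(chrom = "chrSP", size = chrom_len)
  win_start <- unlist(lapply(block_starts, function(b) b + (0:(block - 1)) * size))[seq_len(n)]
  windows <- tibble(chrom = "chrSP", start = as.integer(win_start),
                    end = as.integer(win_start + size))
  peaks <- interval_merge(windows)

  r <- spec$n_reps
  mu <- matrix(spec$window_mu, nrow = n, ncol = 2)  # plus, minus means
  truth <- tibble(chrom = character(), start = integer(), end = integer(),
                  dominant_strand = character(), log2fc = double())
  planted_windows <- integer(0)
  if (spec$n_rloop_regions > 0) {
    k <- spec$rloop_region_windows
    # candidate block-aligned slots, spaced so planted regions never touch
    slots <- seq(1, n - k + 1, by = max(2 * k + 2, block))
    if (length(slots) < spec$n_rloop_regions) {
      abort("simulate_spkas_tags: too many planted regions for the window grid")
    }
    chosen <- sort(sample(slots, spec$n_rloop_regions))
    sgn <- rep_len(c(1, -1), spec$n_rloop_regions)
    for (j in seq_along(chosen)) {
      idx <- chosen[j]:(chosen[j] + k - 1)
      mu[idx, 1] <- spec$window_mu * 2^(sgn[j] * spec$rloop_log2fc / 2)
      mu[idx, 2] <- spec$window_mu * 2^(-sgn[j] * spec$rloop_log2fc / 2)
      planted_windows <- c(planted_windows, idx)
      truth <- dplyr::bind_rows(truth, tibble(
        chrom = "chrSP", start = windows$start[idx[1]], end = windows$end[idx[k]],
        dominant_strand = if (sgn[j] > 0) "+" else "-", log2fc = spec$rloop_log2fc
      ))
    }
  }
  draw <- function(mu_col) {
    matrix(rnbinom(n * r, mu = rep(mu_col, r), size = 1 / spec$window_dispersion), ncol = r)
  }
  counts <- cbind(draw(mu[, 1]), draw(mu[, 2]))
  colnames(counts) <- c(paste0("plus_", seq_len(r)), paste0("minus_", seq_len(r)))
  storage.mode(counts) <- "integer"
  treated <- counts
  if (length(planted_windows) > 0) {
    treated[planted_windows, ] <- as.integer(round(counts[planted_windows, ] /
                                                     spec$rnaseh_deflation))
  }

  tags_from_counts <- function(cnt, strand) {
    total <- sum(cnt)
    idx <- rep.int(seq_len(n), cnt)
    offs <- floor(runif(total) * (size - 150))
    tibble(chrom = "chrSP",
           start = as.integer(windows$start[idx] + offs),
           end = as.integer(windows$start[idx] + offs + 150L),
           name = ".", score = 0, strand = strand)
  }
  mk_tags <- function(mat, strand, cols) {
    lapply(seq_len(r), function(i) {
      x <- tags_from_counts(mat[, cols[i]], strand)
      x[order(x$start), ]
    })
  }
  list(
    chrom_sizes = chrom_sizes, peaks = peaks, windows = windows,
    counts = counts, treated_counts = treated,
    plus_tags = mk_tags(counts, "+", seq_len(r)),
    minus_tags = mk_tags(counts, "-", r + seq_len(r)),
    treated_plus_tags = mk_tags(treated, "+", seq_len(r)),
    treated_minus_tags = mk_tags(treated, "-", r + seq_len(r)),
    truth = truth
  )
}

#' Simulate a time-course count matrix with known trajectory classes
#'
#' Draws equal numbers of constant, monotone (sigmoid), and pulse
#' (impulse) features with negative-binomial noise at the spec's
#' dispersion, across the spec's timepoints and replicates. Baseline
#' levels, fold changes, transition times, and up/down directions are
#' drawn per feature from fixed realistic ranges.
#'
#' @param spec A `kas_sim_spec`.
#' @return List: `tc` (a `kas_tc`), `truth` tibble (`feature`, `class`,
#'   `direction`).
#' @export
simulate_timecourse_counts <- function(spec) {
  set.seed(spec$seed + 4L)
  tp <- spec$timepoints
  r <- spec$tc_reps
  times <- rep(tp, each = r)
  class_counts <- spec$tc_class_counts %||%
    c(constant = spec$tc_genes_per_class, monotone = spec$tc_genes_per_class,
      pulse = spec$tc_genes_per_class)
  classes <- rep(names(class_counts), times = class_counts)
  n_feat <- length(classes)
  mu <- matrix(NA_real_, nrow = n_feat, ncol = length(times))
  direction <- character(n_feat)
  for (i in seq_len(n_feat)) {
    base <- runif(1, 30, 120)
    up <- runif(1) < 0.5
    direction[i] <- if (up) "up" else "down"
    if (classes[i] == "constant") {
      mu[i, ] <- base
      direction[i] <- "none"
    } else if (classes[i] == "monotone") {
      fold <- runif(1, 3, 8)
      h1 <- if (up) base * fold else base / fold
      pars <- list(beta = runif(1, 0.8, 3), h0 = base, h1 = h1,
                   t1 = runif(1, 1, 6))
      mu[i, ] <- sigmoid_value(times, pars)
    } else {
      fold <- runif(1, 4, 10)
      h1 <- if (up) base * fold else base / fold
      t1 <- runif(1, 0.5, 3)
      pars <- list(beta = runif(1, 0.8, 3), h0 = base, h1 = h1, h2 = base,
                   t1 = t1, t2 = t1 + runif(1, 2, 6))
      mu[i, ] <- impulse_value(times, pars)
    }
  }
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / spec$tc_dispersion),
                   nrow = n_feat)
  rownames(counts) <- sprintf("feat_%04d", seq_len(n_feat))
  colnames(counts) <- sprintf("t%g_rep%d", times, rep(seq_len(r), times = length(tp)))
  metadata <- tibble(sample = colnames(counts), timepoint = times,
                     replicate = rep(seq_len(r), times = length(tp)))
  features <- tibble(chrom = "chrTC", start = (seq_len(n_feat) - 1) * 2000,
                     end = seq_len(n_feat) * 2000, name = rownames(counts))
  sf <- tryCatch(size_factors(counts), error = function(e) rep(1, ncol(counts)))
  tc <- structure(list(counts = counts, features = features, metadata = metadata,
                       size_factors = sf), class = "kas_tc")
  list(tc = tc, truth = tibble(feature = rownames(counts), class = classes,
                               direction = direction))
}
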