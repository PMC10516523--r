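# Time-course trajectory classification. Per-feature counts across ordered
# timepoints are fit with three nested negative-binomial mean models --
# constant (1 parameter), sigmoid (4: beta, h0, h1, t1), and impulse (6:
# beta, h0, h1, h2, t1, t2) -- with a fixed per-feature dispersion
# estimated by method of moments and shrunk toward an across-feature
# trend. Likelihood-ratio tests split features into steadily regulated
# (impulse beats constant but not sigmoid) and transiently regulated
# (impulse also beats sigmoid).

logistic <- function(x) 1 / (1 + exp(-x))

#' Impulse model value
#'
#' The six-parameter product-of-sigmoids impulse curve
#' `f(t) = (1/h1) * [h0 + (h1-h0)*s(beta*(t-t1))] * [h2 + (h1-h2)*s(-beta*(t-t2))]`
#' with `s` the standard logistic: a rise (or fall) from plateau `h0`
#' toward peak `h1` at transition `t1`, returning to plateau `h2` at `t2`.
#'
#' @param t Numeric vector of times.
#' @param params Named list/vector with `beta`, `h0`, `h1`, `h2`, `t1`, `t2`;
#'   `h1` must be positive.
#' @return Expected level at each `t`.
#' @export
impulse_value <- function(t, params) {
  p <- as.list(params)
  if (p$h1 <= 0) abort("impulse_value: h1 must be positive")
  (1 / p$h1) *
    (p$h0 + (p$h1 - p$h0) * logistic(p$beta * (t - p$t1))) *
    (p$h2 + (p$h1 - p$h2) * logistic(-p$beta * (t - p$t2)))
}

#' Sigmoid (monotone) model value
#'
#' `f(t) = h0 + (h1 - h0) * s(beta * (t - t1))`.
#'
#' @inheritParams impulse_value
#' @return Expected level at each `t`.
#' @export
sigmoid_value <- function(t, params) {
  p <- as.list(params)
  p$h0 + (p$h1 - p$h0) * logistic(p$beta * (t - p$t1))
}

#' Build a feature-by-sample time-course count matrix
#'
#' Counts tags overlapping each feature per sample and attaches sample
#' metadata and median-of-ratios size factors.
#'
#' @param tag_sets Named list of tag tibbles, one per sample, in the order
#'   of `metadata` rows.
#' @param features Feature tibble with a unique `name` column.
#' @param metadata Tibble with columns `sample`, `timepoint` (numeric
#'   hours) and optionally `replicate`.
#' @return A `kas_tc` object: list with `counts` (features x samples
#'   matrix), `features`, `metadata`, `size_factors`.
#' @export
build_count_matrix <- function(tag_sets, features, metadata) {
  features <- validate_intervals(features, what = "features")
  metadata <- as_tibble(metadata)
  if (!all(c("sample", "timepoint") %in% names(metadata))) {
    abort("build_count_matrix: metadata needs 'sample' and 'timepoint' columns")
  }
  if (any(is.na(metadata$timepoint))) abort("build_count_matrix: sample missing timepoint")
  if (length(tag_sets) != nrow(metadata)) {
    abort("build_count_matrix: one tag set per metadata row required")
  }
  fgr <- as_granges(features[c("chrom", "start", "end")])
  counts <- vapply(tag_sets, function(tags) {
    if (nrow(tags) == 0) return(integer(length(fgr)))
    GenomicRanges::countOverlaps(fgr, as_granges(tags), ignore.strand = TRUE)
  }, integer(length(fgr)))
  rownames(counts) <- features$name
  colnames(counts) <- metadata$sample
  sf <- tryCatch(size_factors(counts), error = function(e) rep(1, ncol(counts)))
  structure(list(counts = counts, features = features, metadata = metadata,
                 size_factors = sf),
            class = "kas_tc")
}

#' @export
print.kas_tc <- function(x, ...) {
  cat(sprintf("# KAS time-course matrix: %d features x %d samples, %d timepoints\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$metadata$timepoint))))
  invisible(x)
}

#' Tidy a time-course matrix into long form
#'
#' @param x A `kas_tc`.
#' @param ... Unused.
#' @return Tibble `feature`, `sample`, `timepoint`, `count`,
#'   `normalized_count`.
#' @export
tidy.kas_tc <- function(x, ...) {
  long <- as_tibble(as.data.frame.table(x$counts, stringsAsFactors = FALSE))
  names(long) <- c("feature", "sample", "count")
  long$timepoint <- x$metadata$timepoint[match(long$sample, x$metadata$sample)]
  long$normalized_count <- long$count / x$size_factors[match(long$sample, x$metadata$sample)]
  long[c("feature", "sample", "timepoint", "count", "normalized_count")]
}

# NB log-likelihood of counts y with mean sf * f(t) and dispersion alpha
nb_loglik <- function(y, mu, alpha) {
  mu <- pmax(mu, 1e-8)
  sum(dnbinom(y, mu = mu, size = 1 / alpha, log = TRUE))
}

# Per-feature MoM dispersion pooled over timepoints (replicates within a
# timepoint are the NB draws), shrunk toward the across-feature trend.
tc_dispersions <- function(counts, timepoints, sf) {
  norm <- sweep(counts, 2, sf, "/")
  groups <- split(seq_along(timepoints), timepoints)
  reps_ok <- lengths(groups) >= 2
  per_feature <- function(row) {
    ms <- vapply(groups[reps_ok], function(idx) mean(row[idx]), numeric(1))
    vs <- vapply(groups[reps_ok], function(idx) var(row[idx]), numeric(1))
    mu <- mean(ms); v <- mean(vs)
    c(mu = mu, alpha = (v - mu) / mu^2)
  }
  est <- t(apply(norm, 1, per_feature))
  shrink_dispersions(est[, "mu"], est[, "alpha"])
}

fit_one_model <- function(y, t, sf, alpha_disp, model, starts) {
  nll <- switch(model,
    constant = function(par) -nb_loglik(y, sf * exp(par[1]), alpha_disp),
    sigmoid = function(par) {
      f <- sigmoid_value(t, list(beta = exp(par[1]), h0 = exp(par[2]),
                                 h1 = exp(par[3]), t1 = par[4]))
      -nb_loglik(y, sf * f, alpha_disp)
    },
    impulse = function(par) {
      f <- impulse_value(t, list(beta = exp(par[1]), h0 = exp(par[2]),
                                 h1 = exp(par[3]), h2 = exp(par[4]),
                                 t1 = par[5], t2 = par[5] + exp(par[6])))
      -nb_loglik(y, sf * f, alpha_disp)
    }
  )
  t_lo <- min(t) - diff(range(t)); t_hi <- max(t) + diff(range(t))
  bounds <- switch(model,
    constant = list(lower = log(1e-6), upper = log(1e9)),
    sigmoid = list(lower = c(log(0.05), log(1e-6), log(1e-6), t_lo),
                   upper = c(log(20), log(1e9), log(1e9), t_hi)),
    impulse = list(lower = c(log(0.05), rep(log(1e-6), 3), t_lo, log(1e-3)),
                   upper = c(log(20), rep(log(1e9), 3), t_hi, log(4 * diff(range(t)) + 1)))
  )
  best <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, bounds$lower), bounds$upper)
    fit <- tryCatch(
      optim(st, nll, method = "L-BFGS-B",
            lower = bounds$lower, upper = bounds$upper,
            control = list(maxit = 200)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  best
}

#' Fit constant, sigmoid, and impulse NB models to one feature
#'
#' Maximizes the negative-binomial log-likelihood (dispersion fixed) for
#' the three nested mean models with multi-start bounded optimization;
#' transition times are initialized on the observed timepoint grid, and
#' each richer model is additionally seeded with the simpler model's
#' solution so the nested log-likelihood ordering holds up to optimizer
#' tolerance.
#'
#' @param y Integer counts for one feature across samples.
#' @param timepoints Numeric timepoint per sample (>= 3 distinct values).
#' @param sf Size factor per sample.
#' @param dispersion Fixed NB dispersion alpha for this feature.
#' @return A `kas_impulse_fit`: impulse parameters, the three
#'   log-likelihoods, the dispersion, and a convergence flag.
#' @export
fit_trajectory_models <- function(y, timepoints, sf, dispersion) {
  t <- timepoints
  if (length(unique(t)) < 3) abort("fit_trajectory_models: need >= 3 distinct timepoints")
  tp <- sort(unique(t))
  norm <- y / sf
  tp_means <- vapply(tp, function(ti) mean(norm[t == ti]), numeric(1))
  m0 <- max(mean(norm), 1e-4)

  fit_c <- fit_one_model(y, t, sf, dispersion, "constant", list(log(m0)))
  h_const <- exp(fit_c$par[1])

  lg <- function(x) log(pmax(x, 1e-4))
  sig_starts <- list()
  for (t1 in tp[-length(tp)]) {
    sig_starts <- c(sig_starts,
                    list(c(log(1), lg(tp_means[1]), lg(tp_means[length(tp)]), t1)))
  }
  # degenerate flat start: sigmoid nests constant
  sig_starts <- c(sig_starts, list(c(log(1), lg(h_const), lg(h_const), median(tp))))
  fit_s <- fit_one_model(y, t, sf, dispersion, "sigmoid", sig_starts)

  peak <- tp[which.max(tp_means)]
  dip <- tp[which.min(tp_means)]
  imp_starts <- list()
  for (tmid in unique(c(peak, dip))) {
    for (span in c(diff(range(tp)) / 4, diff(range(tp)) / 2)) {
      imp_starts <- c(imp_starts, list(c(
        log(1), lg(tp_means[1]), lg(max(tp_means)), lg(tp_means[length(tp)]),
        tmid - span / 2, log(max(span, 1e-2))
      )))
      imp_starts <- c(imp_starts, list(c(
        log(1), lg(tp_means[1]), lg(min(tp_means) + 1e-4), lg(tp_means[length(tp)]),
        tmid - span / 2, log(max(span, 1e-2))
      )))
    }
  }
  # degenerate starts: impulse nests sigmoid (second transition far right)
  far <- max(tp) + diff(range(tp))
  sp <- fit_s$par
  imp_starts <- c(imp_starts,
                  list(c(sp[1], sp[2], sp[3], sp[3], sp[4], log(far - sp[4] + 1))),
                  list(c(log(1), lg(h_const), lg(h_const), lg(h_const), median(tp), log(1))))
  fit_i <- fit_one_model(y, t, sf, dispersion, "impulse", imp_starts)

  converged <- !is.null(fit_c) && !is.null(fit_s) && !is.null(fit_i)
  if (!converged) {
    return(structure(list(converged = FALSE), class = "kas_impulse_fit"))
  }
  ip <- fit_i$par
  params <- list(beta = exp(ip[1]), h0 = exp(ip[2]), h1 = exp(ip[3]),
                 h2 = exp(ip[4]), t1 = ip[5], t2 = ip[5] + exp(ip[6]))
  ll_c <- -fit_c$value; ll_s <- -fit_s$value; ll_i <- -fit_i$value
  # enforce nesting against optimizer slack
  ll_s <- max(ll_s, ll_c)
  ll_i <- max(ll_i, ll_s)
  structure(list(
    params = params, h_const = h_const,
    sigmoid_params = list(beta = exp(sp[1]), h0 = exp(sp[2]), h1 = exp(sp[3]), t1 = sp[4]),
    loglik_constant = ll_c, loglik_sigmoid = ll_s, loglik_impulse = ll_i,
    dispersion = dispersion, timepoints = sort(unique(t)), converged = TRUE
  ), class = "kas_impulse_fit")
}

#' @export
print.kas_impulse_fit <- function(x, ...) {
  if (!x$converged) {
    cat("kas_impulse_fit: did not converge\n")
    return(invisible(x))
  }
  cat(sprintf("kas_impulse_fit: h0=%.2f h1=%.2f h2=%.2f t1=%.2f t2=%.2f beta=%.2f\n",
              x$params$h0, x$params$h1, x$params$h2, x$params$t1, x$params$t2, x$params$beta))
  cat(sprintf("  loglik constant %.2f | sigmoid %.2f | impulse %.2f (alpha=%.3g)\n",
              x$loglik_constant, x$loglik_sigmoid, x$loglik_impulse, x$dispersion))
  invisible(x)
}

#' @rdname fit_trajectory_models
#' @param x A `kas_impulse_fit`.
#' @param ... Unused.
#' @export
tidy.kas_impulse_fit <- function(x, ...) {
  if (!x$converged) return(tibble(term = character(), estimate = double()))
  tibble(term = names(x$params), estimate = unlist(x$params))
}

#' @rdname fit_trajectory_models
#' @export
glance.kas_impulse_fit <- function(x, ...) {
  if (!x$converged) return(tibble(converged = FALSE))
  tibble(loglik_constant = x$loglik_constant, loglik_sigmoid = x$loglik_sigmoid,
         loglik_impulse = x$loglik_impulse, dispersion = x$dispersion,
         converged = TRUE)
}

#' Fit trajectory models to every feature of a time-course matrix
#'
#' Estimates per-feature dispersions (method of moments, shrunk toward the
#' across-feature trend) and runs [fit_trajectory_models()] on each row.
#'
#' @param tc A `kas_tc` from [build_count_matrix()] or
#'   [simulate_timecourse_counts()].
#' @return Named list of `kas_impulse_fit` objects.
#' @export
fit_trajectories <- function(tc) {
  stopifnot(inherits(tc, "kas_tc"))
  # geometric-mean-1 size factors: keeps counts on their raw scale (the NB
  # dispersion is defined there) and makes a global rescale a no-op
  sf <- tc$size_factors / exp(mean(log(tc$size_factors)))
  disp <- tc_dispersions(tc$counts, tc$metadata$timepoint, sf)
  fits <- lapply(seq_len(nrow(tc$counts)), function(i) {
    fit_trajectory_models(tc$counts[i, ], tc$metadata$timepoint, sf, disp[i])
  })
  names(fits) <- rownames(tc$counts)
  fits
}

#' Classify features as steadily or transiently regulated
#'
#' Likelihood-ratio tests: impulse vs constant (5 df) gives `p_diff`;
#' impulse vs sigmoid (2 df) gives `p_trans`; each family is BH-adjusted.
#' `transient_*` requires both adjusted p-values <= `alpha`; `steady_*`
#' requires only the first. Direction is up when the fitted level at the
#' internal extremum (transient) or at the last timepoint (steady) exceeds
#' the fitted level at the first timepoint.
#'
#' @param fits Named list of `kas_impulse_fit` objects.
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @return Tibble: `feature`, `category` (steady_up/steady_down/
#'   transient_up/transient_down/not_significant), `p_diff`, `padj_diff`,
#'   `p_trans`, `padj_trans`.
#' @export
classify_trajectories <- function(fits, alpha = 0.05) {
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  fits_ok <- fits[ok]
  lrt <- function(f, ll0, df) pchisq(pmax(2 * (f$loglik_impulse - ll0), 0), df, lower.tail = FALSE)
  p_diff <- vapply(fits_ok, function(f) lrt(f, f$loglik_constant, 5), numeric(1))
  p_trans <- vapply(fits_ok, function(f) lrt(f, f$loglik_sigmoid, 2), numeric(1))
  padj_diff <- bh_adjust(p_diff)
  padj_trans <- bh_adjust(p_trans)
  category <- vapply(seq_along(fits_ok), function(i) {
    f <- fits_ok[[i]]
    if (padj_diff[i] > alpha) return("not_significant")
    tpts <- f$timepoints
    grid <- seq(min(tpts), max(tpts), length.out = 200)
    fv <- impulse_value(grid, f$params)
    ref <- fv[1]
    if (padj_trans[i] <= alpha) {
      extremum <- fv[which.max(abs(fv - ref))]
      if (extremum > ref) "transient_up" else "transient_down"
    } else {
      if (fv[length(fv)] > ref) "steady_up" else "steady_down"
    }
  }, character(1))
  out <- tibble(
    feature = names(fits_ok), category = category,
    p_diff = p_diff, padj_diff = padj_diff,
    p_trans = p_trans, padj_trans = padj_trans
  )
  if (any(!ok)) {
    out <- dplyr::bind_rows(out, tibble(
      feature = names(fits)[!ok], category = "not_converged",
      p_diff = NA_real_, padj_diff = NA_real_, p_trans = NA_real_, padj_trans = NA_real_
    ))
  }
  out
}
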