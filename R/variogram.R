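#' Abundance cut-off capturing a biomass fraction
#'
#' Ranks EDSUs by decreasing density and finds the smallest set whose
#' cumulated abundance reaches `fraction` of the total; the cut-off is the
#' density of the last EDSU included. Downstream membership uses
#' `z >= cutoff` - with a cut-off chosen at an observed density, a strict
#' inequality would drop the defining sample and capture less than the
#' requested fraction. Set `strict = TRUE` to use `z > cutoff` with the
#' cut-off nudged just below the defining density instead.
#'
#' @param samples weighted sample set ([species_samples()]).
#' @param fraction biomass fraction to capture (default 0.80, the
#'   conventional "dominant aggregations" threshold).
#' @param strict use strict exceedance (see above).
#' @return list of class `abundance_cutoff`: `cutoff` (t/nmi^2), `k` (rank
#'   of the last sample included), `captured_fraction`, `comparison`.
#' @export
abundance_cutoff <- function(samples, fraction = 0.80, strict = FALSE) {
  w <- samples$z * samples$s
  Q <- sum(w)
  if (Q <= 0) stop("abundance cut-off undefined: total abundance is zero")
  ord <- order(-samples$z)
  cum <- cumsum(w[ord])
  k <- which(cum >= fraction * Q)[1]
  ck <- samples$z[ord[k]]
  if (strict) {
    cutoff <- ck * (1 - 1e-12) - 1e-300
    captured <- sum(w[samples$z > cutoff]) / Q
    comparison <- "gt"
  } else {
    cutoff <- ck
    captured <- sum(w[samples$z >= cutoff]) / Q
    comparison <- "ge"
  }
  structure(list(cutoff = cutoff, k = k, captured_fraction = captured,
                 comparison = comparison, fraction = fraction),
            class = "abundance_cutoff")
}

#' @export
print.abundance_cutoff <- function(x, ...) {
  cat(sprintf("<abundance_cutoff> c%.0f = %g t/nmi^2 (rank %d, captures %.1f%% of biomass, %s)\n",
              100 * x$fraction, x$cutoff, x$k, 100 * x$captured_fraction,
              x$comparison))
  invisible(x)
}

#' Indicator transform of a density field
#'
#' Binary field `I(x) = 1{z(x) >= cutoff}` (or strict `>` when the cut-off
#' came from `abundance_cutoff(strict = TRUE)`), isolating the high-density
#' EDSUs that carry the dominant part of the abundance.
#'
#' @param samples weighted sample set.
#' @param cutoff density threshold (t/nmi^2) or an `abundance_cutoff`.
#' @return list: `indicator` (0/1 vector), `proportion` of ones.
#' @export
indicator_transform <- function(samples, cutoff) {
  comparison <- "ge"
  if (inherits(cutoff, "abundance_cutoff")) {
    comparison <- cutoff$comparison
    cutoff <- cutoff$cutoff
  }
  ind <- if (comparison == "gt") as.numeric(samples$z > cutoff)
         else as.numeric(samples$z >= cutoff)
  list(indicator = ind, proportion = mean(ind))
}

#' Omnidirectional empirical variogram
#'
#' Classical semivariance estimator over distance-binned unordered pairs:
#' `gamma(h) = sum (v_i - v_j)^2 / (2 N(h))` for pairs whose separation
#' falls in the bin centred at `h`. Bins are `lag_width` wide with centres
#' at multiples of `lag_width`; pairs beyond `max_lag` are ignored. Works
#' for the 0/1 indicator field (the primary use) or any numeric values.
#' Pairs are unweighted by area of influence.
#'
#' @param x,y projected coordinates, nmi.
#' @param values numeric field at those positions.
#' @param lag_width bin width, nmi (default 1, the EDSU spacing).
#' @param max_lag largest separation used; default half the maximum
#'   inter-sample distance.
#' @return object of class `empirical_variogram`: data frame `lag_centres`,
#'   `semivariance` (NA where a bin is empty), `pair_counts`, plus
#'   `lag_width` and `max_lag`.
#' @export
empirical_variogram <- function(x, y, values, lag_width = 1, max_lag = NULL) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples")
  stopifnot(length(y) == n, length(values) == n)
  d <- stats::dist(cbind(x, y))
  if (is.null(max_lag)) max_lag <- max(d) / 2
  dv <- stats::dist(matrix(values, ncol = 1))  # |v_i - v_j|
  keep <- d <= max_lag + lag_width / 2
  if (!any(keep)) stop("no sample pairs within max_lag")
  bin <- as.integer(floor(d[keep] / lag_width + 0.5))
  sq <- dv[keep]^2
  nbin <- max(bin)
  counts <- tabulate(bin + 1L, nbins = nbin + 1L)
  sums <- unname(rowsum(sq, bin, reorder = TRUE))[, 1]
  lag_centres <- sort(unique(bin)) * lag_width
  all_centres <- (0:nbin) * lag_width
  gamma <- rep(NA_real_, nbin + 1L)
  gamma[sort(unique(bin)) + 1L] <- sums / (2 * counts[sort(unique(bin)) + 1L])
  out <- list(lag_centres = all_centres, semivariance = gamma,
              pair_counts = counts, lag_width = lag_width, max_lag = max_lag)
  # drop the trailing/leading all-empty bins beyond data support
  used <- counts > 0
  if (any(used)) {
    last <- max(which(used))
    out$lag_centres <- out$lag_centres[seq_len(last)]
    out$semivariance <- out$semivariance[seq_len(last)]
    out$pair_counts <- out$pair_counts[seq_len(last)]
  }
  class(out) <- "empirical_variogram"
  out
}

#' Assemble an empirical variogram from precomputed bins
#'
#' Constructor for an [empirical_variogram()] object from already-binned
#' lags, e.g. model curves or externally computed tables.
#'
#' @param lag_centres strictly increasing lag centres, nmi.
#' @param semivariance semivariance per bin.
#' @param pair_counts pairs per bin.
#' @param lag_width bin width; default the spacing of `lag_centres`.
#' @return an `empirical_variogram`.
#' @export
as_empirical_variogram <- function(lag_centres, semivariance, pair_counts,
                                   lag_width = NULL) {
  stopifnot(length(lag_centres) == length(semivariance),
            length(lag_centres) == length(pair_counts),
            !is.unsorted(lag_centres, strictly = TRUE),
            all(semivariance >= 0, na.rm = TRUE), all(pair_counts >= 0))
  if (is.null(lag_width)) {
    lag_width <- if (length(lag_centres) > 1L) min(diff(lag_centres)) else 1
  }
  structure(list(lag_centres = lag_centres, semivariance = semivariance,
                 pair_counts = as.integer(pair_counts), lag_width = lag_width,
                 max_lag = max(lag_centres)),
            class = "empirical_variogram")
}

#' @export
print.empirical_variogram <- function(x, ...) {
  cat(sprintf("<empirical_variogram> %d lag bins (width %g nmi, max lag %.1f nmi)\n",
              sum(x$pair_counts > 0), x$lag_width, x$max_lag))
  df <- as.data.frame(x)
  print(utils::head(df[df$pair_counts > 0, ], 12L), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.empirical_variogram <- function(x, ...) {
  data.frame(lag = x$lag_centres, semivariance = x$semivariance,
             pair_counts = x$pair_counts)
}

#' @export
plot.empirical_variogram <- function(x, ...) {
  ok <- x$pair_counts > 0
  graphics::plot(x$lag_centres[ok], x$semivariance[ok],
                 xlab = "lag (nmi)", ylab = "semivariance",
                 cex = 0.4 + 1.6 * x$pair_counts[ok] / max(x$pair_counts[ok]),
                 ...)
  invisible(x)
}

#' Spherical variogram model
#'
#' `gamma(h) = c0 + c1 * (1.5 h/a - 0.5 (h/a)^3)` for `h < a`, flat at
#' `c0 + c1` beyond: nugget `c0`, partial sill `c1`, range `a`.
#'
#' @param h lag distance(s), nmi.
#' @param nugget,partial_sill,range model parameters.
#' @return model semivariance at `h`.
#' @export
spherical_semivariance <- function(h, nugget, partial_sill, range) {
  u <- pmin(h / range, 1)
  g <- nugget + partial_sill * (1.5 * u - 0.5 * u^3)
  g[h <= 0] <- 0
  g
}

# Pair-count-weighted least squares of (c0, c1) at fixed range, both
# clamped to be non-negative.
wls_at_range <- function(a, h, g, w) {
  f <- 1.5 * pmin(h / a, 1) - 0.5 * pmin(h / a, 1)^3
  # unconstrained 2x2 weighted normal equations
  s11 <- sum(w); s1f <- sum(w * f); sff <- sum(w * f^2)
  sg1 <- sum(w * g); sgf <- sum(w * g * f)
  det <- s11 * sff - s1f^2
  cand <- list()
  if (det > 1e-14 * s11 * sff) {
    c0 <- (sg1 * sff - sgf * s1f) / det
    c1 <- (s11 * sgf - s1f * sg1) / det
    if (c0 >= 0 && c1 >= 0) cand[[length(cand) + 1L]] <- c(c0, c1)
  }
  cand[[length(cand) + 1L]] <- c(0, max(0, sgf / sff))        # c0 = 0
  cand[[length(cand) + 1L]] <- c(max(0, sg1 / s11), 0)        # c1 = 0
  obj <- vapply(cand, function(p) sum(w * (g - p[1] - p[2] * f)^2), numeric(1))
  best <- which.min(obj)
  list(c0 = cand[[best]][1], c1 = cand[[best]][2], objective = obj[best])
}

#' Fit a nugget + spherical model to an empirical variogram
#'
#' Minimizes the pair-count-weighted sum of squared deviations between the
#' empirical semivariances and the spherical model, by a grid search over
#' the range (step `lag_width / 2`) with non-negative weighted least squares
#' for nugget and partial sill at each candidate range, followed by local
#' refinement of the range by Brent minimization. Deterministic. Candidate
#' ranges are restricted to exceed the second usable lag, so the structured
#' component always spans at least two bins; a shorter range would be pinned
#' by the first bin alone and cannot be told apart from nugget noise. The
#' normalized nugget `nugget_pct = 100 c0 / (c0 + c1)` expresses small-scale
#' roughness as a percentage of the sill; the range (nmi) approximates the
#' mean patch diameter of the thresholded field.
#'
#' @param empirical an [empirical_variogram()] (bins with zero pairs are
#'   excluded; at least 3 usable bins required).
#' @return object of class `variogram_fit`: `nugget`, `partial_sill`,
#'   `range_nmi`, `nugget_pct`, `objective`, `degenerate` (TRUE when no
#'   structured component is identifiable, i.e. the partial sill collapsed
#'   to ~0 and `nugget_pct` is reported as 100).
#' @export
fit_spherical_model <- function(empirical) {
  ok <- empirical$pair_counts > 0 & is.finite(empirical$semivariance)
  h <- empirical$lag_centres[ok]
  g <- empirical$semivariance[ok]
  w <- empirical$pair_counts[ok]
  keep <- h > 0
  h <- h[keep]; g <- g[keep]; w <- w[keep]
  if (length(h) < 3L) stop("need at least 3 non-empty lag bins to fit")
  if (all(g == 0)) stop("degenerate fit: all semivariances are zero (no structure)")
  step <- empirical$lag_width / 2
  amax <- max(h)
  # the structured component must span at least two lag bins: a range at or
  # below the second usable lag is pinned by the first bin alone and is not
  # identifiable from binned data
  amin <- sort(h)[2] + 1e-9
  grid <- seq(step, amax, by = step)
  grid <- unique(c(amin, grid[grid > amin]))
  objs <- vapply(grid, function(a) wls_at_range(a, h, g, w)$objective, numeric(1))
  a0 <- grid[which.min(objs)]
  lo <- max(amin, a0 - step); hi <- min(amax, a0 + step)
  opt <- stats::optimize(function(a) wls_at_range(a, h, g, w)$objective,
                         interval = c(lo, hi), tol = 1e-9)
  a_hat <- if (opt$objective <= min(objs)) opt$minimum else a0
  fit <- wls_at_range(a_hat, h, g, w)
  sill <- fit$c0 + fit$c1
  if (sill <= 0) stop("degenerate fit: zero sill")
  degenerate <- fit$c1 <= 1e-10 * sill
  out <- list(nugget = fit$c0, partial_sill = fit$c1, range_nmi = a_hat,
              nugget_pct = 100 * fit$c0 / sill, objective = fit$objective,
              degenerate = degenerate, empirical = empirical)
  class(out) <- "variogram_fit"
  out
}

#' @export
print.variogram_fit <- function(x, ...) {
  cat(sprintf("<variogram_fit> spherical: range %.2f nmi, nugget %.3g, partial sill %.3g (nugget %.1f%% of sill)%s\n",
              x$range_nmi, x$nugget, x$partial_sill, x$nugget_pct,
              if (x$degenerate) " [degenerate: pure nugget]" else ""))
  invisible(x)
}

#' @export
predict.variogram_fit <- function(object, h, ...) {
  spherical_semivariance(h, object$nugget, object$partial_sill, object$range_nmi)
}

#' @export
plot.variogram_fit <- function(x, ...) {
  plot(x$empirical, ...)
  hh <- seq(0, max(x$empirical$lag_centres), length.out = 200)
  graphics::lines(hh, predict(x, hh), col = "steelblue", lwd = 2)
  invisible(x)
}
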