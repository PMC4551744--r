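# Independent brute-force reference implementations: plain loops, no
# incremental updates, no shared code with the package internals.

oracle_cg <- function(x, y, z, s) {
  num_x <- 0; num_y <- 0; den <- 0
  for (i in seq_along(x)) {
    num_x <- num_x + z[i] * s[i] * x[i]
    num_y <- num_y + z[i] * s[i] * y[i]
    den <- den + z[i] * s[i]
  }
  c(num_x / den, num_y / den)
}

oracle_inertia <- function(x, y, z, s) {
  cg <- oracle_cg(x, y, z, s)
  num <- 0; den <- 0
  for (i in seq_along(x)) {
    num <- num + z[i] * s[i] * ((x[i] - cg[1])^2 + (y[i] - cg[2])^2)
    den <- den + z[i] * s[i]
  }
  num / den
}

oracle_isotropy <- function(x, y, z, s) {
  cg <- oracle_cg(x, y, z, s)
  w <- z * s / sum(z * s)
  cxx <- cxy <- cyy <- 0
  for (i in seq_along(x)) {
    cxx <- cxx + w[i] * (x[i] - cg[1])^2
    cxy <- cxy + w[i] * (x[i] - cg[1]) * (y[i] - cg[2])
    cyy <- cyy + w[i] * (y[i] - cg[2])^2
  }
  if (cxx + cyy <= 1e-12 * (1 + cg[1]^2 + cg[2]^2)) return(1)  # point population
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2, 2))$values
  ev <- pmax(ev, 0)
  ev[ev < 1e-12 * max(ev)] <- 0  # same noise clamp as the implementation
  sqrt(min(ev) / max(ev))
}

oracle_pa <- function(z, s) {
  total <- 0
  for (i in seq_along(z)) if (z[i] > 0) total <- total + s[i]
  total
}

# Spreading area via trapezoidal integration of the area-cumulated
# abundance curve Q(T) (piecewise linear, so the trapezoid rule is exact).
oracle_sa <- function(z, s) {
  ord <- order(z, decreasing = TRUE)
  z <- z[ord]; s <- s[ord]
  Q <- sum(z * s)
  Tk <- c(0, cumsum(s))
  Qk <- c(0, cumsum(z * s))
  integral <- 0
  for (i in seq_along(z)) {
    integral <- integral + (Tk[i + 1] - Tk[i]) *
      ((Q - Qk[i]) + (Q - Qk[i + 1])) / 2
  }
  2 * integral / Q
}

oracle_ea <- function(z, s) {
  num <- 0; den <- 0
  for (i in seq_along(z)) {
    num <- num + z[i] * s[i]
    den <- den + z[i]^2 * s[i]
  }
  num^2 / den
}

oracle_gic <- function(p1, p2) {
  cg1 <- oracle_cg(p1$x, p1$y, p1$z, p1$s)
  cg2 <- oracle_cg(p2$x, p2$y, p2$z, p2$s)
  i1 <- oracle_inertia(p1$x, p1$y, p1$z, p1$s)
  i2 <- oracle_inertia(p2$x, p2$y, p2$z, p2$s)
  d2 <- sum((cg1 - cg2)^2)
  if (d2 + i1 + i2 <= 0) return(1)
  1 - d2 / (d2 + i1 + i2)
}

oracle_c80 <- function(z, s, fraction = 0.8) {
  ord <- order(z, decreasing = TRUE)
  Q <- sum(z * s)
  acc <- 0
  for (k in seq_along(ord)) {
    acc <- acc + z[ord[k]] * s[ord[k]]
    if (acc >= fraction * Q) return(z[ord[k]])
  }
  stop("unreachable")
}

# Sequential patch assignment, written as a direct transcription of the
# rule: decreasing density, join nearest current centre within dlim
# (lowest index on ties), centres abundance-weighted.
oracle_patch_assignment <- function(x, y, z, s, dlim) {
  assignment <- rep(NA_integer_, length(x))
  centres <- list()
  weights <- c()
  ord <- order(z, decreasing = TRUE)
  ord <- ord[z[ord] > 0]
  for (i in ord) {
    w <- z[i] * s[i]
    best <- NA_integer_; best_d <- Inf
    for (j in seq_along(centres)) {
      d <- sqrt((centres[[j]][1] - x[i])^2 + (centres[[j]][2] - y[i])^2)
      if (d < best_d - 1e-15) { best <- j; best_d <- d }
    }
    if (!is.na(best) && best_d <= dlim) {
      tot <- weights[best] + w
      centres[[best]] <- (centres[[best]] * weights[best] + c(x[i], y[i]) * w) / tot
      weights[best] <- tot
      assignment[i] <- best
    } else {
      centres[[length(centres) + 1]] <- c(x[i], y[i])
      weights <- c(weights, w)
      assignment[i] <- length(centres)
    }
  }
  assignment
}

oracle_variogram <- function(x, y, v, lag_width, max_lag) {
  sums <- list(); counts <- list()
  n <- length(x)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    h <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
    if (h > max_lag + lag_width / 2) next
    b <- as.character(floor(h / lag_width + 0.5))
    sums[[b]] <- (if (is.null(sums[[b]])) 0 else sums[[b]]) + (v[i] - v[j])^2
    counts[[b]] <- (if (is.null(counts[[b]])) 0 else counts[[b]]) + 1
  }
  bins <- sort(as.integer(names(sums)))
  data.frame(lag = bins * lag_width,
             semivariance = vapply(as.character(bins),
                                   function(b) sums[[b]] / (2 * counts[[b]]),
                                   numeric(1)),
             pair_counts = vapply(as.character(bins),
                                  function(b) counts[[b]], numeric(1)))
}
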