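#' Column roles in the indicator panel
#'
#' Active variables enter the PCA; supplementary variables (standardized
#' biomass and packing density) are only projected onto the axes via
#' correlations with the scores. Centre-of-gravity coordinates enter in
#' degrees and, like the major-patch count, are never mean-standardized.
#' @name panel_columns
#' @keywords internal
NULL

panel_active_columns <- function() {
  c("inertia", "isotropy", "n_major_patches", "positive_area",
    "spreading_area", "equivalent_area", "gic", "range_nmi", "nugget_pct",
    "cg_lon", "cg_lat")
}

panel_unstandardized_columns <- function() {
  c("n_major_patches", "cg_lon", "cg_lat", "cg_x", "cg_y")
}

panel_supplementary_columns <- function() c("biomass", "packing_density")

#' Standardize an indicator panel by species-and-area means
#'
#' Divides each indicator value by the mean of its (species, sub-area)
#' group, so that each group's standardized column has mean 1 and panels
#' pooled across species or areas become comparable. The major-patch count
#' and the centre-of-gravity coordinates pass through unchanged. Biomass
#' and packing density (the supplementary variables) are standardized the
#' same way.
#'
#' @param panel data frame from [compute_indicator_panel()] with columns
#'   `species`, `sub_area`, `year` and the indicator columns.
#' @param columns columns to standardize; defaults to every active and
#'   supplementary column except the pass-through ones.
#' @return the panel with standardized values; attribute `group_means`
#'   records the means used.
#' @export
standardize_panel <- function(panel, columns = NULL) {
  if (is.null(columns)) {
    columns <- setdiff(intersect(c(panel_active_columns(),
                                   panel_supplementary_columns()),
                                 names(panel)),
                       panel_unstandardized_columns())
  }
  grp <- interaction(panel$species, panel$sub_area, drop = TRUE)
  if (any(table(grp) < 2L)) {
    warning("singleton (species, sub_area) group(s): standardization by a ",
            "single value forces those entries to 1")
  }
  means <- list()
  for (col in columns) {
    m <- tapply(panel[[col]], grp, mean)
    if (any(!is.finite(m)) || any(m == 0)) {
      stop("zero or non-finite group mean for column '", col,
           "'; cannot standardize")
    }
    means[[col]] <- m
    panel[[col]] <- as.vector(panel[[col]] / unname(m[as.character(grp)]))
  }
  attr(panel, "group_means") <- means
  panel
}

#' PCA on the correlation matrix with supplementary variables
#'
#' Eigen-decomposes the Pearson correlation matrix of the active columns;
#' scores are the column-scaled data times the eigenvectors, loadings are
#' the correlations between each active variable and each score (equal to
#' `sqrt(eigenvalue) * eigenvector`). Supplementary variables are projected
#' by correlating them with the scores, without influencing the
#' decomposition. Loadings and supplementary correlations are flagged
#' significant by a two-sided correlation t-test at `alpha`. Each component
#' is oriented so its largest-|loading| variable loads positively.
#'
#' @param panel (standardized) indicator panel.
#' @param active,supplementary column names; defaults per [panel_columns].
#' @param alpha significance level for the correlation tests.
#' @return object of class `indicator_pca`: `eigenvalues`, `loadings`,
#'   `scores`, `supplementary_correlations`, `loading_significant`,
#'   `supplementary_significant`, `variance_explained` (percent per axis),
#'   `n`, `active`, `supplementary`.
#' @export
pca_with_supplementary <- function(panel,
                                   active = intersect(panel_active_columns(), names(panel)),
                                   supplementary = intersect(panel_supplementary_columns(), names(panel)),
                                   alpha = 0.05) {
  X <- as.matrix(panel[, active, drop = FALSE])
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 rows for PCA")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant active column(s): ", paste(active[sds == 0], collapse = ", "))
  }
  Z <- scale(X)
  R <- stats::cor(X)
  eg <- eigen(R, symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  V <- eg$vectors
  # loadings before orientation
  Lmat <- V %*% diag(sqrt(lambda), length(lambda))
  flip <- vapply(seq_len(ncol(Lmat)), function(k) {
    j <- which.max(abs(Lmat[, k]))
    if (Lmat[j, k] < 0) -1 else 1
  }, numeric(1))
  V <- sweep(V, 2, flip, `*`)
  Lmat <- sweep(Lmat, 2, flip, `*`)
  scores <- Z %*% V
  comp <- paste0("PC", seq_along(lambda))
  dimnames(Lmat) <- list(active, comp)
  dimnames(scores) <- list(NULL, comp)
  sup <- NULL; sup_sig <- NULL
  if (length(supplementary) > 0L) {
    S <- as.matrix(panel[, supplementary, drop = FALSE])
    sup <- matrix(NA_real_, length(supplementary), length(lambda),
                  dimnames = list(supplementary, comp))
    for (k in seq_along(lambda)) {
      if (lambda[k] > 1e-12) sup[, k] <- stats::cor(S, scores[, k])
    }
    sup_sig <- correlation_significant(sup, n, alpha)
  }
  out <- list(
    eigenvalues = lambda,
    loadings = Lmat,
    scores = scores,
    supplementary_correlations = sup,
    loading_significant = correlation_significant(Lmat, n, alpha),
    supplementary_significant = sup_sig,
    variance_explained = 100 * lambda / sum(lambda),
    n = n, active = active, supplementary = supplementary, alpha = alpha
  )
  class(out) <- "indicator_pca"
  out
}

# Two-sided t-test for a Pearson correlation with n observations.
correlation_significant <- function(r, n, alpha) {
  r2 <- pmin(r^2, 1 - 1e-15)
  tval <- abs(r) * sqrt((n - 2) / (1 - r2))
  p <- 2 * stats::pt(tval, df = n - 2, lower.tail = FALSE)
  p < alpha
}

#' @export
print.indicator_pca <- function(x, digits = 2, ...) {
  cat(sprintf("<indicator_pca> %d rows, %d active variables\n", x$n,
              length(x$active)))
  ve <- x$variance_explained
  cat("variance explained (%):",
      paste(sprintf("PC%d %.1f", seq_len(min(5, length(ve))), ve[seq_len(min(5, length(ve)))]),
            collapse = ", "), "\n")
  k <- seq_len(min(5L, ncol(x$loadings)))
  L <- round(x$loadings[, k, drop = FALSE], digits)
  star <- ifelse(x$loading_significant[, k, drop = FALSE], "*", "")
  print(matrix(paste0(format(L), star), nrow(L), length(k),
               dimnames = dimnames(L)), quote = FALSE)
  if (!is.null(x$supplementary_correlations)) {
    cat("supplementary:\n")
    S <- round(x$supplementary_correlations[, k, drop = FALSE], digits)
    star <- ifelse(x$supplementary_significant[, k, drop = FALSE], "*", "")
    print(matrix(paste0(format(S), star), nrow(S), length(k),
                 dimnames = dimnames(S)), quote = FALSE)
  }
  invisible(x)
}

#' @export
summary.indicator_pca <- function(object, ...) {
  data.frame(component = paste0("PC", seq_along(object$eigenvalues)),
             eigenvalue = object$eigenvalues,
             variance_pct = object$variance_explained,
             cumulative_pct = cumsum(object$variance_explained))
}

#' @export
plot.indicator_pca <- function(x, axes = c(1, 2), ...) {
  L <- x$loadings[, axes, drop = FALSE]
  graphics::plot(NA, xlim = c(-1, 1), ylim = c(-1, 1),
                 xlab = sprintf("PC%d (%.1f%%)", axes[1], x$variance_explained[axes[1]]),
                 ylab = sprintf("PC%d (%.1f%%)", axes[2], x$variance_explained[axes[2]]),
                 asp = 1, ...)
  graphics::symbols(0, 0, circles = 1, inches = FALSE, add = TRUE)
  graphics::arrows(0, 0, L[, 1], L[, 2], length = 0.06)
  graphics::text(L[, 1] * 1.07, L[, 2] * 1.07, rownames(L), cex = 0.7)
  if (!is.null(x$supplementary_correlations)) {
    S <- x$supplementary_correlations[, axes, drop = FALSE]
    graphics::arrows(0, 0, S[, 1], S[, 2], length = 0.06, col = "steelblue")
    graphics::text(S[, 1] * 1.07, S[, 2] * 1.07, rownames(S), cex = 0.7,
                   col = "steelblue")
  }
  invisible(x)
}

#' Number of leading axes to carry into the regression
#'
#' Smallest number of components whose cumulative explained variance
#' reaches `target` (default 85%), capped at `cap` (default 5).
#'
#' @param pca an `indicator_pca`.
#' @param target cumulative variance fraction.
#' @param cap maximum number of axes.
#' @return integer.
#' @export
n_leading_axes <- function(pca, target = 0.85, cap = 5L) {
  cum <- cumsum(pca$variance_explained) / 100
  min(which(cum >= target - 1e-12)[1], cap, length(pca$eigenvalues))
}

#' Forward stepwise regression of a response on PCA scores
#'
#' Forward selection over the candidate axes with an F-test p-to-enter of
#' `alpha` (no removal step: scores are mutually orthogonal, so estimates
#' never change as terms enter, and the selected set equals the axes
#' individually significant at `alpha`).
#'
#' @param response numeric response (standardized biomass).
#' @param scores score matrix (columns = axes); only the first `k` columns
#'   are candidates.
#' @param k number of candidate axes (default: all columns).
#' @param alpha p-to-enter.
#' @return object of class `stepwise_fit`: `selected` (axis names),
#'   `coefficients` (with intercept), `r_squared`, `residuals`, `fitted`,
#'   `entry_pvalues`, `empty` (TRUE when no axis entered).
#' @export
stepwise_regression <- function(response, scores, k = ncol(scores), alpha = 0.05) {
  stopifnot(length(response) == nrow(scores))
  k <- min(k, ncol(scores))
  if (k < 1L) stop("need at least one candidate axis")
  if (length(response) <= k + 1L) {
    warning("few observations relative to candidate axes; F-tests are weak")
  }
  cand <- colnames(scores)[seq_len(k)]
  if (is.null(cand)) cand <- paste0("PC", seq_len(k))
  df <- data.frame(.y = response, scores[, seq_len(k), drop = FALSE])
  names(df) <- c(".y", cand)
  selected <- character(0)
  entry_p <- numeric(0)
  repeat {
    remaining <- setdiff(cand, selected)
    if (length(remaining) == 0L) break
    base_form <- stats::as.formula(
      paste(".y ~", if (length(selected)) paste(selected, collapse = " + ") else "1"))
    fit0 <- stats::lm(base_form, data = df)
    pvals <- vapply(remaining, function(v) {
      fit1 <- stats::update(fit0, stats::as.formula(paste(". ~ . +", v)))
      an <- stats::anova(fit0, fit1)
      an[["Pr(>F)"]][2]
    }, numeric(1))
    if (all(is.na(pvals)) || min(pvals, na.rm = TRUE) >= alpha) break
    best <- remaining[which.min(pvals)]
    selected <- c(selected, best)
    entry_p <- c(entry_p, min(pvals, na.rm = TRUE))
    names(entry_p)[length(entry_p)] <- best
  }
  final_form <- stats::as.formula(
    paste(".y ~", if (length(selected)) paste(selected, collapse = " + ") else "1"))
  fit <- stats::lm(final_form, data = df)
  out <- list(selected = selected,
              coefficients = stats::coef(fit),
              r_squared = summary(fit)$r.squared,
              residuals = stats::residuals(fit),
              fitted = stats::fitted(fit),
              entry_pvalues = entry_p,
              empty = length(selected) == 0L,
              alpha = alpha, lm = fit)
  class(out) <- "stepwise_fit"
  out
}

#' @export
print.stepwise_fit <- function(x, ...) {
  if (x$empty) {
    cat("<stepwise_fit> no axis entered at alpha =", x$alpha,
        "(intercept-only model)\n")
  } else {
    eq <- paste(sprintf("%+.3g*%s", x$coefficients[-1], names(x$coefficients)[-1]),
                collapse = " ")
    cat(sprintf("<stepwise_fit> y = %.3g %s  (R^2 = %.3f)\n",
                x$coefficients[1], eq, x$r_squared))
  }
  invisible(x)
}

#' @export
residuals.stepwise_fit <- function(object, ...) object$residuals

#' Run the four pooled PCA + regression analyses
#'
#' Executes the standard pooling schemes on a two-species, two-area panel:
#' one analysis per species pooling its areas, and one per area pooling the
#' species. Each analysis standardizes the pooled slice by (species, area)
#' group means, runs the correlation-matrix PCA with standardized biomass
#' and packing density as supplementary variables, and regresses
#' standardized biomass on the leading axes by forward stepwise selection.
#' Poolings whose stratum is absent are skipped with a warning.
#'
#' @param panel raw (unstandardized) indicator panel.
#' @param alpha significance level throughout.
#' @param variance_target,max_axes control the candidate axes, see
#'   [n_leading_axes()].
#' @return named list of analyses; each element holds `panel`
#'   (standardized), `pca`, `regression`, `n_axes`.
#' @export
run_pooled_analyses <- function(panel, alpha = 0.05, variance_target = 0.85,
                                max_axes = 5L) {
  species <- unique(panel$species)
  areas <- unique(panel$sub_area)
  poolings <- c(
    stats::setNames(lapply(species, function(s) panel[panel$species == s, ]),
                    paste0("species_", species)),
    stats::setNames(lapply(areas, function(a) panel[panel$sub_area == a, ]),
                    paste0("area_", areas))
  )
  out <- list()
  for (nm in names(poolings)) {
    slice <- poolings[[nm]]
    res <- tryCatch({
      std <- standardize_panel(slice)
      active <- intersect(panel_active_columns(), names(std))
      constant <- active[vapply(std[active], function(v) {
        sv <- stats::sd(v)
        is.na(sv) || sv == 0
      }, logical(1))]
      if (length(constant) > 0L) {
        warning("pooling '", nm, "': constant active column(s) dropped: ",
                paste(constant, collapse = ", "), call. = FALSE)
        active <- setdiff(active, constant)
      }
      pca <- pca_with_supplementary(std, active = active, alpha = alpha)
      k <- n_leading_axes(pca, target = variance_target, cap = max_axes)
      reg <- stepwise_regression(std$biomass, pca$scores, k = k, alpha = alpha)
      list(panel = std, pca = pca, regression = reg, n_axes = k)
    }, error = function(e) {
      warning("pooling '", nm, "' skipped: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(res)) out[[nm]] <- res
  }
  if (length(out) == 0L) stop("no pooled analysis could be run")
  out
}
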