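#' Extract one species' weighted sample set
#'
#' Returns the per-EDSU positions (projected nmi), densities and areas of
#' influence for one species, the common currency of all indicator
#' functions. The dataset is projected first if needed.
#'
#' @param dataset a [survey_dataset()].
#' @param species species label.
#' @return data frame with columns `x`, `y`, `z` (t/nmi^2), `s` (nmi^2),
#'   plus `lon`, `lat` and `transect_id`; attribute `origin` carries the
#'   projection origin.
#' @export
species_samples <- function(dataset, species) {
  col <- paste0("density_", species)
  if (!col %in% names(dataset)) stop("unknown species: ", species)
  if (!all(c("x", "y") %in% names(dataset))) {
    dataset <- project_coordinates(dataset)
  }
  out <- data.frame(x = dataset$x, y = dataset$y,
                    z = dataset[[col]], s = dataset$area_influence,
                    lon = dataset$lon, lat = dataset$lat,
                    transect_id = dataset$transect_id,
                    stringsAsFactors = FALSE)
  attr(out, "origin") <- attr(dataset, "origin")
  out
}

abundance_weights <- function(samples) samples$z * samples$s

#' Centre of gravity of a population
#'
#' Abundance-weighted mean location: each EDSU contributes weight
#' `z * s` (density times area of influence).
#'
#' @param samples sample set from [species_samples()], or any data frame
#'   with `x`, `y`, `z`, `s`.
#' @return list with `x`, `y` (nmi) and, when the projection origin is
#'   known, `lon`, `lat` (degrees).
#' @export
centre_of_gravity <- function(samples) {
  w <- abundance_weights(samples)
  if (sum(w) <= 0) stop("centre of gravity undefined: all densities are zero")
  cg <- list(x = sum(w * samples$x) / sum(w),
             y = sum(w * samples$y) / sum(w))
  or <- attr(samples, "origin")
  if (!is.null(or)) {
    ll <- xy_to_lonlat(cg$x, cg$y, or)
    cg$lon <- ll$lon; cg$lat <- ll$lat
  }
  cg
}

#' Inertia and isotropy of a population
#'
#' Inertia is the abundance-weighted mean squared distance from the centre
#' of gravity (nmi^2), a dispersion measure. The weighted covariance matrix
#' of positions has eigenvalues `lambda1 >= lambda2` summing to the inertia;
#' isotropy is `sqrt(lambda2 / lambda1)`: 1 for a circular cloud, 0 for a
#' collinear one, and 1 by convention when all mass sits at one point.
#'
#' @param samples weighted sample set (see [centre_of_gravity()]).
#' @return list with `inertia`, `isotropy`, eigenvalues `lambda` and
#'   principal `axes` (columns).
#' @export
inertia_and_isotropy <- function(samples) {
  w <- abundance_weights(samples)
  if (sum(w) <= 0) stop("inertia undefined: all densities are zero")
  p <- w / sum(w)
  cx <- sum(p * samples$x); cy <- sum(p * samples$y)
  dx <- samples$x - cx; dy <- samples$y - cy
  cov <- matrix(c(sum(p * dx * dx), sum(p * dx * dy),
                  sum(p * dx * dy), sum(p * dy * dy)), 2, 2)
  eg <- eigen(cov, symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  # clamp a second eigenvalue that is pure floating-point noise: sqrt() in
  # the isotropy would otherwise amplify O(1e-17) residue to O(1e-9)
  if (lambda[2] < 1e-12 * lambda[1]) lambda[2] <- 0
  inertia <- lambda[1] + lambda[2]
  # a point population has zero inertia up to floating-point noise in the
  # weighted mean; relative guard against the coordinate scale
  tol <- 1e-12 * (1 + cx^2 + cy^2)
  iso <- if (inertia <= tol) 1 else sqrt(lambda[2] / lambda[1])
  list(inertia = inertia, isotropy = iso, lambda = lambda, axes = eg$vectors)
}

#' Positive area (area of presence)
#'
#' Total area of influence of EDSUs with strictly positive density.
#'
#' @param samples weighted sample set.
#' @return area in nmi^2.
#' @export
positive_area <- function(samples) {
  sum(samples$s[samples$z > 0])
}

#' Spreading area
#'
#' Aggregation index derived from the area-cumulated abundance curve: rank
#' EDSUs by decreasing density and accumulate abundance `Q(T)` against
#' cumulated area `T`; then `SA = 2 * integral(Q - Q(T)) dT / Q`, here in
#' closed discrete form. Equals the positive area for a uniform field and
#' shrinks as the population concentrates.
#'
#' @param samples weighted sample set.
#' @return area in nmi^2.
#' @export
spreading_area <- function(samples) {
  Q <- sum(abundance_weights(samples))
  if (Q <= 0) stop("spreading area undefined: total abundance is zero")
  ord <- order(-samples$z)
  z <- samples$z[ord]; s <- samples$s[ord]
  qi <- cumsum(z * s)
  sum(s * (Q - qi + z * s / 2)) * 2 / Q
}

#' Equivalent area
#'
#' `EA = (sum z s)^2 / sum(z^2 s)`: the area the population would occupy at
#' its abundance-weighted mean density. At most the positive area
#' (Cauchy-Schwarz), with equality for a uniform field.
#'
#' @param samples weighted sample set.
#' @return area in nmi^2.
#' @export
equivalent_area <- function(samples) {
  Q <- sum(abundance_weights(samples))
  if (Q <= 0) stop("equivalent area undefined: total abundance is zero")
  Q^2 / sum(samples$z^2 * samples$s)
}

#' Identify abundance patches by sequential assignment
#'
#' Positive-density EDSUs are processed in decreasing density order (ties by
#' row order). The first sample founds patch 1 at its location; each
#' subsequent sample joins the nearest patch whose *current*
#' abundance-weighted centre lies within `dlim`, updating that centre
#' incrementally, or founds a new patch otherwise. Ties between equidistant
#' centres go to the lowest patch index. Major patches are those holding
#' strictly more than `min_fraction` of total abundance.
#'
#' @param samples weighted sample set.
#' @param dlim threshold distance from sample to patch centre, nmi.
#' @param min_fraction abundance fraction above which a patch is "major".
#' @return object of class `patch_set`: data frame `patches` (centre_x,
#'   centre_y, abundance, n_members, major), `members` (list of row index
#'   vectors into `samples`), `assignment` (patch index per sample, NA for
#'   zero density), `n_major_patches`, `dlim`, `min_fraction`.
#' @export
identify_patches <- function(samples, dlim = 20, min_fraction = 0.10) {
  pos <- which(samples$z > 0)
  assignment <- rep(NA_integer_, nrow(samples))
  if (length(pos) == 0L) {
    out <- list(patches = data.frame(centre_x = numeric(0), centre_y = numeric(0),
                                     abundance = numeric(0), n_members = integer(0),
                                     major = logical(0)),
                members = list(), assignment = assignment,
                n_major_patches = 0L, dlim = dlim, min_fraction = min_fraction)
    class(out) <- "patch_set"
    return(out)
  }
  ord <- pos[order(-samples$z[pos])]
  cx <- numeric(0); cy <- numeric(0); ab <- numeric(0)
  members <- list()
  for (i in ord) {
    wi <- samples$z[i] * samples$s[i]
    if (length(cx) > 0L) {
      d <- sqrt((cx - samples$x[i])^2 + (cy - samples$y[i])^2)
      j <- which.min(d)  # lowest index wins ties
    } else {
      d <- numeric(0); j <- NA_integer_
    }
    if (length(d) > 0L && d[j] <= dlim) {
      tot <- ab[j] + wi
      if (tot > 0) {
        cx[j] <- (cx[j] * ab[j] + samples$x[i] * wi) / tot
        cy[j] <- (cy[j] * ab[j] + samples$y[i] * wi) / tot
      }
      ab[j] <- tot
      members[[j]] <- c(members[[j]], i)
      assignment[i] <- j
    } else {
      cx <- c(cx, samples$x[i]); cy <- c(cy, samples$y[i]); ab <- c(ab, wi)
      members[[length(cx)]] <- i
      assignment[i] <- length(cx)
    }
  }
  Q <- sum(ab)
  major <- ab > min_fraction * Q
  out <- list(patches = data.frame(centre_x = cx, centre_y = cy, abundance = ab,
                                   n_members = lengths(members), major = major),
              members = members, assignment = assignment,
              n_major_patches = sum(major), dlim = dlim,
              min_fraction = min_fraction)
  class(out) <- "patch_set"
  out
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches (%d major at >%g%% of abundance), dlim = %g nmi\n",
              nrow(x$patches), x$n_major_patches, 100 * x$min_fraction, x$dlim))
  print(x$patches, ...)
  invisible(x)
}

#' Global index of collocation between two populations
#'
#' `GIC = 1 - dCG^2 / (dCG^2 + I1 + I2)` where `dCG` is the distance between
#' the centres of gravity and `I1`, `I2` the inertias: 0 when each
#' population sits at a single but different point, 1 when the centres of
#' gravity coincide (including the degenerate two-coincident-points case).
#' Both populations must share a projection.
#'
#' @param pop1,pop2 weighted sample sets in a common projection.
#' @return GIC in `[0, 1]`.
#' @export
global_index_of_collocation <- function(pop1, pop2) {
  o1 <- attr(pop1, "origin"); o2 <- attr(pop2, "origin")
  if (!is.null(o1) && !is.null(o2) && !isTRUE(all.equal(o1, o2))) {
    stop("populations must share one projection origin")
  }
  cg1 <- centre_of_gravity(pop1); cg2 <- centre_of_gravity(pop2)
  i1 <- inertia_and_isotropy(pop1)$inertia
  i2 <- inertia_and_isotropy(pop2)$inertia
  d2 <- (cg1$x - cg2$x)^2 + (cg1$y - cg2$y)^2
  if (d2 + i1 + i2 <= 0) return(1)
  1 - d2 / (d2 + i1 + i2)
}

#' Total biomass from EDSU or transect areas of influence
#'
#' `edsu`: each EDSU's density times its area of influence, summed.
#' `transect`: mean density within each transect times the transect's area
#' of influence (default: the sum of its member EDSU areas), summed. The
#' two agree exactly when EDSU areas are equal within transects.
#'
#' @param dataset a [survey_dataset()].
#' @param species species label.
#' @param method `"edsu"` or `"transect"`.
#' @param transect_area optional named vector of per-transect areas of
#'   influence (nmi^2) overriding the default.
#' @return biomass in t.
#' @export
estimate_biomass <- function(dataset, species, method = c("edsu", "transect"),
                             transect_area = NULL) {
  method <- match.arg(method)
  col <- paste0("density_", species)
  if (!col %in% names(dataset)) stop("unknown species: ", species)
  z <- dataset[[col]]
  if (method == "edsu") {
    return(sum(z * dataset$area_influence))
  }
  tid <- dataset$transect_id
  if (is.null(tid) || all(is.na(tid))) {
    stop("transect method requires transect ids")
  }
  mean_z <- tapply(z, tid, mean)
  area_t <- if (is.null(transect_area)) {
    tapply(dataset$area_influence, tid, sum)
  } else {
    transect_area[names(mean_z)]
  }
  sum(mean_z * area_t)
}

#' Mean packing density
#'
#' Total biomass divided by positive area (t/nmi^2): the mean density over
#' the area of presence.
#'
#' @param biomass total biomass, t.
#' @param positive_area area of presence, nmi^2.
#' @return packing density, t/nmi^2.
#' @export
packing_density <- function(biomass, positive_area) {
  if (positive_area <= 0) stop("packing density undefined: positive area is zero")
  biomass / positive_area
}

#' Compute the full indicator set for one population slice
#'
#' Assembles, for one (species, sub-area, year) slice, the centre of gravity
#' (degrees and nmi), inertia, isotropy, major-patch count, positive /
#' spreading / equivalent areas, biomass, packing density, the collocation
#' index with a second species when given, and (optionally) the indicator
#' variography descriptors: the abundance cut-off capturing `cutoff_fraction`
#' of biomass, and the fitted spherical range (nmi) and normalized nugget
#' (percent of sill) of the omnidirectional indicator variogram.
#'
#' @param dataset a [survey_dataset()], already filtered to one sub-area and
#'   year (the labels are read off the data).
#' @param species species label.
#' @param other_species optional second species for the collocation index.
#' @param dlim,min_fraction patch parameters, see [identify_patches()].
#' @param variography compute variography descriptors? (needs >= 3 usable
#'   lag bins).
#' @param cutoff_fraction biomass fraction defining the cut-off (default 0.8).
#' @param lag_width,max_lag variogram binning, see [empirical_variogram()].
#' @param biomass_method passed to [estimate_biomass()].
#' @return one-row data frame of class `indicator_set`.
#' @export
compute_indicator_set <- function(dataset, species, other_species = NULL,
                                  dlim = 20, min_fraction = 0.10,
                                  variography = TRUE, cutoff_fraction = 0.80,
                                  lag_width = 1, max_lag = NULL,
                                  biomass_method = "edsu") {
  if (nrow(dataset) == 0L) stop("empty dataset slice")
  # (re)project whenever the origin is unknown so CG can be reported in
  # degrees and x/y stay consistent with it
  if (!all(c("x", "y") %in% names(dataset)) || is.null(attr(dataset, "origin"))) {
    dataset <- project_coordinates(dataset)
  }
  smp <- species_samples(dataset, species)
  if (!any(smp$z > 0)) stop("no positive densities for species ", species)
  cg <- centre_of_gravity(smp)
  ii <- inertia_and_isotropy(smp)
  ps <- identify_patches(smp, dlim = dlim, min_fraction = min_fraction)
  pa <- positive_area(smp)
  q <- estimate_biomass(dataset, species, method = biomass_method)
  gic <- NA_real_
  if (!is.null(other_species)) {
    gic <- global_index_of_collocation(smp, species_samples(dataset, other_species))
  }
  range_nmi <- nugget_pct <- c_cut <- NA_real_
  if (variography) {
    cut <- abundance_cutoff(smp, fraction = cutoff_fraction)
    ind <- indicator_transform(smp, cut$cutoff)
    ev <- empirical_variogram(smp$x, smp$y, ind$indicator,
                              lag_width = lag_width, max_lag = max_lag)
    fit <- fit_spherical_model(ev)
    range_nmi <- fit$range_nmi
    nugget_pct <- fit$nugget_pct
    c_cut <- cut$cutoff
  }
  out <- data.frame(
    species = species,
    sub_area = as.character(dataset$sub_area[1]),
    year = dataset$survey_year[1],
    cg_lon = if (is.null(cg$lon)) NA_real_ else cg$lon,
    cg_lat = if (is.null(cg$lat)) NA_real_ else cg$lat,
    cg_x = cg$x, cg_y = cg$y,
    inertia = ii$inertia, isotropy = ii$isotropy,
    n_major_patches = ps$n_major_patches,
    positive_area = pa,
    spreading_area = spreading_area(smp),
    equivalent_area = equivalent_area(smp),
    gic = gic,
    cutoff = c_cut, range_nmi = range_nmi, nugget_pct = nugget_pct,
    biomass = q,
    packing_density = packing_density(q, pa),
    stringsAsFactors = FALSE
  )
  class(out) <- c("indicator_set", "data.frame")
  out
}

#' Indicator panel over a list of survey datasets
#'
#' Applies [compute_indicator_set()] to every species of every dataset
#' (typically one dataset per sub-area and year) and stacks the rows. With
#' exactly two species per dataset, each species' collocation index is
#' computed against the other. Slices that fail (e.g. a species absent in a
#' year) are skipped with a warning.
#'
#' @param datasets list of [survey_dataset()] objects.
#' @param ... passed to [compute_indicator_set()].
#' @return data frame with one row per (species, sub-area, year).
#' @export
compute_indicator_panel <- function(datasets, ...) {
  rows <- list()
  for (d in datasets) {
    sp <- species_of(d)
    for (k in seq_along(sp)) {
      other <- if (length(sp) == 2L) sp[-k] else NULL
      row <- tryCatch(
        compute_indicator_set(d, sp[k], other_species = other, ...),
        error = function(e) {
          warning(sprintf("slice (%s, %s, %s) skipped: %s", sp[k],
                          d$sub_area[1], d$survey_year[1], conditionMessage(e)),
                  call. = FALSE)
          NULL
        })
      if (!is.null(row)) rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0L) stop("no indicator rows could be computed")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
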