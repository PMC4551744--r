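#' Configuration for a synthetic acoustic survey
#'
#' Defines one simulated survey: a rectangular region sampled along
#' north-south parallel transects, carrying for each species a zero-inflated
#' lognormal density field with spherical spatial autocorrelation. The field
#' for a species is `z = exp(m + sigma * G1) * 1{G2 > Phi^-1(1 - p_occ)}`
#' where `G1` (intensity) and `G2` (occupancy) are standard Gaussian random
#' fields with correlation `(1 - eta) * sph(h; a) + eta * 1{h = 0}`. Species
#' fields may share a latent component (`latent_correlation`), be offset in
#' space (`cg_shift`) and be stretched east-west (`anisotropy_ratio`).
#' Densities are rescaled so the EDSU-integrated biomass equals
#' `total_biomass` exactly.
#'
#' Defaults emulate a Mediterranean summer survey design: 1-nmi EDSUs on
#' 5-nmi-spaced transects, two small-pelagic species with biomass of order
#' 10^4 t, patch (autocorrelation) range 10 nmi and partial occupation of
#' the surveyed rectangle.
#'
#' @param extent `c(width, height)` of the region in nmi.
#' @param transect_spacing inter-transect distance, nmi (survey designs in
#'   the field use 5 or 10).
#' @param edsu_spacing along-transect sample spacing, nmi (the EDSU length).
#' @param variogram_range spherical autocorrelation range `a`, nmi.
#' @param nugget_fraction nugget proportion `eta` of the latent field, in `[0, 1)`.
#' @param log_mean,log_sd mean and sd of log intensity (dimensionless).
#' @param occupied_fraction expected fraction of EDSUs with positive density,
#'   in `(0, 1]`.
#' @param total_biomass named numeric, target biomass (t) per species.
#' @param cg_shift named list of `c(dx, dy)` nmi: displacement applied to the
#'   centre of gravity of each species' field.
#' @param latent_correlation correlation in `[-1, 1]` between the two species'
#'   latent fields.
#' @param anisotropy_ratio in `(0, 1]`: x-lags are scaled by its inverse, so
#'   values < 1 shorten the effective range east-west.
#' @param origin geographic origin `c(lon0, lat0)` used to assign lon/lat.
#' @param seed integer seed; one seed drives all randomness of the draw.
#' @param survey_year,sub_area labels stamped on the generated records.
#' @return a `sim_config` list.
#' @export
sim_config <- function(extent = c(60, 40),
                       transect_spacing = 5,
                       edsu_spacing = 1,
                       variogram_range = 10,
                       nugget_fraction = 0,
                       log_mean = 0,
                       log_sd = 1,
                       occupied_fraction = 0.6,
                       total_biomass = c(anchovy = 15000, sardine = 10000),
                       cg_shift = NULL,
                       latent_correlation = 0,
                       anisotropy_ratio = 1,
                       origin = c(13.0, 37.3),
                       seed = 1L,
                       survey_year = 2002L,
                       sub_area = "S1") {
  cfg <- list(extent = extent, transect_spacing = transect_spacing,
              edsu_spacing = edsu_spacing, variogram_range = variogram_range,
              nugget_fraction = nugget_fraction, log_mean = log_mean,
              log_sd = log_sd, occupied_fraction = occupied_fraction,
              total_biomass = total_biomass, cg_shift = cg_shift,
              latent_correlation = latent_correlation,
              anisotropy_ratio = anisotropy_ratio, origin = origin,
              seed = as.integer(seed), survey_year = survey_year,
              sub_area = sub_area)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$extent) == 2L, all(cfg$extent > 0))
  if (cfg$variogram_range <= 0) stop("variogram_range must be > 0")
  if (cfg$nugget_fraction < 0 || cfg$nugget_fraction >= 1) {
    stop("nugget_fraction must be in [0, 1)")
  }
  if (cfg$occupied_fraction <= 0 || cfg$occupied_fraction > 1) {
    stop("occupied_fraction must be in (0, 1]")
  }
  if (any(cfg$total_biomass <= 0)) stop("total_biomass must be > 0")
  if (is.null(names(cfg$total_biomass)) || any(names(cfg$total_biomass) == "")) {
    stop("total_biomass must be named by species")
  }
  if (cfg$transect_spacing < cfg$edsu_spacing) {
    stop("transect_spacing must be >= edsu_spacing")
  }
  if (abs(cfg$latent_correlation) > 1) stop("latent_correlation must be in [-1, 1]")
  if (cfg$anisotropy_ratio <= 0 || cfg$anisotropy_ratio > 1) {
    stop("anisotropy_ratio must be in (0, 1]")
  }
  invisible(TRUE)
}

#' Parallel-transect EDSU layout
#'
#' Places north-south transects `transect_spacing` nmi apart across the
#' width of the region, with EDSU centres every `edsu_spacing` nmi along
#' each transect (grid nodes, both ends included). Every EDSU - interior
#' and edge alike - receives `area_influence = transect_spacing *
#' edsu_spacing` nmi^2.
#'
#' @param config a [sim_config()].
#' @return data frame with `x`, `y` (nmi), `transect_id`, `area_influence`.
#' @export
build_transect_layout <- function(config) {
  w <- config$extent[1]; h <- config$extent[2]
  if (w < config$transect_spacing) {
    stop("extent width smaller than one transect spacing")
  }
  tx <- seq(0, w, by = config$transect_spacing)
  ty <- seq(0, h, by = config$edsu_spacing)
  layout <- data.frame(
    x = rep(tx, each = length(ty)),
    y = rep(ty, times = length(tx)),
    transect_id = rep(sprintf("T%02d", seq_along(tx)), each = length(ty)),
    area_influence = config$transect_spacing * config$edsu_spacing,
    stringsAsFactors = FALSE
  )
  layout
}

# Spherical correlation function, 1 at h = 0, 0 beyond the range.
spherical_correlation <- function(h, range) {
  u <- pmin(h / range, 1)
  ifelse(h < range, 1 - 1.5 * u + 0.5 * u^3, 0)
}

# Cholesky factor of the latent-field correlation on the layout positions.
# Nugget enters off-diagonal only (diagonal stays 1).
latent_chol <- function(layout, config) {
  n <- nrow(layout)
  if (n > 4000L) {
    stop("dense covariance factorization supports at most ~4000 EDSUs; ",
         "coarsen the layout")
  }
  dx <- outer(layout$x, layout$x, "-") / config$anisotropy_ratio
  dy <- outer(layout$y, layout$y, "-")
  hmat <- sqrt(dx^2 + dy^2)
  C <- (1 - config$nugget_fraction) * spherical_correlation(hmat, config$variogram_range)
  diag(C) <- 1
  L <- tryCatch(chol(C + diag(1e-10, n)),
                error = function(e) NULL)
  if (is.null(L)) {
    stop("latent correlation matrix is not positive definite for this ",
         "(nugget_fraction, variogram_range) combination")
  }
  L
}

#' Simulate a zero-inflated lognormal density field on a survey layout
#'
#' Draws, for each species, correlated Gaussian intensity and occupancy
#' fields on the EDSU positions, thresholds occupancy at the quantile giving
#' the requested occupied fraction, exponentiates the intensity, shifts the
#' centre of gravity by tilting the log-intensity along the requested
#' direction (coefficient solved so the realized displacement matches), and
#' rescales densities so the area-weighted total equals the target biomass
#' exactly. Deterministic given `config$seed`.
#'
#' @param layout EDSU layout from [build_transect_layout()]; one is built
#'   from `config` when omitted.
#' @param config a [sim_config()].
#' @return a [survey_dataset()] with attribute `sim_truth`: the config, the
#'   seed, and per species the realized biomass, occupied fraction and
#'   centre of gravity (projected nmi).
#' @export
simulate_density_field <- function(config, layout = NULL) {
  if (is.null(layout)) layout <- build_transect_layout(config)
  species <- names(config$total_biomass)
  n <- nrow(layout)
  L <- latent_chol(layout, config)
  set.seed(config$seed)
  # shared latent components across species, then independent remainders;
  # fixed draw order makes per-species streams reproducible
  rho <- config$latent_correlation
  a_sh <- sqrt(abs(rho))
  draw_field <- function() drop(crossprod(L, stats::rnorm(n)))
  common1 <- draw_field(); common2 <- draw_field()
  dens <- matrix(0, n, length(species), dimnames = list(NULL, species))
  truth_sp <- list()
  for (k in seq_along(species)) {
    sgn <- if (k == 1L || rho >= 0) 1 else -1
    e1 <- draw_field(); e2 <- draw_field()
    g1 <- sgn * a_sh * common1 + sqrt(1 - abs(rho)) * e1
    g2 <- sgn * a_sh * common2 + sqrt(1 - abs(rho)) * e2
    occ <- g2 > stats::qnorm(1 - config$occupied_fraction)
    if (!any(occ)) occ[which.max(g2)] <- TRUE  # guarantee a non-empty support
    z <- exp(config$log_mean + config$log_sd * g1) * occ
    shift <- cg_shift_for(config, species[k])
    if (!is.null(shift) && any(shift != 0)) {
      z <- apply_cg_shift(z, layout, shift)
    }
    s <- layout$area_influence
    z <- z * config$total_biomass[[species[k]]] / sum(z * s)
    dens[, k] <- z
    truth_sp[[species[k]]] <- list(
      biomass = sum(z * s),
      occupied_fraction = mean(z > 0),
      cg = c(x = sum(z * s * layout$x) / sum(z * s),
             y = sum(z * s * layout$y) / sum(z * s))
    )
  }
  ll <- xy_to_lonlat(layout$x, layout$y, config$origin)
  df <- data.frame(
    survey_year = config$survey_year,
    sub_area = config$sub_area,
    transect_id = layout$transect_id,
    lon = ll$lon, lat = ll$lat,
    area_influence = layout$area_influence,
    stringsAsFactors = FALSE
  )
  for (sp in species) df[[paste0("density_", sp)]] <- dens[, sp]
  df$x <- layout$x; df$y <- layout$y
  out <- survey_dataset(df, species = species, origin = config$origin)
  attr(out, "sim_truth") <- list(config = config, seed = config$seed,
                                 species = truth_sp)
  out
}

cg_shift_for <- function(config, species) {
  if (is.null(config$cg_shift)) return(NULL)
  if (!is.null(names(config$cg_shift))) return(config$cg_shift[[species]])
  config$cg_shift
}

# Tilt positive densities by an exponential linear trend exp(b . p) whose
# coefficient vector b is solved (Newton on the realized field; the Jacobian
# is the tilted covariance of positions, positive definite) so the weighted
# CG moves by exactly `shift`.
apply_cg_shift <- function(z, layout, shift) {
  s <- layout$area_influence
  px <- layout$x - mean(layout$x); py <- layout$y - mean(layout$y)
  w0 <- z * s
  cg0 <- c(sum(w0 * px), sum(w0 * py)) / sum(w0)
  target <- cg0 + shift
  pos <- z > 0
  if (target[1] <= min(px[pos]) || target[1] >= max(px[pos]) ||
      target[2] <= min(py[pos]) || target[2] >= max(py[pos])) {
    stop("requested cg_shift pushes the centre of gravity outside the ",
         "positive support of the layout")
  }
  b <- c(0, 0)
  for (iter in 1:200) {
    e <- b[1] * px + b[2] * py
    w <- w0 * exp(e - max(e[pos]))
    sw <- sum(w)
    cg <- c(sum(w * px), sum(w * py)) / sw
    resid <- target - cg
    if (max(abs(resid)) < 1e-12) break
    cxx <- sum(w * px * px) / sw - cg[1]^2
    cxy <- sum(w * px * py) / sw - cg[1] * cg[2]
    cyy <- sum(w * py * py) / sw - cg[2]^2
    J <- matrix(c(cxx, cxy, cxy, cyy), 2, 2)
    step <- tryCatch(solve(J, resid), error = function(e2) NULL)
    if (is.null(step)) break
    # damp long steps: the tilt is exponential in b
    if (sqrt(sum(step^2)) > 1) step <- step / sqrt(sum(step^2))
    b <- b + step
  }
  if (max(abs(resid)) > 1e-6) {
    warning("cg_shift solve did not fully converge; realized shift off by ",
            signif(max(abs(resid)), 3), " nmi")
  }
  z * exp(b[1] * px + b[2] * py)
}

#' Ground truth of a simulated dataset
#' @param dataset a dataset produced by [simulate_density_field()].
#' @return the `sim_truth` attribute.
#' @export
sim_truth <- function(dataset) attr(dataset, "sim_truth")

#' Simulate a multi-year survey panel
#'
#' Runs [simulate_density_field()] for each configuration in `configs`
#' (typically one per survey year, sharing one layout and differing in
#' biomass, occupation and seed) and returns the datasets with their ground
#' truths. Used to emulate biomass-occupation coupling across years: feed
#' configs whose `total_biomass` and `occupied_fraction` rise together.
#'
#' @param configs list of [sim_config()] objects with identical layout
#'   parameters (extent, spacings, origin).
#' @return list with elements `datasets` (list of `survey_dataset`) and
#'   `truths` (list of `sim_truth` records).
#' @export
simulate_multiyear_panel <- function(configs) {
  if (length(configs) < 1L) stop("need at least one config")
  if (length(configs) == 1L) {
    warning("panel of a single survey: no multivariate analysis is possible downstream")
  }
  layout_key <- function(cfg) {
    paste(c(cfg$extent, cfg$transect_spacing, cfg$edsu_spacing, cfg$origin),
          collapse = "|")
  }
  keys <- vapply(configs, layout_key, character(1))
  if (length(unique(keys)) != 1L) {
    stop("all configs in a panel must share one layout (extent, spacings, origin)")
  }
  layout <- build_transect_layout(configs[[1]])
  datasets <- lapply(configs, simulate_density_field, layout = layout)
  list(datasets = datasets, truths = lapply(datasets, sim_truth))
}

#' Year-on-year coupled configurations
#'
#' Convenience builder for a panel in which total biomass and occupied
#' fraction co-vary across years, the construction used to emulate the
#' biomass-occupation coupling that the multivariate stage is meant to
#' detect.
#'
#' @param base a [sim_config()] supplying all fixed parameters.
#' @param years integer vector of survey years.
#' @param biomass_factors multiplier on `base$total_biomass` per year
#'   (recycled across species).
#' @param occupied_fractions occupied fraction per year.
#' @param seeds integer seed per year.
#' @return list of `sim_config` objects.
#' @export
coupled_year_configs <- function(base, years,
                                 biomass_factors = seq(1, 2, length.out = length(years)),
                                 occupied_fractions = seq(0.3, 0.6, length.out = length(years)),
                                 seeds = base$seed + seq_along(years) - 1L) {
  stopifnot(length(biomass_factors) == length(years),
            length(occupied_fractions) == length(years),
            length(seeds) == length(years))
  lapply(seq_along(years), function(i) {
    cfg <- unclass(base)
    cfg$survey_year <- years[i]
    cfg$total_biomass <- base$total_biomass * biomass_factors[i]
    cfg$occupied_fraction <- occupied_fractions[i]
    cfg$seed <- as.integer(seeds[i])
    class(cfg) <- "sim_config"
    validate_sim_config(cfg)
    cfg
  })
}
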