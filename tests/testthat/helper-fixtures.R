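# Small builders used across test files.

make_samples <- function(x, y, z, s = rep(1, length(x))) {
  data.frame(x = x, y = y, z = z, s = s)
}

rand_samples <- function(n, zero_prob = 0.3, extent = 50) {
  z <- stats::rlnorm(n)
  z[stats::runif(n) < zero_prob] <- 0
  make_samples(x = stats::runif(n, 0, extent), y = stats::runif(n, 0, extent),
               z = z, s = stats::runif(n, 0.5, 5))
}

make_dataset <- function(x, y, dens, s = rep(1, length(x)),
                         origin = c(15, 37), year = 2005L, sub_area = "S1") {
  n <- length(x)
  ll <- spatfish::xy_to_lonlat(x, y, origin)
  df <- data.frame(survey_year = rep(year, n), sub_area = rep(sub_area, n),
                   transect_id = rep("T01", n), lon = ll$lon, lat = ll$lat,
                   area_influence = s, stringsAsFactors = FALSE)
  for (sp in names(dens)) df[[paste0("density_", sp)]] <- dens[[sp]]
  df$x <- x; df$y <- y
  spatfish::survey_dataset(df, origin = origin)
}

# An 8-year, 2-species, 2-area panel with biomass and occupation rising
# together; the construction the multivariate stage is meant to detect.
make_coupled_panel <- function(seed, extent = c(45, 25), years = 8L) {
  areas <- list(S1 = c(12.6, 37.4), G1 = c(22.8, 40.2))
  datasets <- list()
  for (ai in seq_along(areas)) {
    base <- spatfish::sim_config(
      extent = extent, transect_spacing = 5, edsu_spacing = 1,
      variogram_range = 10, nugget_fraction = 0.15, log_sd = 1,
      total_biomass = c(anchovy = 15000, sardine = 10000),
      cg_shift = list(anchovy = c(0, 0), sardine = c(6, 0)),
      origin = areas[[ai]], sub_area = names(areas)[ai], seed = seed)
    cfgs <- spatfish::coupled_year_configs(
      base, years = 2002L + seq_len(years) - 1L,
      biomass_factors = seq(1, 2, length.out = years),
      occupied_fractions = seq(0.3, 0.6, length.out = years),
      seeds = seed + 1000L * ai + seq_len(years))
    datasets <- c(datasets, spatfish::simulate_multiyear_panel(cfgs)$datasets)
  }
  datasets
}
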