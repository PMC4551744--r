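test_that("transect layout counts, spacing and area conservation", {
  cfg <- sim_config(extent = c(10, 5), transect_spacing = 5, edsu_spacing = 1,
                    total_biomass = c(anchovy = 1))
  lay <- build_transect_layout(cfg)
  # 3 transects x 6 EDSUs
  expect_identical(nrow(lay), 18L)
  expect_identical(length(unique(lay$transect_id)), 3L)
  expect_true(all(lay$area_influence == 5))
  expect_equal(sum(lay$area_influence), 18 * 5 * 1)
  # degenerate height: one EDSU per transect
  cfg2 <- sim_config(extent = c(10, 0.5), transect_spacing = 5,
                     total_biomass = c(anchovy = 1))
  lay2 <- build_transect_layout(cfg2)
  expect_identical(nrow(lay2), 3L)
  # extent narrower than one transect spacing is rejected
  expect_error(build_transect_layout(
    sim_config(extent = c(3, 10), transect_spacing = 5,
               total_biomass = c(anchovy = 1))), "transect spacing")
})

test_that("degenerate limits: constant field, determinism, biomass conservation", {
  # occupied_fraction 1 and log_sd 0 give a constant field at Q / sum(s)
  cfg <- sim_config(extent = c(20, 10), occupied_fraction = 1, log_sd = 0,
                    total_biomass = c(anchovy = 1234), seed = 5)
  d <- simulate_density_field(cfg)
  expect_equal(d$density_anchovy,
               rep(1234 / sum(d$area_influence), nrow(d)), tolerance = 1e-12)
  # same seed, same config: bit-identical draws
  cfg2 <- sim_config(extent = c(20, 10), occupied_fraction = 0.5,
                     total_biomass = c(anchovy = 100, sardine = 50), seed = 77)
  d1 <- simulate_density_field(cfg2)
  d2 <- simulate_density_field(cfg2)
  expect_identical(d1$density_anchovy, d2$density_anchovy)
  expect_identical(d1$density_sardine, d2$density_sardine)
  # rescaling conservation across random configs
  for (seed in 1:10) {
    cfg3 <- sim_config(extent = c(25, 15), occupied_fraction = 0.4,
                       nugget_fraction = 0.2, seed = seed,
                       total_biomass = c(anchovy = 5000, sardine = 2500))
    d3 <- simulate_density_field(cfg3)
    expect_equal(sum(d3$density_anchovy * d3$area_influence), 5000,
                 tolerance = 1e-9)
    expect_equal(sum(d3$density_sardine * d3$area_influence), 2500,
                 tolerance = 1e-9)
  }
})

test_that("realized occupied fraction concentrates around the target", {
  # short-range field over a large extent: realized positive fraction within
  # +/-0.05 of the 0.5 target in at least 95% of seeds
  cfg0 <- sim_config(extent = c(95, 95), transect_spacing = 5,
                     variogram_range = 5, occupied_fraction = 0.5,
                     total_biomass = c(anchovy = 1000))
  hits <- 0L
  n_seeds <- 60L
  for (seed in seq_len(n_seeds)) {
    cfg <- sim_config(extent = c(95, 95), transect_spacing = 5,
                      variogram_range = 5, occupied_fraction = 0.5,
                      total_biomass = c(anchovy = 1000), seed = seed)
    tr <- sim_truth(simulate_density_field(cfg))
    if (abs(tr$species$anchovy$occupied_fraction - 0.5) <= 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("centre-of-gravity shift displaces the realized CG as requested", {
  for (seed in 1:5) {
    cfg0 <- sim_config(extent = c(40, 30), occupied_fraction = 0.8, seed = seed,
                       total_biomass = c(anchovy = 1000))
    cfg1 <- sim_config(extent = c(40, 30), occupied_fraction = 0.8, seed = seed,
                       total_biomass = c(anchovy = 1000),
                       cg_shift = list(anchovy = c(5, -3)))
    cg0 <- sim_truth(simulate_density_field(cfg0))$species$anchovy$cg
    cg1 <- sim_truth(simulate_density_field(cfg1))$species$anchovy$cg
    # displacement is along the requested direction with the requested length
    delta <- cg1 - cg0
    expect_equal(sqrt(sum(delta^2)), sqrt(34), tolerance = 1e-6)
    expect_equal(delta[["x"]] / delta[["y"]], 5 / -3, tolerance = 1e-6)
  }
})

test_that("latent correlation couples the two species' fields", {
  z_cor <- function(rho, seed) {
    cfg <- sim_config(extent = c(60, 40), occupied_fraction = 1,
                      latent_correlation = rho, seed = seed,
                      total_biomass = c(anchovy = 100, sardine = 100))
    d <- simulate_density_field(cfg)
    cor(log(d$density_anchovy), log(d$density_sardine))
  }
  pos <- mean(vapply(1:5, function(s) z_cor(0.8, s), numeric(1)))
  zero <- mean(vapply(1:5, function(s) z_cor(0, s), numeric(1)))
  expect_gt(pos, 0.55)
  expect_lt(abs(zero), 0.35)
})

test_that("isotropic fields show matched variography along and across transects", {
  # square grid with equal spacing in x and y; compare the mean squared
  # increment at one grid step in each direction
  gx <- numeric(0)
  gy <- numeric(0)
  for (seed in 1:12) {
    cfg <- sim_config(extent = c(48, 48), transect_spacing = 2,
                      edsu_spacing = 2, variogram_range = 10,
                      occupied_fraction = 1, anisotropy_ratio = 1,
                      total_biomass = c(anchovy = 100), seed = seed)
    d <- simulate_density_field(cfg)
    v <- log(d$density_anchovy)
    key <- paste(d$x, d$y)
    idx <- function(x, y) match(paste(x, y), key)
    i_x <- idx(d$x + 2, d$y); i_y <- idx(d$x, d$y + 2)
    gx <- c(gx, mean((v - v[i_x])^2, na.rm = TRUE) / 2)
    gy <- c(gy, mean((v - v[i_y])^2, na.rm = TRUE) / 2)
  }
  expect_lt(abs(log(mean(gx) / mean(gy))), 0.2)
})

test_that("anisotropy shortens the east-west structure", {
  gx <- numeric(0); gy <- numeric(0)
  for (seed in 1:8) {
    cfg <- sim_config(extent = c(48, 48), transect_spacing = 2,
                      edsu_spacing = 2, variogram_range = 16,
                      occupied_fraction = 1, anisotropy_ratio = 0.25,
                      total_biomass = c(anchovy = 100), seed = seed)
    d <- simulate_density_field(cfg)
    v <- log(d$density_anchovy)
    key <- paste(d$x, d$y)
    idx <- function(x, y) match(paste(x, y), key)
    gx <- c(gx, mean((v - v[idx(d$x + 2, d$y)])^2, na.rm = TRUE) / 2)
    gy <- c(gy, mean((v - v[idx(d$x, d$y + 2)])^2, na.rm = TRUE) / 2)
  }
  # x-lags are inflated by 1/ratio, so variance grows faster east-west
  expect_gt(mean(gx), 1.5 * mean(gy))
})

test_that("multi-year panels enforce shared layouts and couple biomass with occupation", {
  base <- sim_config(extent = c(45, 25), occupied_fraction = 0.5,
                     total_biomass = c(anchovy = 1000, sardine = 500), seed = 3)
  cfgs <- coupled_year_configs(base, years = 2001:2008)
  panel <- simulate_multiyear_panel(cfgs)
  expect_length(panel$datasets, 8L)
  bio <- vapply(panel$truths, function(t) t$species$anchovy$biomass, numeric(1))
  pa <- vapply(panel$datasets, function(d) {
    positive_area(species_samples(d, "anchovy"))
  }, numeric(1))
  expect_gt(cor(bio, pa, method = "spearman"), 0)
  # identical configs, different seeds: same target biomass, different draws
  c1 <- coupled_year_configs(base, years = 2001:2002,
                             biomass_factors = c(1, 1),
                             occupied_fractions = c(0.5, 0.5),
                             seeds = c(11L, 12L))
  p2 <- simulate_multiyear_panel(c1)
  expect_equal(p2$truths[[1]]$species$anchovy$biomass,
               p2$truths[[2]]$species$anchovy$biomass)
  expect_false(identical(p2$datasets[[1]]$density_anchovy,
                         p2$datasets[[2]]$density_anchovy))
  # single-config panel is flagged
  expect_warning(simulate_multiyear_panel(cfgs[1]), "single")
  # inconsistent layouts are rejected
  other <- sim_config(extent = c(50, 25), total_biomass = c(anchovy = 1))
  expect_error(simulate_multiyear_panel(list(base, other)), "layout")
})
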