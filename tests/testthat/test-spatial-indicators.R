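test_that("centre of gravity: identity, weighting, and the all-zero contract", {
  one <- make_samples(3.2, -1.5, 4, 2)
  cg <- centre_of_gravity(one)
  expect_equal(c(cg$x, cg$y), c(3.2, -1.5))
  # A=(0,0) z=2 s=1 and B=(10,0) z=1 s=2 carry equal weight -> CG (5,0)
  two <- make_samples(c(0, 10), c(0, 0), c(2, 1), c(1, 2))
  cg2 <- centre_of_gravity(two)
  expect_equal(c(cg2$x, cg2$y), c(5, 0))
  expect_error(centre_of_gravity(make_samples(1:3, 1:3, c(0, 0, 0))),
               "all densities are zero")
})

test_that("inertia and isotropy on hand-calculable configurations", {
  # all mass at one point: zero inertia, isotropy 1 by convention
  pt <- make_samples(c(2, 2), c(3, 3), c(1, 4))
  ii <- inertia_and_isotropy(pt)
  expect_equal(ii$inertia, 0)
  expect_equal(ii$isotropy, 1)
  # equal masses at (0,0) and (10,0): inertia 25, collinear -> isotropy 0
  line <- make_samples(c(0, 10), c(0, 0), c(1, 1))
  ii2 <- inertia_and_isotropy(line)
  expect_equal(ii2$inertia, 25)
  expect_equal(ii2$isotropy, 0)
  # equal masses at the four corners (+/-1, +/-1): inertia 2, isotropy 1
  sq <- make_samples(c(1, 1, -1, -1), c(1, -1, 1, -1), rep(1, 4))
  ii3 <- inertia_and_isotropy(sq)
  expect_equal(ii3$inertia, 2)
  expect_equal(ii3$isotropy, 1)
})

test_that("occupation and aggregation areas on hand-evaluated cases", {
  expect_equal(positive_area(make_samples(1:3, 1:3, c(1, 3, 0), c(1, 1, 7))), 2)
  expect_equal(positive_area(make_samples(1:2, 1:2, c(0, 0))), 0)
  # single positive sample: SA = EA = its area of influence
  single <- make_samples(0, 0, 2, 3.5)
  expect_equal(spreading_area(single), 3.5)
  expect_equal(equivalent_area(single), 3.5)
  # ranked-sum hand evaluation: z = {3,1}, s = {1,1} -> SA = 1.5, EA = 1.6
  two <- make_samples(c(0, 1), c(0, 0), c(3, 1))
  expect_equal(spreading_area(two), 1.5)
  expect_equal(equivalent_area(two), 1.6)
  # uniform field: PA = SA = EA = total area
  unif <- make_samples(1:6, rep(0, 6), rep(2.5, 6), rep(1.5, 6))
  expect_equal(spreading_area(unif), 9, tolerance = 1e-12)
  expect_equal(equivalent_area(unif), 9, tolerance = 1e-12)
  expect_equal(positive_area(unif), 9)
  expect_error(spreading_area(make_samples(1, 1, 0)), "zero")
  expect_error(equivalent_area(make_samples(1, 1, 0)), "zero")
})

test_that("patch identification follows the sequential rule", {
  # two clusters on a line: {10,9} at x=50,51 and {5,4,3} at x=0,1,2
  smp <- make_samples(c(50, 51, 0, 1, 2), rep(0, 5), c(10, 9, 5, 4, 3))
  ps <- identify_patches(smp, dlim = 20, min_fraction = 0.10)
  expect_identical(nrow(ps$patches), 2L)
  expect_equal(sort(ps$patches$abundance), c(12, 19))
  expect_identical(ps$n_major_patches, 2L)
  expect_equal(sum(ps$patches$abundance),
               sum(smp$z * smp$s))
  # two positives 50 nmi apart with dlim 20 cannot merge
  far <- make_samples(c(0, 50), c(0, 0), c(1, 1))
  expect_identical(nrow(identify_patches(far, dlim = 20)$patches), 2L)
  # single positive sample: one patch, major
  ps1 <- identify_patches(make_samples(1, 1, 2), dlim = 20)
  expect_identical(ps1$n_major_patches, 1L)
  # no positives: empty patch set
  ps0 <- identify_patches(make_samples(1:2, 1:2, c(0, 0)))
  expect_identical(ps0$n_major_patches, 0L)
  expect_identical(nrow(ps0$patches), 0L)
})

test_that("collocation index: boundary values, hand case, symmetry", {
  a <- make_samples(c(0, 0), c(0, 2), c(1, 1))
  b <- make_samples(c(3, 3), c(0, 2), c(1, 1))
  # I1 = I2 = 1, dCG^2 = 9 -> GIC = 1 - 9/11
  expect_equal(global_index_of_collocation(a, b), 1 - 9 / 11, tolerance = 1e-12)
  expect_equal(global_index_of_collocation(a, b),
               global_index_of_collocation(b, a), tolerance = 1e-12)
  # zero-abundance population is an error
  expect_error(global_index_of_collocation(a, make_samples(1, 1, 0)),
               "zero")
  # populations on different projections are rejected
  a2 <- a; attr(a2, "origin") <- c(15, 37)
  b2 <- b; attr(b2, "origin") <- c(20, 40)
  expect_error(global_index_of_collocation(a2, b2), "projection")
})

test_that("biomass estimators agree where they must and weight areas correctly", {
  d <- make_dataset(c(0, 1), c(0, 0), list(anchovy = c(2, 3)), s = c(4, 5))
  expect_equal(estimate_biomass(d, "anchovy", "edsu"), 23)
  expect_equal(estimate_biomass(d, "anchovy", "transect"),
               mean(c(2, 3)) * 9)
  # equal EDSU areas within one transect: methods agree exactly
  d2 <- make_dataset(0:4, rep(0, 5), list(anchovy = runif(5)), s = rep(2, 5))
  expect_equal(estimate_biomass(d2, "anchovy", "edsu"),
               estimate_biomass(d2, "anchovy", "transect"), tolerance = 1e-12)
  # all-zero densities: zero under both methods
  d3 <- make_dataset(0:2, rep(0, 3), list(anchovy = rep(0, 3)))
  expect_equal(estimate_biomass(d3, "anchovy", "edsu"), 0)
  expect_equal(estimate_biomass(d3, "anchovy", "transect"), 0)
  expect_error(estimate_biomass(d, "sprat"), "unknown species")
})

test_that("packing density is biomass over positive area", {
  expect_equal(packing_density(23, 9), 23 / 9)
  expect_error(packing_density(1, 0), "positive area is zero")
  # uniform field: packing density equals the constant density
  smp <- make_samples(1:5, rep(0, 5), rep(2.5, 5), rep(2, 5))
  expect_equal(packing_density(sum(smp$z * smp$s), positive_area(smp)), 2.5)
})

test_that("scale and translation equivariance of the indicator suite", {
  set.seed(31)
  for (rep in 1:20) {
    smp <- rand_samples(15)
    if (!any(smp$z > 0)) next
    k <- runif(1, 0.1, 10)
    sk <- smp; sk$z <- sk$z * k
    st <- smp; st$x <- st$x + 12.5; st$y <- st$y - 7.25
    cg <- centre_of_gravity(smp); cgt <- centre_of_gravity(st)
    expect_equal(c(cgt$x, cgt$y), c(cg$x + 12.5, cg$y - 7.25), tolerance = 1e-9)
    cgk <- centre_of_gravity(sk)
    expect_equal(c(cgk$x, cgk$y), c(cg$x, cg$y), tolerance = 1e-9)
    for (f in list(function(p) inertia_and_isotropy(p)$inertia,
                   function(p) inertia_and_isotropy(p)$isotropy,
                   positive_area, spreading_area, equivalent_area,
                   function(p) identify_patches(p, dlim = 10)$n_major_patches)) {
      expect_equal(f(sk), f(smp), tolerance = 1e-9)
      expect_equal(f(st), f(smp), tolerance = 1e-9)
    }
    expect_equal(sum(sk$z * sk$s), k * sum(smp$z * smp$s), tolerance = 1e-9)
  }
})

test_that("compute_indicator_set composes the component indicators", {
  d <- make_dataset(c(0, 1), c(0, 0), list(anchovy = c(3, 1), sardine = c(1, 3)))
  iset <- compute_indicator_set(d, "anchovy", other_species = "sardine",
                                variography = FALSE)
  smp <- species_samples(d, "anchovy")
  expect_equal(iset$spreading_area, spreading_area(smp))
  expect_equal(iset$equivalent_area, equivalent_area(smp))
  expect_equal(iset$positive_area, positive_area(smp))
  expect_equal(iset$biomass, estimate_biomass(d, "anchovy"))
  expect_equal(iset$gic,
               global_index_of_collocation(smp, species_samples(d, "sardine")))
  cg <- centre_of_gravity(smp)
  expect_equal(iset$cg_lon, cg$lon)
  # invariant: packing density x positive area = biomass
  expect_equal(iset$packing_density * iset$positive_area, iset$biomass,
               tolerance = 1e-9)
  # empty slice errors
  expect_error(compute_indicator_set(d[0, ], "anchovy"), "empty")
  # uniform field collapse within the composed set
  du <- make_dataset(0:5, rep(0, 6), list(anchovy = rep(2, 6)), s = rep(3, 6))
  isu <- compute_indicator_set(du, "anchovy", variography = FALSE)
  expect_equal(isu$positive_area, 18)
  expect_equal(isu$spreading_area, 18, tolerance = 1e-12)
  expect_equal(isu$equivalent_area, 18, tolerance = 1e-12)
  expect_identical(isu$n_major_patches, 1L)
})
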