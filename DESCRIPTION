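Package: spatfish
Title: Spatial Indicators and Indicator Variography for Acoustic Survey Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise the spatial distribution of pelagic fish
    populations from acoustic-survey density data at the resolution of the
    elementary distance sampling unit (EDSU). Implements the classical suite
    of survey-based spatial indicators (centre of gravity, inertia and
    isotropy, positive/spreading/equivalent areas, major-patch counts,
    global index of collocation, packing density), indicator variography of
    the high-density fraction of the stock (abundance cut-off, indicator
    transform, omnidirectional empirical variogram, nugget plus spherical
    model fit), biomass estimation from EDSU or transect areas of influence,
    and a multivariate stage linking biomass to spatial structure via
    correlation-matrix PCA with supplementary variables and stepwise
    regression on component scores. A Gaussian-random-field survey simulator
    generates zero-inflated lognormal density fields along parallel
    transects with recorded ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    withr
Config/testthat/edition: 3
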