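---
title: "Methods: survey spatial indicators, indicator variography, and the biomass linkage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: survey spatial indicators, indicator variography, and the biomass linkage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatfish)
```

This vignette documents the models, conventions and numerical choices
behind `spatfish`, in the spirit of a methods section: what each quantity
is, which decisions were genuinely open, and what the synthetic-survey
tests do and do not demonstrate about real data.

## Data model and projection

The unit of observation is the EDSU: a 1-nmi along-track segment with a
per-species density `z` (t·nmi⁻²) and an area of influence `s` (nmi²), the
surface it represents in every spatial integral. Weighting by `s` is what
lets surveys with locally irregular designs (coastline gaps, edge sectors)
enter the same indicator formulas as perfectly regular ones.

Positions arrive as WGS84 longitude/latitude but all indicator math needs
planar nautical miles (inertia is reported in nmi², patch distances in
nmi). We use a local equirectangular projection about the dataset mean
position: `y = (lat − lat₀)·60` (one minute of latitude is one nautical
mile by definition) and `x = (lon − lon₀)·60·cos(lat₀)`. At the ≤ 200 nmi
extents of typical survey sub-areas and mid-latitudes this agrees with
great-circle distances to well under 1 % (asserted in the test suite
against a haversine oracle); no geodesic machinery is warranted. The
inverse transform is exact, origins at ±90° latitude are rejected, and the
origin is stored on the dataset so centres of gravity can be reported in
degrees. Which projection the original survey software used is not
documented anywhere we could rely on; the equirectangular choice is our
own, and its error is negligible at these scales.

## The indicator suite

All indicators weight each EDSU by `z·s` (abundance) or `s` (area), so a
dense EDSU representing a wide swath counts accordingly.

* **Centre of gravity and inertia** are the abundance-weighted mean
  location and mean squared distance from it. The weighted covariance
  matrix of positions has eigenvalues `λ₁ ≥ λ₂` summing to the inertia;
  **isotropy** `√(λ₂/λ₁)` is 1 for a circular cloud and 0 for a collinear
  one. Two conventions are ours: a point population (zero inertia) has
  isotropy 1, and a second eigenvalue below `1e−12·λ₁` is treated as 0 —
  the square root would otherwise amplify O(1e−17) eigen-solver noise into
  O(1e−9) spurious isotropy.
* **Positive area** sums `s` over strictly positive densities. No minimum
  density floor is applied; what counts as "present" is whatever the
  upstream echo-classification called nonzero.
* **Spreading area** integrates the area-cumulated abundance curve:
  ranking EDSUs by decreasing density, `SA = (2/Q)·Σ s_i(Q − Q_i + z_i
  s_i/2)`. **Equivalent area** is `Q²/Σz²s`. Both equal the positive area
  exactly for a uniform field and shrink with concentration; `EA ≤ PA` and
  `SA ≤ PA` always (Cauchy–Schwarz and concavity respectively), but `EA ≤
  SA` is *not* a theorem — `z = {3, 1}, s = {1, 1}` gives `EA = 1.6 > SA =
  1.5`, and the test suite pins this counterexample so nobody "fixes" it.
* **Patches** are grown sequentially: positive EDSUs in decreasing density
  order, each joining the nearest patch whose *current* abundance-weighted
  centre lies within `dlim` (default 20 nmi), else founding a new patch.
  Ties in density follow input row order; ties in distance go to the
  lowest patch index. Membership is decided against the centre at
  assignment time — the final centre may drift, and re-testing membership
  afterwards could disagree; we document rather than hide this property of
  the sequential design. "Major" patches hold strictly more than 10 % of
  abundance (strictness configurable).
* **Global index of collocation** `1 − ΔCG²/(ΔCG² + I₁ + I₂)` compares two
  populations in one shared projection (enforced). The fully degenerate
  case — both populations a single point at the same location — is defined
  as 1 (coincident centres of gravity).
* **Biomass** can be integrated per EDSU (`Σ z s`) or per transect (mean
  density × transect area of influence); the two agree exactly when EDSU
  areas are constant within a transect, a property used as a test oracle.
  **Packing density** is biomass over positive area.

## Indicator variography

The high-density fraction of a stock — the part a fishery actually targets
— is isolated by the abundance cut-off `c80`: EDSUs are ranked by
decreasing density and the cut-off is the density of the last EDSU needed
to reach 80 % of biomass. One inequality convention matters: with a
cut-off *chosen at an observed density*, strict exceedance would exclude
the defining EDSU and capture less than 80 %. Membership is therefore `z ≥
c80` (a strict variant is provided, nudging the threshold just below the
defining density). The binary field `1{z ≥ c80}` then goes into the
classical omnidirectional semivariogram estimator over unordered pairs,
binned at the EDSU spacing (1 nmi) up to half the maximum inter-sample
distance. Variogram pairs are *unweighted* by area of influence — the
weights enter the indicators, not the pair statistic — which is a
documented divergence risk against legacy variography software whose
internal estimator is not published.

The nugget + spherical model `γ(h) = c₀ + c₁(1.5h/a − 0.5(h/a)³)` (flat
beyond `a`) is fitted by pair-count-weighted least squares: a grid over the
range at half-lag steps, non-negative weighted least squares for `(c₀,
c₁)` at each candidate, then Brent refinement of the range. The fit is
fully deterministic. Candidate ranges must exceed the *second* usable lag:
a range at or below it would make the structured component a function of
the first bin alone, indistinguishable from nugget noise — with that rule,
flat (pure-nugget) input collapses to `c₁ = 0` and is flagged degenerate
with a normalized nugget of 100 %, and randomly permuting indicator values
over fixed positions reliably reports ≥ 80 % nugget. The normalized nugget
`100·c₀/(c₀+c₁)` measures small-scale roughness; the range approximates
mean patch size.

## The survey simulator

Real EDSU tables from the motivating surveys are not public, so the
package generates its own: north–south parallel transects (5 or 10 nmi
apart, the two designs used in practice) with 1-nmi EDSUs, each carrying
`area_influence = transect_spacing × edsu_spacing` — interior and edge
alike, a deliberate simplification. Per species, density is a
transformed-Gaussian field: `z = exp(m + σG₁)·1{G₂ > Φ⁻¹(1 − p_occ)}`,
with `G₁` (intensity) and `G₂` (occupancy) standard Gaussian fields sharing
the correlation `(1−η)·sph(h; a) + η·1{h=0}`. This is the simplest law
producing the three features the indicators respond to: zero inflation,
right skew, and spatial autocorrelation with a controllable range and
nugget. Anisotropy stretches x-lags by the inverse of `anisotropy_ratio`;
species fields share a latent component with correlation
`latent_correlation`; and a requested centre-of-gravity shift is realized
by tilting the log-intensity with an exponential linear trend whose
coefficient vector is solved by Newton iteration on the realized field (the
Jacobian is the tilted position covariance), so the realized CG
displacement matches the request to ~1e−12 nmi rather than approximately.
Densities are finally rescaled so `Σ z s` equals the target biomass
exactly; the scaling leaves every indicator except biomass and packing
density untouched (scale equivariance, tested).

The covariance is factorized densely on the sample locations, which keeps
the generator exact but caps it at ~4000 EDSUs; larger surveys should be
simulated in sub-areas. One seed drives all randomness; per-species draws
follow a fixed order so runs are bit-reproducible. If an occupancy draw
leaves no positive EDSU (possible at small `p_occ`), the cell with the
highest occupancy field is forced positive so downstream indicators remain
defined — a documented departure from the pure model in a vanishing
fraction of draws.

Default parameters describe a plausible Mediterranean summer survey:
biomass of order 10⁴ t per species, autocorrelation range 10 nmi, nugget
fraction 0.15 (observed indicator variograms always carry some small-scale
roughness; an exactly zero nugget would also make the fitted nugget
percentage degenerate under mean-standardization), occupation 0.3–0.6 of
the surveyed rectangle. Multi-year panels are built by co-varying total
biomass and occupied fraction across years — the biomass–occupation
coupling the multivariate stage is designed to detect. What the simulator
does *not* emulate: coastline-shaped survey boundaries (irregularity can
be exercised by masking EDSUs), day/night behaviour, school-level
(sub-EDSU) structure, and vessel-track deviations. Passing tests on these
fields show the estimators recover known structure of the assumed law —
not that the law is a complete model of any real ecosystem.

## The multivariate stage

Indicators are standardized by dividing each value by its (species,
sub-area) group mean — "mean 1 within each cell" — except the major-patch
count and the CG coordinates, which stay in their natural units (degrees
for the CG: the indicator tables report it in degrees, and correlation-
matrix PCA is scale-free anyway, so the choice only affects readability).
Interpreting "species and area mean" as the mean over years within each
(species, sub-area) cell is the only reading that makes panels pooled
across areas or species comparable, and it reduces to "the mean in the
area" for single-area poolings.

PCA is an eigendecomposition of the Pearson correlation matrix of the
active columns; loadings are variable–score correlations (equal to
`√λ·e`), so eigenvalues sum to the number of active variables and the
correlation matrix is reconstructed exactly from the loadings (both
asserted to 1e−10). Standardized biomass and packing density enter as
supplementary variables — correlated with the scores but excluded from the
decomposition. Component signs are arbitrary in any PCA; we fix them so
each axis's largest-|loading| variable loads positively, making outputs
reproducible run to run. Loading and supplementary-correlation
significance uses the two-sided correlation t-test at α = 0.05 — the
convention of the classical multivariate packages this stage mirrors; with
4–9 years per cell these tests are weak, and the flags should be read as
screening, not inference.

The regression of standardized biomass on component scores uses forward
selection with an F-test p-to-enter of 0.05 over the leading axes (the
smallest set reaching 85 % of variance, capped at 5). Because scores are
mutually orthogonal, coefficients never change as terms enter and the
selected set equals the axes individually significant at 0.05 — an
algebraic identity the tests verify. No removal step is needed for the
same reason. One calibration subtlety: with K candidate axes, the
probability that a pure-noise response selects nothing is essentially
`0.95^K` (0.95 at K = 1, 0.899 at K = 2 by exact simulation), so the
"null stays empty at least 90 % of the time" property holds only for a
single candidate axis — the dominant-axis case of a strongly collinear
indicator panel; the suite checks the null calibration there and pins a
fixed-seed K = 2 case separately. This familywise inflation is inherent to
stepwise selection at a fixed per-entry level, not an implementation
artifact.

Four pooling schemes are run on a two-species, two-area panel: each
species pooled across areas, and each area pooled across species —
per-cell analysis being impossible with so few years. Constant active
columns within a pooling (e.g. a patch count that never varies) are
dropped with a warning rather than aborting the pooled run.

## Problem sizes and tolerances in the test suite

Exact identities (projection round-trips, ranked-sum formulas, PCA
algebra, stepwise orthogonality) are asserted at 1e−9 to 1e−12. Brute-force
oracle equivalence uses 500 random instances of ≤ 20 EDSUs. Stochastic
recovery properties use the smallest sizes at which the statistics
stabilize: ~1000 EDSUs on 5-nmi transects for variogram range recovery
(within ±30 % of the simulated 10 nmi in ≥ 80 % of 50 seeds, both for the
indicator field at the c80 cut-off and for log density), ~1900 EDSUs for
occupancy-fraction concentration, 2000 random points for the Bernoulli
sill check (within 10 % of `p(1−p)`), and 50 independent 8-year ×
2-species × 2-area panels of 260-EDSU surveys for the end-to-end check
that standardized biomass aligns positively with the first component
carrying positive occupation/aggregation/patchiness loadings. Acceptance-
grade boundary values (the collocation index at 0 and 1) are exact.
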