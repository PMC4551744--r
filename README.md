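# spatfish

Spatial indicators and indicator variography for acoustic-survey data on
small pelagic fish.

Fisheries acoustic surveys deliver one density value (t·nmi⁻²) per
*elementary distance sampling unit* (EDSU, the 1-nmi along-track segment),
together with the *area of influence* s (nmi²) that each EDSU represents.
From such tables, `spatfish` characterises how a population occupies space
and how that structure co-varies with stock biomass — the toolkit used to
compare anchovy and sardine distributions across Mediterranean survey
areas, rebuilt as a tested, reusable R package. Because survey EDSU tables
are rarely public, the package ships a transect-survey simulator with
recorded ground truth, so every stage can be exercised and validated end to
end.

## What it computes

With density `z_i`, weight `s_i` at projected position `(x_i, y_i)`, and
`Q = Σ z_i s_i` the total biomass:

* **Centre of gravity** `CG = Σ z_i s_i (x_i, y_i) / Q` and **inertia**
  `I = Σ z_i s_i ‖(x_i,y_i) − CG‖² / Q` (nmi²), with **isotropy**
  `√(λ₂/λ₁)` from the weighted covariance eigenvalues — location and
  dispersion of the population.
* **Positive area** `PA = Σ s_i 1{z_i > 0}`, **spreading area**
  `SA = (2/Q) Σ_i s_i (Q − Q_i + z_i s_i/2)` over density-ranked EDSUs, and
  **equivalent area** `EA = Q² / Σ z_i² s_i` — occupation and aggregation.
* **Major patches**: sequential assignment of density-ranked EDSUs to the
  nearest patch centre within a threshold distance (default 20 nmi),
  counting patches holding > 10 % of abundance.
* **Global index of collocation** between two species,
  `GIC = 1 − ΔCG² / (ΔCG² + I₁ + I₂)` ∈ [0, 1].
* **Biomass** by EDSU-area or transect-area integration and **packing
  density** `Pck = Q / PA`.
* **Indicator variography** of the high-density fraction of the stock: the
  cut-off `c80` above which EDSUs carry 80 % of biomass, the binary field
  `1{z ≥ c80}`, its omnidirectional empirical semivariogram, and a
  pair-count-weighted nugget + spherical model fit yielding the
  autocorrelation **range** (mean patch size, nmi) and the **normalized
  nugget** (% of sill; small-scale roughness).
* **Multivariate linkage**: indicators standardized by species-and-area
  means, PCA on their correlation matrix with standardized biomass and Pck
  as supplementary variables, and forward stepwise regression of
  standardized biomass on the leading component scores.

## Worked example

```r
library(spatfish)

cfg <- sim_config(extent = c(45, 25), transect_spacing = 5,
                  variogram_range = 10, nugget_fraction = 0.15,
                  occupied_fraction = 0.5,
                  total_biomass = c(anchovy = 15000, sardine = 10000),
                  cg_shift = list(anchovy = c(0, 0), sardine = c(6, 0)),
                  seed = 42)
survey <- simulate_density_field(cfg)
compute_indicator_set(survey, "anchovy", other_species = "sardine")
```

yields (transposed):

```
cg_lon          13.48      # centre of gravity, degrees E
cg_lat          37.49      # degrees N
inertia         189.87     # nmi^2 - dispersion around the CG
isotropy        0.54       # 1 = circular, 0 = collinear
n_major_patches 3          # patches holding > 10% of abundance
positive_area   705        # nmi^2 of presence
spreading_area  367.9      # nmi^2, aggregation-corrected occupation
equivalent_area 369.2      # nmi^2, Q^2 / sum(z^2 s)
gic             0.81       # overlap with sardine
cutoff          16.11      # c80, t/nmi^2
range_nmi       9.53       # fitted spherical range (true: 10)
nugget_pct      36.1       # % of sill
biomass         15000      # t (the simulation target, exactly)
packing_density 21.28      # t/nmi^2 over the positive area
```

The population sits at 13.48°E 37.49°N occupying 705 nmi² of the surveyed
rectangle; its high-density patches (EDSUs above 16.1 t·nmi⁻², which carry
80 % of the 15 000 t biomass) have a fitted autocorrelation range of
9.5 nmi against a simulated truth of 10 nmi. The variography steps are also
available piecewise:

```r
smp <- species_samples(survey, "anchovy")
cut <- abundance_cutoff(smp)
fit <- fit_spherical_model(empirical_variogram(smp$x, smp$y,
         indicator_transform(smp, cut)$indicator))
#> <abundance_cutoff> c80 = 16.1075 t/nmi^2 (rank 65, captures 80.5% of biomass, ge)
#> <variogram_fit> spherical: range 9.53 nmi, nugget 0.0751, partial sill 0.133
#>                 (nugget 36.1% of sill)
```

The full pipeline — simulate (or read CSVs), indicators per (species,
sub-area, year), variography, pooled PCA + stepwise regression, manifest
and summary report — runs from one YAML config:

```r
run_pipeline(system.file("extdata", "demo-config.yaml", package = "spatfish"),
             out_dir = "demo-out")
```

A thin command-line wrapper for the `run` and `simulate` stages is
installed at `inst/cli/spatfish-pipeline.R`.

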