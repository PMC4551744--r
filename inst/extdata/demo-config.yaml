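# Demo pipeline configuration: a synthetic two-species, two-area, 8-year
# panel with biomass and occupation rising together across years.
simulate:
  years: [2002, 2003, 2004, 2005, 2006, 2007, 2008, 2009]
  biomass_factors: [1.0, 1.15, 1.3, 1.45, 1.6, 1.75, 1.9, 2.0]
  occupied_fractions: [0.30, 0.34, 0.39, 0.43, 0.47, 0.51, 0.56, 0.60]
  areas:
    S1:
      extent: [30, 20]
      transect_spacing: 5
      edsu_spacing: 1
      variogram_range: 10
      log_sd: 1
      total_biomass: {anchovy: 15000, sardine: 10000}
      cg_shift: {anchovy: [0, 0], sardine: [6, 0]}
      origin: [12.6, 37.4]
    G1:
      extent: [30, 20]
      transect_spacing: 5
      edsu_spacing: 1
      variogram_range: 7
      log_sd: 1
      total_biomass: {anchovy: 40000, sardine: 25000}
      cg_shift: {anchovy: [0, 0], sardine: [2, 0]}
      origin: [22.8, 40.2]
dlim: 20
min_patch_fraction: 0.10
cutoff_fraction: 0.80
lag_width: 1
alpha: 0.05
seed: 1
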