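#' Run the full survey analysis pipeline
#'
#' Orchestrates simulate (or read) -> spatial indicators + indicator
#' variography -> pooled PCA + stepwise regression, writing all inter-stage
#' artifacts and a run manifest to `out_dir`. Failures in one (species,
#' sub-area, year) slice are logged and skipped, never fatal to the run.
#'
#' The configuration is a list (or a YAML file holding one) with elements:
#' \describe{
#'   \item{input}{character vector of survey CSV paths; omit to simulate.}
#'   \item{simulate}{when no `input`: list with `areas` (named list of
#'     [sim_config()] argument lists), `years`, `biomass_factors`,
#'     `occupied_fractions` driving [coupled_year_configs()].}
#'   \item{dlim, min_patch_fraction, cutoff_fraction, lag_width, alpha,
#'     variance_target, max_axes}{analysis parameters; defaults 20, 0.10,
#'     0.80, 1, 0.05, 0.85, 5.}
#'   \item{seed}{integer; drives all simulation randomness.}
#' }
#'
#' @param config list or path to a YAML file.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `panel`, `analyses`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(dlim = 20, min_patch_fraction = 0.10, cutoff_fraction = 0.80,
                   lag_width = 1, alpha = 0.05, variance_target = 0.85,
                   max_axes = 5L, seed = 1L)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    warnings_log <<- c(warnings_log, msg)
    message(msg)
  }

  t0 <- Sys.time()
  datasets <- withCallingHandlers(
    pipeline_inputs(config),
    warning = function(w) { note("input: %s", conditionMessage(w))
                            invokeRestart("muffleWarning") })
  message(sprintf("[%s] inputs ready: %d dataset(s), %d EDSUs total",
                  format(Sys.time() - t0), length(datasets),
                  sum(vapply(datasets, nrow, integer(1)))))
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    write_survey_csv(d, file.path(out_dir, sprintf("survey_%s_%s.csv",
                                                   d$sub_area[1], d$survey_year[1])))
    tr <- sim_truth(d)
    if (!is.null(tr)) {
      jsonlite::write_json(
        list(seed = tr$seed, species = tr$species),
        file.path(out_dir, sprintf("truth_%s_%s.json", d$sub_area[1],
                                   d$survey_year[1])),
        auto_unbox = TRUE, digits = NA)
    }
  }

  panel <- withCallingHandlers(
    compute_indicator_panel(datasets, dlim = config$dlim,
                            min_fraction = config$min_patch_fraction,
                            cutoff_fraction = config$cutoff_fraction,
                            lag_width = config$lag_width),
    warning = function(w) { note("indicators: %s", conditionMessage(w))
                            invokeRestart("muffleWarning") })
  utils::write.csv(panel, file.path(out_dir, "indicators.csv"), row.names = FALSE)
  message(sprintf("[%s] indicators: %d rows", format(Sys.time() - t0), nrow(panel)))

  analyses <- withCallingHandlers(
    run_pooled_analyses(panel, alpha = config$alpha,
                        variance_target = config$variance_target,
                        max_axes = config$max_axes),
    warning = function(w) { note("multivariate: %s", conditionMessage(w))
                            invokeRestart("muffleWarning") })
  dir.create(file.path(out_dir, "pca"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "models"), showWarnings = FALSE)
  for (nm in names(analyses)) {
    a <- analyses[[nm]]
    jsonlite::write_json(list(
      eigenvalues = a$pca$eigenvalues,
      variance_explained = a$pca$variance_explained,
      loadings = as.data.frame(a$pca$loadings),
      loading_significant = as.data.frame(a$pca$loading_significant),
      supplementary_correlations = as.data.frame(a$pca$supplementary_correlations),
      scores = as.data.frame(a$pca$scores)),
      file.path(out_dir, "pca", paste0(nm, ".json")),
      auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(list(
      selected = a$regression$selected,
      coefficients = as.list(a$regression$coefficients),
      r_squared = a$regression$r_squared,
      entry_pvalues = as.list(a$regression$entry_pvalues),
      empty = a$regression$empty,
      n_candidate_axes = a$n_axes),
      file.path(out_dir, "models", paste0(nm, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  message(sprintf("[%s] multivariate: %d pooled analyses",
                  format(Sys.time() - t0), length(analyses)))

  manifest <- list(
    package_version = as.character(utils::packageVersion("spatfish")),
    seed = config$seed,
    config = config[setdiff(names(config), "input_datasets")],
    rows = list(datasets = length(datasets),
                edsus = sum(vapply(datasets, nrow, integer(1))),
                indicator_rows = nrow(panel),
                analyses = length(analyses)),
    warnings = warnings_log
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_summary_report(panel, analyses, file.path(out_dir, "summary.md"))
  invisible(list(panel = panel, analyses = analyses, manifest = manifest))
}

validate_pipeline_config <- function(config) {
  if (is.null(config$input) && is.null(config$simulate)) {
    stop("config must provide either 'input' CSV paths or a 'simulate' block")
  }
  if (!is.null(config$input) && !all(file.exists(config$input))) {
    stop("input file(s) not found: ",
         paste(config$input[!file.exists(config$input)], collapse = ", "))
  }
  stopifnot(config$dlim > 0, config$min_patch_fraction >= 0,
            config$min_patch_fraction < 1, config$cutoff_fraction > 0,
            config$cutoff_fraction <= 1, config$lag_width > 0,
            config$alpha > 0, config$alpha < 1)
  invisible(TRUE)
}

pipeline_inputs <- function(config) {
  if (!is.null(config$input)) {
    return(lapply(config$input, read_survey_csv, schema = config$schema))
  }
  sim <- config$simulate
  years <- as.integer(sim$years)
  datasets <- list()
  seed_base <- as.integer(config$seed)
  for (ai in seq_along(sim$areas)) {
    area_name <- names(sim$areas)[ai]
    args <- sim$areas[[ai]]
    args$sub_area <- area_name
    args$seed <- seed_base
    if (!is.null(args$total_biomass)) {
      args$total_biomass <- unlist(args$total_biomass)
    }
    if (!is.null(args$cg_shift)) args$cg_shift <- lapply(args$cg_shift, unlist)
    base <- do.call(sim_config, args)
    cfgs <- coupled_year_configs(
      base, years,
      biomass_factors = sim$biomass_factors %||% seq(1, 2, length.out = length(years)),
      occupied_fractions = sim$occupied_fractions %||% seq(0.3, 0.6, length.out = length(years)),
      seeds = seed_base + 1000L * ai + seq_along(years))
    datasets <- c(datasets, simulate_multiyear_panel(cfgs)$datasets)
  }
  datasets
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_summary_report <- function(panel, analyses, path) {
  lines <- c("# Survey spatial-analysis summary", "",
             sprintf("%d indicator rows (%d species, %d sub-areas, %d years)",
                     nrow(panel), length(unique(panel$species)),
                     length(unique(panel$sub_area)),
                     length(unique(panel$year))), "",
             "## Indicator ranges per species and sub-area", "")
  num_cols <- c("inertia", "isotropy", "n_major_patches", "positive_area",
                "spreading_area", "equivalent_area", "gic", "range_nmi",
                "nugget_pct", "biomass", "packing_density")
  grp <- interaction(panel$species, panel$sub_area, drop = TRUE)
  for (g in levels(grp)) {
    sub <- panel[grp == g, ]
    lines <- c(lines, sprintf("### %s", g), "",
               "| indicator | min | median | max |", "|---|---|---|---|")
    for (col in intersect(num_cols, names(sub))) {
      v <- sub[[col]]
      lines <- c(lines, sprintf("| %s | %.4g | %.4g | %.4g |", col,
                                min(v), stats::median(v), max(v)))
    }
    lines <- c(lines, "")
  }
  lines <- c(lines, "## Regression of standardized biomass on PCA scores", "")
  for (nm in names(analyses)) {
    reg <- analyses[[nm]]$regression
    eq <- if (reg$empty) "no axis entered" else {
      paste0(sprintf("%.3g", reg$coefficients[1]),
             paste(sprintf(" %+.3g*%s", reg$coefficients[-1],
                           names(reg$coefficients)[-1]), collapse = ""),
             sprintf("  (R^2 = %.3f)", reg$r_squared))
    }
    lines <- c(lines, sprintf("- **%s**: %s", nm, eq))
  }
  writeLines(lines, path)
  invisible(path)
}
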