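#' Survey datasets at EDSU resolution
#'
#' A `survey_dataset` is a data frame with one row per elementary distance
#' sampling unit (EDSU): the 1-nmi along-track segment to which an acoustic
#' density (t/nmi^2) is assigned for each species. Besides the geographic
#' position (WGS84 decimal degrees) each EDSU carries an *area of influence*
#' `area_influence` (nmi^2), the surface it represents in every spatial
#' integral, and grouping keys (`survey_year`, `sub_area`, `transect_id`).
#' Species densities live in wide columns named `density_<species>`.
#'
#' @param data data frame with columns `survey_year`, `sub_area`,
#'   `transect_id`, `lon`, `lat`, `area_influence` and one `density_<species>`
#'   column per species. Optional `x`, `y` hold projected positions in nmi.
#' @param species character vector of species labels; defaults to the
#'   species found in `density_*` columns, in column order.
#' @param origin projection origin `c(lon0, lat0)` in degrees, or `NULL` to
#'   use the arithmetic mean position when projecting.
#' @return object of class `survey_dataset` (a data frame).
#' @export
survey_dataset <- function(data, species = NULL, origin = NULL) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  required <- c("survey_year", "sub_area", "transect_id", "lon", "lat",
                "area_influence")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  dens_cols <- grep("^density_", names(data), value = TRUE)
  if (is.null(species)) {
    species <- sub("^density_", "", dens_cols)
  }
  if (length(species) == 0L) {
    stop("no species density columns found (expected columns named 'density_<species>')")
  }
  missing_sp <- setdiff(paste0("density_", species), names(data))
  if (length(missing_sp) > 0L) {
    stop("missing density column(s): ", paste(missing_sp, collapse = ", "))
  }
  validate_survey_records(data, species)
  attr(data, "species") <- species
  attr(data, "origin") <- origin
  class(data) <- c("survey_dataset", "data.frame")
  data
}

validate_survey_records <- function(data, species) {
  bad_row <- function(cond, what) {
    if (any(cond, na.rm = FALSE)) {
      idx <- which(is.na(cond) | cond)
      stop(sprintf("%s at row(s) %s", what,
                   paste(utils::head(idx, 5L), collapse = ", ")))
    }
  }
  bad_row(is.na(data$lon) | data$lon < -180 | data$lon > 180,
          "longitude outside [-180, 180] or missing")
  bad_row(is.na(data$lat) | data$lat < -90 | data$lat > 90,
          "latitude outside [-90, 90] or missing")
  bad_row(is.na(data$area_influence) | data$area_influence <= 0,
          "non-positive or missing area_influence")
  for (sp in species) {
    z <- data[[paste0("density_", sp)]]
    bad_row(is.na(z), sprintf("missing density for species '%s'", sp))
    bad_row(!is.na(z) & z < 0, sprintf("negative density for species '%s'", sp))
  }
  invisible(TRUE)
}

#' @export
print.survey_dataset <- function(x, ...) {
  sp <- species_of(x)
  cat(sprintf("<survey_dataset> %d EDSUs, %d species (%s)\n",
              nrow(x), length(sp), paste(sp, collapse = ", ")))
  cat(sprintf("  years: %s | sub-areas: %s\n",
              paste(sort(unique(x$survey_year)), collapse = ", "),
              paste(sort(unique(as.character(x$sub_area))), collapse = ", ")))
  or <- attr(x, "origin")
  if (!is.null(or)) {
    cat(sprintf("  projection origin: (%.4f, %.4f) deg\n", or[1], or[2]))
  }
  NextMethod()
}

#' Species labels of a survey dataset
#' @param dataset a `survey_dataset`.
#' @return character vector of species labels.
#' @export
species_of <- function(dataset) {
  sp <- attr(dataset, "species")
  if (is.null(sp)) sp <- sub("^density_", "", grep("^density_", names(dataset), value = TRUE))
  sp
}

#' Local planar projection of geographic coordinates
#'
#' Projects WGS84 longitude/latitude onto a local equirectangular plane in
#' nautical miles: `x = (lon - lon0) * 60 * cos(lat0)`, `y = (lat - lat0) * 60`
#' (one minute of latitude = 1 nmi). Adequate for the <= 200 nmi extents of
#' typical survey sub-areas; all indicator math runs on these coordinates.
#'
#' @param dataset a `survey_dataset`.
#' @param origin `c(lon0, lat0)` in degrees; default is the origin stored on
#'   the dataset, else the arithmetic mean of the record positions.
#' @return the dataset with `x`, `y` columns filled (nmi) and the origin
#'   recorded in `attr(, "origin")`.
#' @export
project_coordinates <- function(dataset, origin = NULL) {
  if (is.null(origin)) origin <- attr(dataset, "origin")
  if (is.null(origin)) origin <- c(mean(dataset$lon), mean(dataset$lat))
  xy <- lonlat_to_xy(dataset$lon, dataset$lat, origin)
  dataset$x <- xy$x
  dataset$y <- xy$y
  attr(dataset, "origin") <- origin
  dataset
}

#' @rdname project_coordinates
#' @param lon,lat geographic coordinates in decimal degrees.
#' @export
lonlat_to_xy <- function(lon, lat, origin) {
  check_origin(origin)
  list(x = (lon - origin[1]) * 60 * cos(origin[2] * pi / 180),
       y = (lat - origin[2]) * 60)
}

#' @rdname project_coordinates
#' @param x,y projected coordinates in nmi.
#' @export
xy_to_lonlat <- function(x, y, origin) {
  check_origin(origin)
  list(lon = origin[1] + x / (60 * cos(origin[2] * pi / 180)),
       lat = origin[2] + y / 60)
}

check_origin <- function(origin) {
  if (!is.numeric(origin) || length(origin) != 2L || anyNA(origin)) {
    stop("projection origin must be c(lon0, lat0)")
  }
  if (abs(origin[2]) >= 90) {
    stop("projection origin latitude at +/-90 degrees is not usable (cos(lat0) -> 0)")
  }
  invisible(TRUE)
}

# Canonical column order used on disk.
survey_csv_columns <- function(species, has_xy) {
  c("survey_year", "sub_area", "transect_id", "lon", "lat", "area_influence",
    paste0("density_", species), if (has_xy) c("x", "y"))
}

#' Read an EDSU survey table from CSV
#'
#' Reads a comma-separated file with a header row into a validated
#' [survey_dataset()]. Column names may be mapped to the canonical fields via
#' `schema`; density columns are recognised either as `density_<species>` or
#' through the schema's `density` mapping. Missing densities are an error,
#' never silently zero.
#'
#' @param path file path.
#' @param schema optional column mapping: a named list (canonical field ->
#'   file column name; element `density` is itself a named vector
#'   species -> file column name), or a path to a JSON/YAML file holding the
#'   same structure.
#' @param origin optional projection origin `c(lon0, lat0)`.
#' @return a `survey_dataset`; row order preserved.
#' @export
read_survey_csv <- function(path, schema = NULL, origin = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  schema <- load_schema(schema)
  numeric_fields <- function(nms) {
    nms[nms %in% c("lon", "lat", "area_influence", "x", "y") |
        startsWith(nms, "density_")]
  }
  if (!is.null(schema)) {
    for (field in setdiff(names(schema), "density")) {
      src <- schema[[field]]
      if (!src %in% names(raw)) stop("schema column '", src, "' not found in file")
      names(raw)[names(raw) == src] <- field
    }
    if (!is.null(schema$density)) {
      dens <- unlist(schema$density)
      for (sp in names(dens)) {
        if (!dens[[sp]] %in% names(raw)) {
          stop("schema density column '", dens[[sp]], "' not found in file")
        }
        names(raw)[names(raw) == dens[[sp]]] <- paste0("density_", sp)
      }
    }
  }
  for (col in numeric_fields(names(raw))) raw[[col]] <- as.double(raw[[col]])
  survey_dataset(raw, origin = origin)
}

load_schema <- function(schema) {
  if (is.null(schema) || is.list(schema)) return(schema)
  if (is.character(schema) && length(schema) == 1L && file.exists(schema)) {
    if (grepl("\\.ya?ml$", schema)) return(yaml::read_yaml(schema))
    return(jsonlite::fromJSON(schema, simplifyVector = TRUE))
  }
  stop("schema must be a named list or a path to a JSON/YAML file")
}

#' Write an EDSU survey table to CSV
#'
#' Writes RFC-4180 CSV with deterministic column and row order and full
#' double precision (`%.17g`), so that write -> read round-trips reproduce
#' the values exactly and re-writing an unmodified dataset is byte-stable.
#'
#' @param dataset a `survey_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_survey_csv <- function(dataset, path) {
  sp <- species_of(dataset)
  has_xy <- all(c("x", "y") %in% names(dataset))
  cols <- survey_csv_columns(sp, has_xy)
  out <- dataset[, cols, drop = FALSE]
  cells <- lapply(out, csv_cell)
  header <- paste(vapply(cols, csv_quote, character(1)), collapse = ",")
  body <- if (nrow(out) > 0L) do.call(paste, c(cells, sep = ",")) else character(0)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}

csv_cell <- function(v) {
  if (is.double(v)) {
    s <- sprintf("%.17g", v)
    # trim to shortest representation that round-trips exactly
    for (d in 1:16) {
      cand <- sprintf(paste0("%.", d, "g"), v)
      ok <- as.numeric(cand) == v
      s[ok & nchar(cand) < nchar(s)] <- cand[ok & nchar(cand) < nchar(s)]
    }
    s
  } else if (is.numeric(v)) {
    as.character(v)
  } else {
    vapply(as.character(v), csv_quote, character(1), USE.NAMES = FALSE)
  }
}

csv_quote <- function(s) {
  if (grepl('[",\n]', s)) paste0('"', gsub('"', '""', s), '"') else s
}
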