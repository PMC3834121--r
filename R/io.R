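# File interchange: flat CSV for tabular data, GeoJSON FeatureCollections
# for grid cells and reserves, JSON for fitted models and summaries.

OBS_COLUMNS <- c("species", "gear", "lat", "lon", "depth_fm",
                 "habitat_code", "detected")

#' Read / write observation records
#'
#' One row per sampling event: `species, gear, lat, lon, depth_fm,
#' habitat_code, detected` (UTF-8 CSV with header). Schema violations are
#' reported with row numbers.
#'
#' @param path CSV file path.
#' @return data frame of observation records.
#' @export
read_observations <- function(path) {
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(OBS_COLUMNS, names(obs))
  if (length(missing_cols))
    stop_validation("observation file ", path, " lacks column(s): ",
                    paste(missing_cols, collapse = ", "))
  bad <- which(!obs$detected %in% c(0, 1))
  if (length(bad))
    stop_validation("detected must be 0/1; offending row(s): ",
                    paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!obs$gear %in% GEAR_LEVELS)
  if (length(bad))
    stop_validation("unknown gear; offending row(s): ",
                    paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(obs$depth_fm < 0)
  if (length(bad))
    stop_validation("negative depth_fm; offending row(s): ",
                    paste(utils::head(bad, 5), collapse = ", "))
  obs
}

#' @rdname read_observations
#' @param obs observation data frame.
#' @export
write_observations <- function(obs, path) {
  utils::write.csv(obs[, OBS_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Read / write habitat bottom-type samples
#'
#' CSV with columns `cell_id, bottom_type` (`HB`/`NH`), the raw mapped
#' data feeding [code_habitat()].
#'
#' @param path CSV file path.
#' @return data frame with `cell_id`, `bottom_type`.
#' @export
read_habitat_samples <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("cell_id", "bottom_type") %in% names(s)))
    stop_validation("habitat sample file needs columns cell_id, bottom_type")
  bad <- which(!s$bottom_type %in% BOTTOM_TYPES)
  if (length(bad))
    stop_validation("unknown bottom_type; offending row(s): ",
                    paste(utils::head(bad, 5), collapse = ", "))
  s
}

GRID_COLUMNS <- c("cell_id", "lat_min", "lat_max", "lon_min", "lon_max",
                  "depth_fm", "depth_bin", "habitat_code", "max_slope_pct",
                  "area_km2")

#' Read / write the analysis grid as flat CSV
#'
#' @param path CSV file path.
#' @return grid-cell data frame.
#' @export
read_grid_csv <- function(path) {
  g <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(GRID_COLUMNS, names(g))
  if (length(missing_cols))
    stop_validation("grid file ", path, " lacks column(s): ",
                    paste(missing_cols, collapse = ", "))
  g
}

#' @rdname read_grid_csv
#' @param cells grid-cell data frame.
#' @export
write_grid_csv <- function(cells, path) {
  keep <- c(GRID_COLUMNS, intersect("class", names(cells)))
  utils::write.csv(cells[, keep], path, row.names = FALSE)
  invisible(path)
}

#' Write / read the analysis grid as GeoJSON
#'
#' Each cell becomes a rectangle Polygon feature with properties
#' `cell_id, depth_fm, depth_bin, habitat_code, max_slope_pct, area_km2`
#' (plus `class` when present).
#'
#' @param cells grid-cell data frame.
#' @param path GeoJSON file path.
#' @export
write_grid_geojson <- function(cells, path) {
  props <- setdiff(c(GRID_COLUMNS, "class"),
                   c("lat_min", "lat_max", "lon_min", "lon_max"))
  props <- intersect(props, names(cells))
  features <- lapply(seq_len(nrow(cells)), function(i) {
    ci <- cells[i, ]
    ring <- list(c(ci$lon_min, ci$lat_min), c(ci$lon_max, ci$lat_min),
                 c(ci$lon_max, ci$lat_max), c(ci$lon_min, ci$lat_max),
                 c(ci$lon_min, ci$lat_min))
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = as.list(ci[props]))
  })
  fc <- list(type = "FeatureCollection", features = features)
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname write_grid_geojson
#' @return `read_grid_geojson` returns a grid-cell data frame.
#' @export
read_grid_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  rows <- lapply(fc$features, function(f) {
    coords <- f$geometry$coordinates[[1]]
    lon <- vapply(coords, function(p) p[[1]], numeric(1))
    lat <- vapply(coords, function(p) p[[2]], numeric(1))
    cbind(data.frame(lat_min = min(lat), lat_max = max(lat),
                     lon_min = min(lon), lon_max = max(lon)),
          as.data.frame(f$properties, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  out[, c(GRID_COLUMNS, intersect("class", names(out)))]
}

#' Write / read reserves as GeoJSON
#'
#' FeatureCollection of Polygon features with properties
#' `name, status, efficiency`.
#'
#' @param reserves list of [reserve()] objects.
#' @param path GeoJSON file path.
#' @export
write_reserves_geojson <- function(reserves, path) {
  features <- lapply(reserves, function(r) {
    coords <- lapply(r$rings, function(ring) {
      ring <- rbind(ring, ring[1, ])  # close the ring
      lapply(seq_len(nrow(ring)), function(i) as.numeric(ring[i, ]))
    })
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = coords),
         properties = list(name = r$name, status = r$status,
                           efficiency = r$efficiency))
  })
  fc <- list(type = "FeatureCollection", features = features)
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname write_reserves_geojson
#' @return `read_reserves_geojson` returns a list of [reserve()] objects.
#' @export
read_reserves_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  lapply(fc$features, function(f) {
    rings <- lapply(f$geometry$coordinates, function(ring) {
      do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    })
    reserve(f$properties$name, rings, status = f$properties$status,
            efficiency = f$properties$efficiency)
  })
}

#' Serialize a fitted occurrence model to JSON
#'
#' Stores the spec, coefficient table, log-likelihood, AIC, deviances and
#' the sequential deviance-explained decomposition.
#'
#' @param fit a fitted [occurrence_model()].
#' @param path JSON file path.
#' @export
write_fitted_json <- function(fit, path) {
  de <- deviance_explained(fit)
  obj <- list(
    spec = list(lat = fit$spec$lat, depth = fit$spec$depth,
                habitat = fit$spec$habitat, label = format(fit$spec)),
    coefficients = list(term = names(fit$coefficients),
                        estimate = unname(fit$coefficients),
                        se = unname(fit$se)),
    loglik = fit$loglik, aic = fit$aic,
    null_deviance = fit$null_deviance, residual_deviance = fit$deviance,
    deviance_explained = list(group = de$group,
                              pct = de$pct_explained,
                              total_pct = attr(de, "total")),
    n = fit$n, centers = as.list(fit$centers), domain = fit$domain
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}
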