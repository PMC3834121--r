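#' Code a cell's habitat from intersecting bottom-mapping samples
#'
#' A one-arcminute cell is coded `"HB"` (hardbottom) if any intersecting
#' mapped datum is hardbottom, regardless of how many not-hardbottom data
#' also fall in the cell; `"NH"` if data exist and all are not-hardbottom;
#' and `"UN"` (unknown) if the cell was never sampled by the bottom-mapping
#' program.
#'
#' @param bottom_types character vector of raw bottom-type data intersecting
#'   one cell; allowed values are `"HB"` and `"NH"`. A zero-length vector
#'   means the cell is unsampled.
#' @return one of `"HB"`, `"NH"`, `"UN"`.
#' @examples
#' code_habitat(c("HB", "NH"))  # "HB"
#' code_habitat(character(0))   # "UN"
#' @export
code_habitat <- function(bottom_types) {
  bad <- setdiff(unique(bottom_types), BOTTOM_TYPES)
  if (length(bad))
    stop_validation("unknown bottom_type value(s): ", paste(bad, collapse = ", "))
  if (length(bottom_types) == 0L) return("UN")
  if (any(bottom_types == "HB")) "HB" else "NH"
}

#' Reclassify unknown cells as possible hardbottom by slope
#'
#' Cells with no bottom-mapping coverage (`"UN"`) are promoted to possible
#' hardbottom (`"PH"`) when their maximum percent slope exceeds a threshold
#' (default 1.45, the mean maximum slope of mapped hardbottom cells).
#' The comparison is strict; cells already coded `HB`, `PH` or `NH` are
#' never altered, and the operation is idempotent.
#'
#' @param cells grid-cell data frame with columns `habitat_code` and
#'   `max_slope_pct`.
#' @param slope_threshold percent slope above which an `UN` cell becomes
#'   `PH`; default `1.45`.
#' @return `cells` with updated `habitat_code`.
#' @export
reclassify_by_slope <- function(cells, slope_threshold = 1.45) {
  slope <- cells$max_slope_pct
  if (any(!is.finite(slope)) || any(slope < 0))
    stop_validation("max_slope_pct must be finite and non-negative")
  promote <- cells$habitat_code == "UN" & slope > slope_threshold
  cells$habitat_code[promote] <- "PH"
  cells
}

#' Assign a depth bin index
#'
#' Depth bins are half-open intervals `[k*w, (k+1)*w)` in fathoms, so a
#' depth on a bin boundary belongs to the deeper bin's lower edge (e.g.
#' 25 fm with 5-fm bins is bin 5, the interval \[25, 30)).
#'
#' @param depth_fm depth in fathoms (non-negative, vectorized).
#' @param bin_width bin width in fathoms; default 5.
#' @return integer bin indices `floor(depth_fm / bin_width)`.
#' @export
assign_depth_bin <- function(depth_fm, bin_width = 5) {
  if (any(!is.finite(depth_fm)) || any(depth_fm < 0))
    stop_validation("depth_fm must be finite and non-negative")
  assert_scalar_number(bin_width, "bin_width")
  if (bin_width <= 0) stop_validation("bin_width must be positive")
  as.integer(floor(depth_fm / bin_width))
}

#' Convert fathoms to meters
#'
#' Uses the international fathom, 1 fathom = 1.8288 m, so the 25-100 fathom
#' analysis band spans 45.7-182.9 m at one decimal.
#'
#' @param d depth in fathoms (vectorized).
#' @return depth in meters.
#' @export
fathoms_to_meters <- function(d) {
  if (any(!is.finite(d))) stop_validation("depth must be finite")
  d * METERS_PER_FATHOM
}

#' Spherical area of a latitude/longitude rectangle
#'
#' Area of the cell rectangle on a sphere of radius 6371.0088 km:
#' `R^2 * dlambda * (sin(phi2) - sin(phi1))` with angles in radians. At
#' one-arcminute scale and study latitudes this differs from a projected
#' (UTM) area by far less than 1 percent, and all protection metrics are
#' ratios of such areas.
#'
#' @param lat_min,lat_max,lon_min,lon_max rectangle bounds, degrees WGS84
#'   (vectorized).
#' @return area in square kilometres.
#' @export
compute_cell_area <- function(lat_min, lat_max, lon_min, lon_max) {
  if (any(lat_max <= lat_min) || any(lon_max <= lon_min))
    stop_validation("degenerate or inverted cell bounds")
  rad <- pi / 180
  EARTH_RADIUS_KM^2 * (lon_max - lon_min) * rad *
    (sin(lat_max * rad) - sin(lat_min * rad))
}

#' Restrict grid cells to the analysis depth band
#'
#' Keeps cells whose representative depth lies in the closed interval
#' `[min_fm, max_fm]` (default 25-100 fathoms, the shelf-edge band holding
#' most mature-fish observations). Order is preserved.
#'
#' @param cells grid-cell data frame with a `depth_fm` column.
#' @param min_fm,max_fm band limits in fathoms.
#' @return the retained rows of `cells`.
#' @export
filter_analysis_domain <- function(cells, min_fm = 25, max_fm = 100) {
  if (min_fm > max_fm) stop_validation("min_fm must not exceed max_fm")
  keep <- cells$depth_fm >= min_fm & cells$depth_fm <= max_fm
  cells[keep, , drop = FALSE]
}

#' Build a grid-cell data frame
#'
#' Assembles and validates the one-arcminute analysis grid container used
#' throughout the package: one row per cell with WGS84 bounds, representative
#' depth, 5-fathom depth bin, habitat code, maximum slope and spherical area.
#'
#' @param lat_min,lon_min lower-left corners of each cell, degrees.
#' @param depth_fm representative depth at the cell centroid, fathoms.
#' @param habitat_code habitat codes, in `c("HB","PH","NH","UN")`.
#' @param max_slope_pct maximum percent slope per cell.
#' @param cell_id optional identifiers; defaults to `cell_<row>`.
#' @param cell_size cell edge in degrees; default `1/60` (one arcminute).
#' @return a `data.frame` with one row per cell.
#' @export
make_grid_cells <- function(lat_min, lon_min, depth_fm, habitat_code,
                            max_slope_pct = 0,
                            cell_id = NULL, cell_size = 1 / 60) {
  n <- length(lat_min)
  bad <- setdiff(unique(habitat_code), HABITAT_CODES)
  if (length(bad))
    stop_validation("invalid habitat_code value(s): ", paste(bad, collapse = ", "))
  if (any(depth_fm < 0)) stop_validation("depth_fm must be non-negative")
  cell_id <- cell_id %||% sprintf("cell_%06d", seq_len(n))
  lat_max <- lat_min + cell_size
  lon_max <- lon_min + cell_size
  data.frame(
    cell_id = as.character(cell_id),
    lat_min = lat_min, lat_max = lat_max,
    lon_min = lon_min, lon_max = lon_max,
    depth_fm = depth_fm,
    depth_bin = assign_depth_bin(depth_fm),
    habitat_code = as.character(habitat_code),
    max_slope_pct = rep_len(max_slope_pct, n),
    area_km2 = compute_cell_area(lat_min, lat_max, lon_min, lon_max),
    stringsAsFactors = FALSE
  )
}
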