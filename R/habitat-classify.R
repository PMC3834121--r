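#' Four-way habitat suitability classification of one depth-grid cell
#'
#' Applies the rule-based habitat classification, in strict precedence:
#' \enumerate{
#'   \item \strong{Known} — the species was detected in the cell by any
#'     source other than the headboat logbook.
#'   \item \strong{Probable} — a headboat detection fell in the cell, or the
#'     cell's habitat code is hardbottom (`HB`) or possible hardbottom (`PH`).
#'   \item \strong{NotSuitable} — habitat is not-hardbottom (`NH`), more than
#'     5 samples were taken, and no detection of any kind occurred.
#'   \item \strong{Unknown} — otherwise (fewer negative samples than the
#'     evidence threshold and no identified habitat).
#' }
#' Headboat detections are down-weighted to Probable, never Known, because
#' of their coarse self-reported positions. Any detection blocks
#' NotSuitable. Exactly 5 negative samples on `NH` habitat falls through to
#' Unknown (the evidence threshold is strict).
#'
#' @param n_samples number of effort-bearing sampling events in the cell.
#' @param n_detect_reliable detections from sources other than the headboat
#'   survey.
#' @param n_detect_hbs headboat-survey detections.
#' @param habitat_code the cell's habitat code, one of `"HB","PH","NH","UN"`.
#' @return one of `"Known"`, `"Probable"`, `"NotSuitable"`, `"Unknown"`.
#' @export
classify_cell <- function(n_samples, n_detect_reliable, n_detect_hbs,
                          habitat_code) {
  if (!habitat_code %in% HABITAT_CODES)
    stop_validation("invalid habitat code: ", habitat_code)
  if (min(n_samples, n_detect_reliable, n_detect_hbs) < 0)
    stop_validation("counts must be non-negative")
  if (n_detect_reliable > 0) return("Known")
  if (n_detect_hbs > 0 || habitat_code %in% c("HB", "PH")) return("Probable")
  if (habitat_code == "NH" && n_samples > 5) return("NotSuitable")
  "Unknown"
}

#' Summarize per-cell observations for classification
#'
#' Collapses an observation table to the per-cell counts the classifier
#' consumes. Sampling events are matched to cells by point-in-rectangle
#' containment. Only effort-bearing sources (every gear except the headboat
#' logbook, which lacks reliable per-cell effort) contribute to `n_samples`;
#' headboat rows contribute detections only.
#'
#' @param cells grid-cell data frame (see [make_grid_cells()]).
#' @param observations observation data frame with columns `gear`, `lat`,
#'   `lon`, `detected` (see [read_observations()]).
#' @return data frame with columns `cell_id`, `n_samples`,
#'   `n_detect_reliable`, `n_detect_hbs`.
#' @export
summarize_cell_observations <- function(cells, observations) {
  n <- nrow(cells)
  out <- data.frame(cell_id = cells$cell_id,
                    n_samples = integer(n),
                    n_detect_reliable = integer(n),
                    n_detect_hbs = integer(n),
                    stringsAsFactors = FALSE)
  if (nrow(observations) == 0L) return(out)
  idx <- locate_cells(cells, observations$lat, observations$lon)
  inside <- !is.na(idx)
  idx <- idx[inside]
  gear <- observations$gear[inside]
  det <- observations$detected[inside]
  hbs <- gear == "HBS"
  add_counts <- function(which_rows) {
    tab <- tabulate(idx[which_rows], nbins = n)
    tab
  }
  out$n_samples <- add_counts(!hbs)
  out$n_detect_reliable <- add_counts(!hbs & det == 1)
  out$n_detect_hbs <- add_counts(hbs & det == 1)
  out
}

# Row index of the cell containing each point (NA if outside all cells).
# Assumes a regular grid: every cell edge is an integer number of cell
# widths from the grid origin, which holds for all grids this package
# builds. Cell membership is half-open [min, max).
locate_cells <- function(cells, lat, lon) {
  lat0 <- min(cells$lat_min)
  lon0 <- min(cells$lon_min)
  w <- cells$lat_max[1] - cells$lat_min[1]
  key_of <- function(la, lo) paste(floor((la - lat0) / w + 1e-9),
                                   floor((lo - lon0) / w + 1e-9))
  idx <- match(key_of(lat, lon), key_of(cells$lat_min, cells$lon_min))
  idx[lat < lat0 | lon < lon0] <- NA_integer_
  idx
}

#' Classify every cell of a grid
#'
#' Runs [classify_cell()] over the grid given an observation table.
#'
#' @inheritParams summarize_cell_observations
#' @return `cells` with an added `class` column.
#' @export
classify_grid <- function(cells, observations) {
  s <- summarize_cell_observations(cells, observations)
  cells$class <- vapply(seq_len(nrow(cells)), function(i) {
    classify_cell(s$n_samples[i], s$n_detect_reliable[i], s$n_detect_hbs[i],
                  cells$habitat_code[i])
  }, character(1))
  cells
}

#' Total area and domain fraction per habitat class
#'
#' @param cells classified grid-cell data frame (with `class` and
#'   `area_km2` columns); each cell must appear once.
#' @return data frame with one row per class (`Known`, `Probable`,
#'   `NotSuitable`, `Unknown`): total `area_km2` and `fraction` of the
#'   summed domain area. Fractions sum to 1.
#' @export
summarize_area_by_class <- function(cells) {
  if (anyDuplicated(cells$cell_id))
    stop_validation("duplicate cell_id in classified cells")
  classes <- c("Known", "Probable", "NotSuitable", "Unknown")
  area <- vapply(classes, function(cl) sum(cells$area_km2[cells$class == cl]),
                 numeric(1))
  data.frame(class = classes,
             area_km2 = unname(area),
             fraction = unname(area) / sum(cells$area_km2),
             stringsAsFactors = FALSE)
}
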