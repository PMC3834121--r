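#' Construct a marine reserve
#'
#' A reserve is a named closed polygon (one or more rings of WGS84
#' vertices) with a status and a bycatch-elimination efficiency weight.
#' Fully no-take areas have efficiency 1; areas whose protection comes
#' from a no-anchoring provision (CHAPC-type) are conventionally assigned
#' efficiency 0.5.
#'
#' @param name reserve label.
#' @param rings a two-column matrix (lon, lat) of polygon vertices, or a
#'   list of such matrices for multi-ring reserves. Rings need not repeat
#'   the first vertex.
#' @param status `"existing"` or `"proposed"`.
#' @param efficiency weight in \[0, 1\]; default 1.
#' @return an object of class `"reserve"`.
#' @export
reserve <- function(name, rings, status = c("existing", "proposed"),
                    efficiency = 1) {
  status <- match.arg(status)
  if (!is.numeric(efficiency) || efficiency < 0 || efficiency > 1)
    stop_validation("efficiency must lie in [0, 1]")
  if (is.matrix(rings)) rings <- list(rings)
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    if (ncol(r) != 2L || nrow(r) < 3L)
      stop_validation("each ring needs >= 3 (lon, lat) vertices")
    # drop a repeated closing vertex
    if (all(r[1, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
    if (nrow(r) < 3L) stop_validation("degenerate ring in reserve ", name)
    if (ring_self_intersects(r))
      stop_validation("self-intersecting ring in reserve ", name)
    r
  })
  structure(list(name = name, rings = rings, status = status,
                 efficiency = efficiency),
            class = "reserve")
}

#' @export
print.reserve <- function(x, ...) {
  cat(sprintf("reserve '%s' (%s, efficiency %.2f, %d ring(s))\n",
              x$name, x$status, x$efficiency, length(x$rings)))
  invisible(x)
}

# O(n^2) proper-crossing check; reserves have few vertices.
ring_self_intersects <- function(r) {
  n <- nrow(r)
  seg <- cbind(r, r[c(2:n, 1), , drop = FALSE])
  cross <- function(a, b, c)
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent via wraparound
      a <- seg[i, 1:2]; b <- seg[i, 3:4]; c <- seg[j, 1:2]; d <- seg[j, 3:4]
      if (cross(a, b, c) * cross(a, b, d) < 0 &&
          cross(c, d, a) * cross(c, d, b) < 0) return(TRUE)
    }
  }
  FALSE
}

# Sutherland-Hodgman clip of a polygon (matrix of x,y vertices) against an
# axis-aligned rectangle; returns the clipped vertex matrix (possibly 0 rows).
clip_polygon_rect <- function(poly, xmin, xmax, ymin, ymax) {
  clip_edge <- function(pts, inside, intersect) {
    n <- nrow(pts)
    if (n == 0L) return(pts)
    out <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(n)) {
      cur <- pts[i, ]
      prev <- pts[if (i == 1) n else i - 1, ]
      cur_in <- inside(cur)
      prev_in <- inside(prev)
      if (cur_in) {
        if (!prev_in) out <- rbind(out, intersect(prev, cur))
        out <- rbind(out, cur)
      } else if (prev_in) {
        out <- rbind(out, intersect(prev, cur))
      }
    }
    out
  }
  ix <- function(p, q, val, coord) {
    t <- (val - p[coord]) / (q[coord] - p[coord])
    p + t * (q - p)
  }
  poly <- clip_edge(poly, function(p) p[1] >= xmin,
                    function(p, q) ix(p, q, xmin, 1))
  poly <- clip_edge(poly, function(p) p[1] <= xmax,
                    function(p, q) ix(p, q, xmax, 1))
  poly <- clip_edge(poly, function(p) p[2] >= ymin,
                    function(p, q) ix(p, q, ymin, 2))
  poly <- clip_edge(poly, function(p) p[2] <= ymax,
                    function(p, q) ix(p, q, ymax, 2))
  poly
}

shoelace_area <- function(pts) {
  n <- nrow(pts)
  if (is.null(n) || n < 3L) return(0)
  x <- pts[, 1]; y <- pts[, 2]
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Fraction of a grid cell covered by a reserve
#'
#' Clips each reserve ring against the cell rectangle and returns the
#' intersection area divided by the cell area. Geometry is evaluated in a
#' local equal-area approximation: longitudes are scaled by the cosine of
#' the cell's centroid latitude, which is accurate to well under a percent
#' at one-arcminute scale. Multi-ring intersections are summed (rings are
#' assumed disjoint) and capped at 1.
#'
#' @param cell one row of a grid-cell data frame.
#' @param res a [reserve()].
#' @return overlap fraction in \[0, 1\].
#' @export
cell_reserve_overlap <- function(cell, res) {
  if (!inherits(res, "reserve")) stop_validation("res must be a reserve")
  lat0 <- (cell$lat_min + cell$lat_max) / 2
  sc <- cos(lat0 * pi / 180)
  # work in cell-local coordinates to avoid cancellation at degree scale
  cell_a <- (cell$lon_max - cell$lon_min) * sc * (cell$lat_max - cell$lat_min)
  inter <- sum(vapply(res$rings, function(r) {
    local <- cbind((r[, 1] - cell$lon_min) * sc, r[, 2] - cell$lat_min)
    shoelace_area(clip_polygon_rect(local,
                                    0, (cell$lon_max - cell$lon_min) * sc,
                                    0, cell$lat_max - cell$lat_min))
  }, numeric(1)))
  min(1, inter / cell_a)
}

# Overlap fractions of every cell with one reserve, with a cheap bounding
# box pre-filter.
overlap_fractions <- function(cells, res) {
  bb <- apply(do.call(rbind, res$rings), 2, range)
  cand <- which(cells$lon_max >= bb[1, 1] & cells$lon_min <= bb[2, 1] &
                  cells$lat_max >= bb[1, 2] & cells$lat_min <= bb[2, 2])
  frac <- numeric(nrow(cells))
  for (i in cand)
    frac[i] <- cell_reserve_overlap(cells[i, , drop = FALSE], res)
  frac
}

#' Percent of a habitat class' area covered by a reserve
#'
#' Area of the selected habitat class(es) inside the reserve, as a percent
#' of the jurisdiction-wide (all supplied cells) area of those classes.
#'
#' @param cells classified grid-cell data frame (`class`, `area_km2`
#'   columns), already clipped to the analysis depth band.
#' @param res a [reserve()].
#' @param class_set habitat classes to count, e.g. `"Known"` or
#'   `c("Known", "Probable")`.
#' @return percent in \[0, 100\]. If the jurisdiction holds no area of the
#'   requested classes the metric is undefined and an error of class
#'   `"reefsdm_not_evaluable"` is raised (reported downstream as
#'   "Not eval." rather than a silent zero).
#' @export
habitat_protection_pct <- function(cells, res, class_set = "Known") {
  sel <- cells$class %in% class_set
  total <- sum(cells$area_km2[sel])
  if (total <= 0)
    stop_not_evaluable("no jurisdiction area in class(es) ",
                       paste(class_set, collapse = ", "))
  frac <- overlap_fractions(cells, res)
  100 * sum(cells$area_km2[sel] * frac[sel]) / total
}

#' Percent of stock protected by a reserve
#'
#' Area-weighted detection probability inside the reserve as a percent of
#' the jurisdiction-wide area-weighted detection probability, scaled by
#' the reserve's efficiency weight. Because the metric is a ratio, it is
#' invariant to uniform rescaling of all probabilities, so it can be read
#' as a percent of relative abundance.
#'
#' @param surface data frame `cell_id`, `p` from [predict_surface()].
#' @param cells grid-cell data frame aligned with `surface` by `cell_id`.
#' @param res a [reserve()].
#' @param apply_efficiency multiply by `res$efficiency` (default `TRUE`).
#' @return percent in \[0, 100\].
#' @export
stock_protection_pct <- function(surface, cells, res,
                                 apply_efficiency = TRUE) {
  p <- surface$p[match(cells$cell_id, surface$cell_id)]
  if (any(is.na(p)))
    stop_validation("surface is missing probabilities for some cells")
  if (any(p <= 0 | p >= 1))
    stop_validation("probabilities must lie strictly in (0, 1)")
  total <- sum(p * cells$area_km2)
  frac <- overlap_fractions(cells, res)
  eff <- if (apply_efficiency) res$efficiency else 1
  100 * eff * sum(p * cells$area_km2 * frac) / total
}

#' Protection per unit area
#'
#' Divides a protection percentage by the reserve's area, giving the
#' conservation benefit per square kilometre closed — the efficiency axis
#' used to compare reserves of very different sizes.
#'
#' @param pct a protection percentage.
#' @param area_km2 reserve area (> 0).
#' @return percent per square kilometre.
#' @export
per_area_efficiency <- function(pct, area_km2) {
  if (any(area_km2 <= 0)) stop_validation("reserve area must be positive")
  pct / area_km2
}

#' Reserve area inside the analysis cells
#'
#' @param cells grid-cell data frame (the clipped analysis domain).
#' @param res a [reserve()].
#' @return area in square kilometres of the reserve's intersection with
#'   the supplied cells.
#' @export
reserve_area_km2 <- function(cells, res) {
  sum(cells$area_km2 * overlap_fractions(cells, res))
}

#' Aggregate protection over a set of reserves
#'
#' Computes jurisdiction-wide totals at the cell level: each cell's
#' protected fraction is `min(1, sum of overlaps)` across the selected
#' reserves, so overlapping reserves are never double-counted, and the
#' efficiency applied to a cell is the maximum efficiency among the
#' reserves covering it.
#'
#' @param reserves list of [reserve()] objects.
#' @param cells classified grid-cell data frame.
#' @param surface optional probability surface (for the stock metric).
#' @param mode which reserves to include: `"all"`, `"existing"` or
#'   `"proposed"`.
#' @return list with `area_km2` (protected area), `pct_known`,
#'   `pct_known_probable` (or `NA` where not evaluable) and `pct_stock`
#'   (`NULL` without a surface).
#' @export
aggregate_reserves <- function(reserves, cells, surface = NULL,
                               mode = c("all", "existing", "proposed")) {
  mode <- match.arg(mode)
  if (mode != "all")
    reserves <- Filter(function(r) r$status == mode, reserves)
  n <- nrow(cells)
  cover <- numeric(n)
  eff <- numeric(n)
  for (r in reserves) {
    frac <- overlap_fractions(cells, r)
    cover <- pmin(1, cover + frac)
    eff <- ifelse(frac > 0, pmax(eff, r$efficiency), eff)
  }
  class_pct <- function(class_set) {
    sel <- cells$class %in% class_set
    total <- sum(cells$area_km2[sel])
    if (total <= 0) return(NA_real_)
    100 * sum(cells$area_km2[sel] * cover[sel]) / total
  }
  out <- list(area_km2 = sum(cells$area_km2 * cover),
              pct_known = class_pct("Known"),
              pct_known_probable = class_pct(c("Known", "Probable")))
  if (!is.null(surface)) {
    p <- surface$p[match(cells$cell_id, surface$cell_id)]
    out$pct_stock <- 100 * sum(p * cells$area_km2 * cover * eff) /
      sum(p * cells$area_km2)
  }
  out
}

#' Per-reserve protection report
#'
#' One row per reserve with its clipped area, percent of Known habitat,
#' percent of Known & Probable habitat, percent of stock under each
#' supplied probability surface, and protection per unit area. Metrics
#' whose jurisdiction-wide denominator is empty are reported `NA`
#' ("not evaluable"), never silently zero.
#'
#' @param reserves list of [reserve()] objects.
#' @param cells classified grid-cell data frame, clipped to the analysis
#'   band.
#' @param surfaces named list of probability surfaces (e.g.
#'   `list(xval = ..., aic = ...)`); percent-of-stock columns are emitted
#'   per surface as `pct_stock_<name>`.
#' @param surface_cells cells over which the surfaces are defined; default
#'   `cells`. A species whose model covers only part of the habitat
#'   jurisdiction (e.g. a latitude-restricted domain) uses the restricted
#'   set here: a reserve lying wholly outside it gets `NA` stock metrics.
#' @return data frame, one row per reserve.
#' @export
protection_report <- function(reserves, cells, surfaces = list(),
                              surface_cells = cells) {
  safe_pct <- function(expr) tryCatch(expr, reefsdm_not_evaluable =
                                        function(e) NA_real_)
  rows <- lapply(reserves, function(r) {
    area <- reserve_area_km2(cells, r)
    row <- data.frame(name = r$name, status = r$status,
                      efficiency = r$efficiency, area_km2 = area,
                      pct_known = safe_pct(
                        habitat_protection_pct(cells, r, "Known")),
                      pct_known_probable = safe_pct(
                        habitat_protection_pct(cells, r,
                                               c("Known", "Probable"))),
                      stringsAsFactors = FALSE)
    in_surface <- reserve_area_km2(surface_cells, r)
    for (nm in names(surfaces)) {
      pct <- if (area > 0 && in_surface == 0) NA_real_
             else stock_protection_pct(surfaces[[nm]], surface_cells, r)
      row[[paste0("pct_stock_", nm)]] <- pct
      row[[paste0("per_area_", nm)]] <-
        if (area > 0) per_area_efficiency(pct, area) else NA_real_
    }
    row
  })
  do.call(rbind, rows)
}
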