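# Cell-enumeration oracle for aggregate metrics: computes each metric by
# explicit per-cell union of rectangle intersections (closed form for
# axis-aligned rectangles, no polygon clipping involved).
rect_overlap_frac <- function(cell, lon0, lon1, lat0, lat1) {
  dx <- max(0, min(cell$lon_max, lon1) - max(cell$lon_min, lon0))
  dy <- max(0, min(cell$lat_max, lat1) - max(cell$lat_min, lat0))
  (dx * dy) / ((cell$lon_max - cell$lon_min) * (cell$lat_max - cell$lat_min))
}

test_that("cell/reserve overlap matches closed-form rectangle intersection", {
  cells <- toy_cells(3, 3, depth_fm = 50)
  w <- 1 / 60
  c1 <- cells[1, ]
  # containment
  big <- rect_reserve("big", c1$lon_min - w, c1$lat_min - w, 3 * w, 3 * w)
  expect_equal(cell_reserve_overlap(c1, big), 1)
  # disjoint
  far <- rect_reserve("far", c1$lon_min + 10, c1$lat_min, w, w)
  expect_equal(cell_reserve_overlap(c1, far), 0)
  # exactly the western half of the cell
  half <- rect_reserve("half", c1$lon_min, c1$lat_min - w, w / 2, 3 * w)
  expect_equal(cell_reserve_overlap(c1, half), 0.5, tolerance = 1e-9)
  # random rectangles against the closed-form oracle
  set.seed(42)
  for (i in 1:50) {
    lon0 <- c1$lon_min + runif(1, -w, w)
    lat0 <- c1$lat_min + runif(1, -w, w)
    dw <- runif(1, w / 4, 2 * w)
    dh <- runif(1, w / 4, 2 * w)
    r <- rect_reserve("r", lon0, lat0, dw, dh)
    expect_equal(cell_reserve_overlap(c1, r),
                 rect_overlap_frac(c1, lon0, lon0 + dw, lat0, lat0 + dh),
                 tolerance = 1e-9)
  }
})

test_that("reserve construction validates geometry and efficiency", {
  expect_error(reserve("bad", matrix(c(0, 0, 1, 1), 2, 2)),
               class = "reefsdm_validation_error")
  expect_error(rect_reserve("bad", 0, 0, 1, 1, efficiency = 1.5),
               class = "reefsdm_validation_error")
  bow <- cbind(lon = c(0, 1, 0, 1), lat = c(0, 1, 1, 0))
  expect_error(reserve("bowtie", bow), "self-intersecting",
               class = "reefsdm_validation_error")
  # closing vertex may be repeated
  ring <- cbind(lon = c(0, 1, 1, 0, 0), lat = c(0, 0, 1, 1, 0))
  expect_length(reserve("ok", ring)$rings[[1]][, 1], 4)
})

test_that("habitat protection percentages are ratios of class areas", {
  cells <- toy_cells(2, 5, depth_fm = 50)
  cells$class <- rep(c("Known", "Unknown"), 5)
  w <- 1 / 60
  # reserve covering the first two columns (4 cells, 2 Known)
  r <- rect_reserve("r", min(cells$lon_min), min(cells$lat_min),
                    2 * w, 2 * w)
  expect_equal(habitat_protection_pct(cells, r, "Known"),
               100 * 2 / 5, tolerance = 1e-9)
  whole <- rect_reserve("all", min(cells$lon_min) - w,
                        min(cells$lat_min) - w, 10 * w, 10 * w)
  expect_equal(habitat_protection_pct(cells, whole, "Known"), 100)
  far <- rect_reserve("far", 0, 0, w, w)
  expect_equal(habitat_protection_pct(cells, far, "Known"), 0)
  expect_error(habitat_protection_pct(cells, r, "NotSuitable"),
               class = "reefsdm_not_evaluable")
})

test_that("stock protection is the efficiency-weighted p-area ratio", {
  cells <- toy_cells(1, 3, depth_fm = 50)
  cells$area_km2 <- c(1, 1, 5)
  surface <- data.frame(cell_id = cells$cell_id, p = c(0.4, 0.3, 0.5))
  w <- 1 / 60
  r1 <- rect_reserve("first", cells$lon_min[1], cells$lat_min[1], w, w)
  expect_equal(stock_protection_pct(surface, cells, r1), 12.5,
               tolerance = 1e-9)
  r_half <- rect_reserve("chapc", cells$lon_min[1], cells$lat_min[1],
                         w, w, efficiency = 0.5)
  expect_equal(stock_protection_pct(surface, cells, r_half), 6.25,
               tolerance = 1e-9)
  whole <- rect_reserve("all", min(cells$lon_min) - w,
                        min(cells$lat_min) - w, 5 * w, 3 * w)
  expect_equal(stock_protection_pct(surface, cells, whole), 100,
               tolerance = 1e-9)
  # invariance to uniform probability rescaling
  half_p <- surface
  half_p$p <- surface$p / 2
  expect_equal(stock_protection_pct(half_p, cells, r1),
               stock_protection_pct(surface, cells, r1), tolerance = 1e-9)
  bad <- surface
  bad$p[1] <- 1.2
  expect_error(stock_protection_pct(bad, cells, r1),
               class = "reefsdm_validation_error")
})

test_that("per-area efficiency scales as a simple ratio", {
  expect_equal(per_area_efficiency(12.5, 25), 0.5)
  expect_equal(per_area_efficiency(10, 50), per_area_efficiency(10, 25) / 2)
  expect_equal(per_area_efficiency(0, 25), 0)
  expect_error(per_area_efficiency(5, 0), class = "reefsdm_validation_error")
})

test_that("aggregation unions overlaps at the cell level", {
  cells <- toy_cells(4, 5, depth_fm = 50)
  cells$class <- rep(c("Known", "Probable", "Unknown", "NotSuitable"), 5)
  set.seed(7)
  surface <- data.frame(cell_id = cells$cell_id,
                        p = runif(nrow(cells), 0.05, 0.6))
  w <- 1 / 60
  rA <- rect_reserve("A", min(cells$lon_min), min(cells$lat_min),
                     2.5 * w, 2.5 * w)
  rB <- rect_reserve("B", min(cells$lon_min) + 1.5 * w,
                     min(cells$lat_min) + 1.5 * w, 2 * w, 2 * w,
                     status = "proposed")
  rC <- rect_reserve("C", min(cells$lon_min) + 4 * w,
                     min(cells$lat_min), w, 4 * w, status = "proposed")

  # identical overlapping reserves behave idempotently (cell-aligned
  # geometry, where the capped cell-level union is exact)
  rAl <- rect_reserve("Al", min(cells$lon_min), min(cells$lat_min),
                      2 * w, 2 * w)
  agg1 <- aggregate_reserves(list(rAl), cells, surface)
  agg2 <- aggregate_reserves(list(rAl, rAl), cells, surface)
  expect_equal(agg2$pct_stock, agg1$pct_stock, tolerance = 1e-9)
  expect_equal(agg2$area_km2, agg1$area_km2, tolerance = 1e-9)

  # disjoint reserves add
  aggA <- aggregate_reserves(list(rA), cells, surface)
  aggC <- aggregate_reserves(list(rC), cells, surface)
  aggAC <- aggregate_reserves(list(rA, rC), cells, surface)
  expect_equal(aggAC$pct_stock, aggA$pct_stock + aggC$pct_stock,
               tolerance = 1e-9)

  # partial overlap: union below the sum, above each part, and equal to
  # the brute-force cell-level union oracle
  aggB <- aggregate_reserves(list(rB), cells, surface)
  aggAB <- aggregate_reserves(list(rA, rB), cells, surface)
  expect_lt(aggAB$pct_stock, aggA$pct_stock + aggB$pct_stock)
  expect_gte(aggAB$pct_stock, max(aggA$pct_stock, aggB$pct_stock))
  fr <- function(r, i) rect_overlap_frac(cells[i, ],
                                         min(r$rings[[1]][, 1]),
                                         max(r$rings[[1]][, 1]),
                                         min(r$rings[[1]][, 2]),
                                         max(r$rings[[1]][, 2]))
  cover <- vapply(seq_len(nrow(cells)),
                  function(i) min(1, fr(rA, i) + fr(rB, i)), numeric(1))
  oracle <- 100 * sum(surface$p * cells$area_km2 * cover) /
    sum(surface$p * cells$area_km2)
  expect_equal(aggAB$pct_stock, oracle, tolerance = 1e-9)

  # adding a reserve never decreases any aggregate (union monotonicity)
  expect_gte(aggAB$area_km2, aggA$area_km2)
  expect_gte(aggAB$pct_known, aggA$pct_known)
  # mode filtering
  agg_ex <- aggregate_reserves(list(rA, rB, rC), cells, surface,
                               mode = "existing")
  expect_equal(agg_ex$pct_stock, aggA$pct_stock, tolerance = 1e-9)
})

test_that("maximum efficiency applies per covered cell in aggregates", {
  cells <- toy_cells(1, 2, depth_fm = 50)
  surface <- data.frame(cell_id = cells$cell_id, p = c(0.2, 0.2))
  w <- 1 / 60
  full <- rect_reserve("full", cells$lon_min[1], cells$lat_min[1], w, w,
                       efficiency = 1)
  weak <- rect_reserve("weak", cells$lon_min[1], cells$lat_min[1], w, w,
                       efficiency = 0.5, status = "proposed")
  both <- aggregate_reserves(list(full, weak), cells, surface)
  expect_equal(both$pct_stock, 50, tolerance = 1e-9)  # max(1, 0.5) on cell 1
  alone <- aggregate_reserves(list(weak), cells, surface)
  expect_equal(alone$pct_stock, 25, tolerance = 1e-9)
})

test_that("protection report flags not-evaluable metrics as NA", {
  cells <- toy_cells(2, 2, depth_fm = 50)
  cells$class <- c("Probable", "Probable", "Unknown", "Unknown")
  surface <- data.frame(cell_id = cells$cell_id, p = rep(0.3, 4))
  w <- 1 / 60
  r <- rect_reserve("r", cells$lon_min[1], cells$lat_min[1], w, w)
  rep_df <- protection_report(list(r), cells, list(xval = surface))
  expect_true(is.na(rep_df$pct_known))           # no Known cells anywhere
  expect_false(is.na(rep_df$pct_known_probable))
  expect_true(rep_df$pct_stock_xval >= 0 && rep_df$pct_stock_xval <= 100)
  expect_equal(rep_df$per_area_xval,
               rep_df$pct_stock_xval / rep_df$area_km2)
  # reserve wholly outside the surface's restricted domain: stock is NA
  rep2 <- protection_report(list(r), cells, list(xval = surface[3:4, ]),
                            surface_cells = cells[3:4, ])
  expect_true(is.na(rep2$pct_stock_xval))
})
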