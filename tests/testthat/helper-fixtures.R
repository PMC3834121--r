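# Shared fixture builders. Everything is generated in code; nothing is
# read from disk.

# A small rectangular toy grid with arcminute-aligned cells and constant
# depth inside the analysis band. lat0/lon0 are south-west corners in
# arcminutes for exact alignment.
toy_cells <- function(n_lat = 4, n_lon = 5, lat0_min = 1800, lon0_min = -4800,
                      depth_fm = 50, habitat_code = "HB") {
  ix <- rep(seq_len(n_lat), times = n_lon)
  jx <- rep(seq_len(n_lon), each = n_lat)
  make_grid_cells(lat_min = (lat0_min + ix - 1) / 60,
                  lon_min = (lon0_min + jx - 1) / 60,
                  depth_fm = rep_len(depth_fm, n_lat * n_lon),
                  habitat_code = rep_len(habitat_code, n_lat * n_lon))
}

# Rectangle reserve helper (lon/lat of SW corner plus width/height in deg).
rect_reserve <- function(name, lon, lat, w, h, status = "existing",
                         efficiency = 1) {
  reserve(name,
          cbind(lon = c(lon, lon + w, lon + w, lon),
                lat = c(lat, lat, lat + h, lat + h)),
          status = status, efficiency = efficiency)
}

# A reduced-size synthetic dataset for unit tests (shared across files via
# a cache so the suite stays fast).
.fixture_cache <- new.env(parent = emptyenv())

small_dataset <- function(seed = 7) {
  key <- paste0("ds", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- synthetic_dataset(
      seed = seed, n_lat_cells = 120, n_lon_cells = 40, n_events = 4000)
  }
  .fixture_cache[[key]]
}

# Independent rule-table oracle for the habitat classifier: evaluates the
# four class definitions as plain predicates (no precedence chain shared
# with the implementation).
classify_oracle <- function(n_samples, rel, hbs, code) {
  known <- rel > 0
  probable <- !known & (hbs > 0 | code %in% c("HB", "PH"))
  notsuit <- !known & !probable & code == "NH" & n_samples > 5 &
    rel == 0 & hbs == 0
  if (known) "Known" else if (probable) "Probable"
  else if (notsuit) "NotSuitable" else "Unknown"
}

# Brute-force threshold oracle: scan every candidate midpoint threshold
# and count the contingency table directly.
brute_best_threshold <- function(scores, labels) {
  u <- sort(unique(scores))
  thr <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  best <- -Inf
  best_t <- thr[1]
  for (t in thr) {
    pred <- as.numeric(scores >= t)
    tpr <- sum(pred == 1 & labels == 1) / sum(labels == 1)
    tnr <- sum(pred == 0 & labels == 0) / sum(labels == 0)
    if (tpr + tnr > best + 1e-12) {
      best <- tpr + tnr
      best_t <- t
    }
  }
  list(threshold = best_t, sum = best)
}
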