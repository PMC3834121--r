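# Internal validation helpers shared across modules.

HABITAT_CODES <- c("HB", "PH", "NH", "UN")
BOTTOM_TYPES <- c("HB", "NH")
GEAR_LEVELS <- c("MARMAP", "HBS", "FRG", "SEFIS-trap", "SEFIS-video",
                 "Oculina-ROV", "DW-ROV", "RFOP", "REEF")
REFERENCE_GEAR <- "DW-ROV"
EARTH_RADIUS_KM <- 6371.0088
METERS_PER_FATHOM <- 1.8288

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("reefsdm_validation_error", "error")))
}

stop_not_evaluable <- function(...) {
  stop(errorCondition(paste0(...), class = c("reefsdm_not_evaluable", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stop_validation(name, " must be a single finite number")
  invisible(x)
}

# Deterministic child seed: keeps derived seeds in 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 69069 + offset) %% .Machine$integer.max)
}

config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"), tf)
  unname(tools::md5sum(tf))
}
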