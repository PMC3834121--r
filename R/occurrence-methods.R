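#' @export
print.occurrence_model <- function(x, ...) {
  cat("Logit-link occurrence model (", format(x$spec), ")\n", sep = "")
  cat(sprintf("  events: %d   detections: %d (%.2f%%)\n", x$n,
              sum(x$data$detected), 100 * mean(x$data$detected)))
  cat(sprintf("  logLik: %.2f   AIC: %.2f   deviance: %.2f (null %.2f)\n",
              x$loglik, x$aic, x$deviance, x$null_deviance))
  cat("  coefficients:\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.occurrence_model <- function(object, ...) object$coefficients

#' @export
logLik.occurrence_model <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$n,
            class = "logLik")
}

#' @export
deviance.occurrence_model <- function(object, ...) object$deviance

#' @export
nobs.occurrence_model <- function(object, ...) object$n

#' @export
summary.occurrence_model <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients,
               `Std. Error` = object$se,
               `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(spec = object$spec, coefficients = tab, aic = object$aic,
                 deviance = object$deviance,
                 null_deviance = object$null_deviance,
                 pct_explained = 100 * (object$null_deviance -
                                          object$deviance) /
                   object$null_deviance,
                 n = object$n),
            class = "summary.occurrence_model")
}

#' @export
print.summary.occurrence_model <- function(x, ...) {
  cat("Occurrence model:", format(x$spec), "\n\n")
  stats::printCoefmat(x$coefficients, digits = 4, signif.stars = FALSE)
  cat(sprintf("\nNull deviance: %.2f   Residual deviance: %.2f\n",
              x$null_deviance, x$deviance))
  cat(sprintf("Deviance explained: %.1f%%   AIC: %.2f   n = %d\n",
              x$pct_explained, x$aic, x$n))
  invisible(x)
}

#' Predict detection probability from a fitted occurrence model
#'
#' Evaluates the inverse-logit of the linear predictor for new covariate
#' values, with the gear (catchability) effect fixed at a standardization
#' gear, so that surfaces over space are comparable across sampling
#' methods. Covariates outside the fitted domain raise an error rather
#' than silently extrapolating.
#'
#' @param object a fitted [occurrence_model()].
#' @param newdata data frame with columns `lat`, `depth_fm`,
#'   `habitat_code` (and optionally `gear`, which overrides `gear`).
#' @param gear standardization gear used for every row lacking an explicit
#'   gear; default the reference level `"DW-ROV"`.
#' @param type `"response"` (probability) or `"link"` (logit).
#' @param check_domain if `TRUE` (default), error when `lat` or `depth_fm`
#'   falls outside the fitted domain.
#' @param ... unused.
#' @return numeric vector of probabilities in (0, 1) (or logits).
#' @export
predict.occurrence_model <- function(object, newdata,
                                     gear = REFERENCE_GEAR,
                                     type = c("response", "link"),
                                     check_domain = TRUE, ...) {
  type <- match.arg(type)
  if (missing(newdata)) {
    eta <- stats::qlogis(object$fitted)
    return(if (type == "response") object$fitted else eta)
  }
  if (!gear %in% GEAR_LEVELS)
    stop_validation("unknown standardization gear: ", gear)
  if (check_domain) {
    d <- object$domain
    out_lat <- newdata$lat < d$lat[1] | newdata$lat > d$lat[2]
    out_dep <- newdata$depth_fm < d$depth_fm[1] |
      newdata$depth_fm > d$depth_fm[2]
    if (any(out_lat | out_dep))
      stop_validation(sum(out_lat | out_dep),
                      " row(s) outside the fitted domain (lat ",
                      d$lat[1], "-", d$lat[2], " degN, depth ",
                      d$depth_fm[1], "-", d$depth_fm[2], " fm)")
  }
  if (is.null(newdata$gear)) newdata$gear <- gear
  dm <- build_design_matrix(newdata, object$spec, object$centers,
                            levels = object$levels)
  eta <- drop(dm$X %*% object$coefficients)
  if (type == "response") stats::plogis(eta) else eta
}

#' Single-point detection probability
#'
#' Convenience scalar/vector form of [predict.occurrence_model()].
#'
#' @inheritParams predict.occurrence_model
#' @param lat,depth_fm,habitat_code covariate values.
#' @return detection probabilities in (0, 1).
#' @export
predict_probability <- function(object, lat, depth_fm, habitat_code = "HB",
                                gear = REFERENCE_GEAR, check_domain = TRUE) {
  nd <- data.frame(lat = lat, depth_fm = depth_fm,
                   habitat_code = habitat_code, stringsAsFactors = FALSE)
  predict(object, nd, gear = gear, check_domain = check_domain)
}

#' @export
residuals.occurrence_model <- function(object,
                                       type = c("deviance", "response"),
                                       ...) {
  type <- match.arg(type)
  y <- object$data$detected
  p <- object$fitted
  if (type == "response") return(y - p)
  sign(y - p) * sqrt(-2 * (y * log(p) + (1 - y) * log(1 - p)))
}

#' @export
simulate.occurrence_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- as.data.frame(replicate(nsim,
                                 stats::rbinom(object$n, 1, object$fitted)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.occurrence_model <- function(x, gear = REFERENCE_GEAR,
                                  habitat_code = "HB", n_points = 101, ...) {
  lat <- seq(x$domain$lat[1], x$domain$lat[2], length.out = n_points)
  depth <- stats::median(x$data$depth_fm)
  p <- predict_probability(x, lat, depth, habitat_code, gear)
  graphics::plot(lat, p, type = "l", xlab = "latitude (deg N)",
                 ylab = "detection probability",
                 main = paste0(format(x$spec), "\n", gear, " at ",
                               round(depth, 1), " fm, ", habitat_code), ...)
  invisible(data.frame(lat = lat, p = p))
}

#' Restrict grid cells to a species' modelled domain
#'
#' Keeps the cells over which the fitted model is interpretable: the
#' 25-100 fathom depth band intersected with the species' latitude range
#' (26-34 degrees N for speckled hind; 28-34 degrees N for warsaw grouper,
#' whose occurrence is modelled only north of 28 degrees because positive
#' records further south are vanishingly rare).
#'
#' @param cells grid-cell data frame.
#' @param species `"speckled_hind"` or `"warsaw_grouper"`.
#' @param lat_bounds,depth_bounds optional length-2 overrides.
#' @return the retained rows of `cells`.
#' @export
restrict_domain <- function(cells, species = c("speckled_hind",
                                               "warsaw_grouper"),
                            lat_bounds = NULL, depth_bounds = c(25, 100)) {
  species <- match.arg(species)
  lat_bounds <- lat_bounds %||%
    switch(species, speckled_hind = c(26, 34), warsaw_grouper = c(28, 34))
  lat_c <- (cells$lat_min + cells$lat_max) / 2
  keep <- cells$depth_fm >= depth_bounds[1] & cells$depth_fm <= depth_bounds[2] &
    lat_c >= lat_bounds[1] & lat_c <= lat_bounds[2]
  cells[keep, , drop = FALSE]
}

#' Predict a probability-of-occurrence surface over grid cells
#'
#' Evaluates the fitted model at each cell's centroid latitude,
#' representative depth and habitat code, with the gear effect fixed at
#' the standardization gear. Cells should first pass [restrict_domain()].
#'
#' @param object a fitted [occurrence_model()].
#' @param cells grid-cell data frame.
#' @param gear standardization gear; default `"DW-ROV"`.
#' @param check_domain passed to [predict.occurrence_model()].
#' @return data frame with columns `cell_id` and `p`.
#' @export
predict_surface <- function(object, cells, gear = REFERENCE_GEAR,
                            check_domain = TRUE) {
  nd <- data.frame(lat = (cells$lat_min + cells$lat_max) / 2,
                   depth_fm = cells$depth_fm,
                   habitat_code = cells$habitat_code,
                   stringsAsFactors = FALSE)
  p <- predict(object, nd, gear = gear, check_domain = check_domain)
  data.frame(cell_id = cells$cell_id, p = p, stringsAsFactors = FALSE)
}
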