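#' Candidate term structure for the occurrence model
#'
#' A model specification names one latitude form, one depth form, and
#' whether the habitat factor enters; the gear (catchability) factor is
#' always included. Squared forms are single centered-and-squared columns
#' without the linear term; categorical forms are dummy-coded floor bins.
#'
#' @param lat one of `"none"`, `"cont"` (degrees, continuous), `"sq"`
#'   (centered degrees squared), `"cat1deg"` (1-degree bins, categorical).
#' @param depth one of `"none"`, `"cat10fm"` (10-fathom bins),
#'   `"cat5fm"` (5-fathom bins), `"sq"` (centered fathoms squared).
#' @param habitat logical; include the habitat factor (`HB` reference,
#'   dummies for `NH` and `UN`)?
#' @return an object of class `"occ_spec"`.
#' @seealso [candidate_specs()] for the full 32-model candidate set.
#' @export
model_spec <- function(lat = c("none", "cont", "sq", "cat1deg"),
                       depth = c("none", "cat10fm", "cat5fm", "sq"),
                       habitat = FALSE) {
  spec <- list(lat = match.arg(lat), depth = match.arg(depth),
               habitat = isTRUE(habitat))
  class(spec) <- "occ_spec"
  spec
}

#' @export
format.occ_spec <- function(x, ...) {
  parts <- "gear"
  if (x$lat != "none")
    parts <- c(parts, switch(x$lat, cont = "lat_cont", sq = "lat_sq",
                             cat1deg = "lat"))
  if (x$depth != "none")
    parts <- c(parts, switch(x$depth, cat10fm = "dep", cat5fm = "dep_fine",
                             sq = "dep_sq"))
  if (x$habitat) parts <- c(parts, "hab")
  paste(parts, collapse = " + ")
}

#' @export
print.occ_spec <- function(x, ...) {
  cat("occurrence model spec:", format(x), "\n")
  invisible(x)
}

#' Enumerate the full candidate model set
#'
#' All combinations of four latitude forms (including none), four depth
#' forms (including none) and habitat in/out, with gear always present:
#' 32 candidate specifications.
#'
#' @return a list of [model_spec()] objects, named by their formula labels.
#' @export
candidate_specs <- function() {
  out <- list()
  for (lat in c("none", "cont", "sq", "cat1deg"))
    for (depth in c("none", "cat10fm", "cat5fm", "sq"))
      for (hab in c(FALSE, TRUE))
        out[[length(out) + 1L]] <- model_spec(lat, depth, hab)
  names(out) <- vapply(out, format, character(1))
  out
}

# Default centering constants: midpoints of the shelf-edge analysis domain
# (latitude 26-34 degrees N, depth 25-100 fathoms). Squared terms are
# centered before squaring to reduce collinearity with the intercept.
default_centers <- function() c(lat = 30, depth = 62.5)

#' Build the design matrix for an occurrence model
#'
#' Constructs the dummy-coded design matrix for a candidate specification:
#' an intercept; gear dummies with `DW-ROV` as the reference level;
#' latitude as raw degrees (`cont`), centered degrees squared (`sq`) or
#' floor-degree bin dummies (`cat1deg`, lowest bin as reference); depth as
#' centered fathoms squared (`sq`) or floor 10/5-fathom bin dummies
#' (lowest bin as reference); habitat dummies for `NH` and `UN` with
#' hardbottom (`HB`, to which `PH` is mapped) as reference.
#'
#' @param records observation data frame with columns `gear`, `lat`,
#'   `depth_fm`, `habitat_code`, `detected`.
#' @param spec a [model_spec()].
#' @param centers named numeric `c(lat=, depth=)` used to center squared
#'   terms; defaults to the analysis-domain midpoints (30 deg N, 62.5 fm).
#' @param levels training factor-level sets, as returned in the result;
#'   supply when building a prediction matrix so columns match the fit.
#' @return list with `X` (matrix), `y` (response, `NULL` if `records`
#'   lacks `detected`), `groups` (variable group per column) and `levels`.
#' @export
build_design_matrix <- function(records, spec, centers = default_centers(),
                                levels = NULL) {
  n <- nrow(records)
  training <- is.null(levels)
  if (training) {
    if (n < 2L) stop_validation("need at least 2 records to build a design")
    if (length(unique(records$detected)) < 2L)
      stop_validation("response has a single class; both detections and non-detections are required")
    bad <- setdiff(unique(records$gear), GEAR_LEVELS)
    if (length(bad))
      stop_validation("unknown gear value(s): ", paste(bad, collapse = ", "))
    levels <- list(
      gear = setdiff(sort(unique(records$gear)), REFERENCE_GEAR),
      lat_bins = if (spec$lat == "cat1deg") sort(unique(floor(records$lat))),
      depth_bins = if (spec$depth %in% c("cat10fm", "cat5fm")) {
        w <- if (spec$depth == "cat10fm") 10 else 5
        sort(unique(assign_depth_bin(records$depth_fm, w)))
      }
    )
  }

  cols <- list(`(Intercept)` = rep(1, n))
  groups <- "intercept"
  add <- function(name, values, group) {
    cols[[name]] <<- values
    groups <<- c(groups, group)
  }

  for (g in levels$gear)
    add(paste0("gear", g), as.numeric(records$gear == g), "gear")

  if (spec$lat == "cont") {
    add("lat_cont", records$lat, "latitude")
  } else if (spec$lat == "sq") {
    add("lat_sq", (records$lat - centers[["lat"]])^2, "latitude")
  } else if (spec$lat == "cat1deg") {
    bins <- floor(records$lat)
    for (b in levels$lat_bins[-1])
      add(paste0("lat", b), as.numeric(bins == b), "latitude")
  }

  if (spec$depth == "sq") {
    add("dep_sq", (records$depth_fm - centers[["depth"]])^2, "depth")
  } else if (spec$depth %in% c("cat10fm", "cat5fm")) {
    w <- if (spec$depth == "cat10fm") 10 else 5
    bins <- assign_depth_bin(records$depth_fm, w)
    for (b in levels$depth_bins[-1])
      add(paste0("dep", w, "fm_", b), as.numeric(bins == b), "depth")
  }

  if (spec$habitat) {
    hab <- ifelse(records$habitat_code == "PH", "HB", records$habitat_code)
    for (h in c("NH", "UN"))
      add(paste0("hab", h), as.numeric(hab == h), "habitat")
  }

  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)

  if (training) {
    const <- vapply(seq_len(ncol(X))[-1],
                    function(j) length(unique(X[, j])) == 1L, logical(1))
    if (any(const))
      stop_validation("constant (perfectly collinear) design column(s): ",
                      paste(colnames(X)[-1][const], collapse = ", "))
  }

  y <- if ("detected" %in% names(records)) records$detected
  list(X = X, y = y, groups = groups, levels = levels)
}

#' Maximum-likelihood logistic fit of a design matrix
#'
#' Fits a binomial GLM with logit link by iteratively reweighted least
#' squares (convergence when the relative deviance change is below `1e-8`,
#' at most 100 iterations). Standard errors come from the inverse Fisher
#' information at the optimum; the null deviance is the closed-form
#' intercept-only binomial deviance at the observed proportion.
#'
#' @param X design matrix including an intercept column.
#' @param y binary response vector (0/1).
#' @param epsilon,maxit IRLS convergence tolerance and iteration cap.
#' @return list with `coefficients`, `se`, `loglik`, `deviance`,
#'   `null_deviance`, `df` (number of estimated coefficients), `aic`,
#'   `fitted`, `iter`.
#' @export
fit_logistic <- function(X, y, epsilon = 1e-8, maxit = 100L) {
  if (length(unique(y)) < 2L)
    stop_validation("response has a single class")
  if (qr(X)$rank < ncol(X))
    stop_validation("design matrix is rank deficient")
  fit <- suppressWarnings(stats::glm.fit(
    X, y, family = stats::binomial(),
    control = stats::glm.control(epsilon = epsilon, maxit = maxit)
  ))
  if (!fit$converged || any(!is.finite(fit$coefficients)))
    stop("logistic fit did not converge after ", fit$iter,
         " IRLS iterations (possible separation); deviance = ",
         format(fit$deviance))
  if (fit$deviance < 1e-6)
    stop("complete separation: the fit classifies the training data ",
         "perfectly (residual deviance ", format(fit$deviance), " after ",
         fit$iter, " iterations); coefficients are not identified")
  p <- fit$fitted.values
  w <- p * (1 - p)
  info <- crossprod(X * sqrt(w))
  # Quasi-separated fits (a factor cell with no detections) leave the
  # information matrix numerically singular: the point estimates and
  # predictions remain usable, the affected standard errors do not.
  se <- tryCatch(sqrt(diag(solve(info))),
                 error = function(e) rep(NA_real_, ncol(X)))
  loglik <- sum(stats::dbinom(y, 1, p, log = TRUE))
  pbar <- mean(y)
  null_dev <- -2 * (sum(y) * log(pbar) + sum(1 - y) * log(1 - pbar))
  k <- ncol(X)
  list(coefficients = stats::setNames(fit$coefficients, colnames(X)),
       se = stats::setNames(se, colnames(X)),
       loglik = loglik,
       deviance = fit$deviance,
       null_deviance = null_dev,
       df = k,
       aic = 2 * k - 2 * loglik,
       fitted = p,
       iter = fit$iter)
}

#' Fit a logit-link occurrence model to presence-absence records
#'
#' The central fitting function: models the probability that a sampling
#' event detects the species as a logit-linear function of gear
#' (catchability), latitude, depth and habitat, under one candidate term
#' structure. Returns a classed object supporting `print`, `summary`,
#' `coef`, `predict`, `logLik`, `AIC`, `deviance`, `residuals`, `simulate`
#' and `plot`, plus [deviance_explained()] and [predict_surface()].
#'
#' @param records observation data frame with columns `gear`, `lat`,
#'   `depth_fm`, `habitat_code`, `detected` (0/1), one row per sampling
#'   event. Multiple captures in one event are not modelled; the response
#'   is binary.
#' @param spec a [model_spec()]; default gear-only.
#' @param centers centering constants for squared terms, see
#'   [build_design_matrix()].
#' @param domain optional list with `lat` and `depth_fm` length-2 bounds;
#'   predictions outside it raise an error rather than extrapolate.
#'   Defaults to the observed covariate ranges of `records`.
#' @param epsilon,maxit IRLS control, see [fit_logistic()].
#' @return an object of class `"occurrence_model"`.
#' @examples
#' obs <- synthetic_dataset(seed = 1, n_events = 2000)$observations
#' fit <- occurrence_model(obs, model_spec(lat = "cont", depth = "sq"))
#' fit
#' @export
occurrence_model <- function(records, spec = model_spec(),
                             centers = default_centers(), domain = NULL,
                             epsilon = 1e-8, maxit = 100L) {
  stopifnot(inherits(spec, "occ_spec"))
  d <- build_design_matrix(records, spec, centers)
  f <- fit_logistic(d$X, d$y, epsilon = epsilon, maxit = maxit)
  domain <- domain %||% list(lat = range(records$lat),
                             depth_fm = range(records$depth_fm))
  out <- c(f, list(spec = spec, centers = centers, levels = d$levels,
                   groups = d$groups, domain = domain, n = nrow(records),
                   data = records, call = match.call()))
  class(out) <- "occurrence_model"
  out
}

#' Sequential deviance decomposition of an occurrence model
#'
#' Refits the model adding one variable group at a time in `entry_order`
#' and reports, for each group, 100 x (deviance before - deviance after) /
#' null deviance: the percent of null deviance explained by that group's
#' entry. Components depend on the entry order but always sum to the total
#' deviance explained of the full model.
#'
#' @param object a fitted [occurrence_model()].
#' @param entry_order character vector ordering the groups; default
#'   `c("gear", "latitude", "depth", "habitat")`. Groups absent from the
#'   spec are skipped.
#' @return data frame with columns `group` and `pct_explained`, plus a
#'   `"total"` attribute (percent of null deviance explained overall).
#' @export
deviance_explained <- function(object,
                               entry_order = c("gear", "latitude", "depth",
                                               "habitat")) {
  stopifnot(inherits(object, "occurrence_model"))
  present <- c("gear",
               if (object$spec$lat != "none") "latitude",
               if (object$spec$depth != "none") "depth",
               if (object$spec$habitat) "habitat")
  entry_order <- intersect(entry_order, present)
  if (!setequal(entry_order, present))
    stop_validation("entry_order must cover exactly the groups in the spec")

  spec_upto <- function(groups) {
    model_spec(lat = if ("latitude" %in% groups) object$spec$lat else "none",
               depth = if ("depth" %in% groups) object$spec$depth else "none",
               habitat = "habitat" %in% groups)
  }
  dev_of <- function(groups) {
    d <- build_design_matrix(object$data, spec_upto(groups), object$centers)
    fit_logistic(d$X, d$y)$deviance
  }
  prev <- object$null_deviance
  pct <- numeric(length(entry_order))
  for (i in seq_along(entry_order)) {
    dev_i <- if (i == length(entry_order)) object$deviance
             else dev_of(entry_order[seq_len(i)])
    pct[i] <- 100 * (prev - dev_i) / object$null_deviance
    prev <- dev_i
  }
  out <- data.frame(group = entry_order, pct_explained = pct,
                    stringsAsFactors = FALSE)
  attr(out, "total") <- 100 *
    (object$null_deviance - object$deviance) / object$null_deviance
  out
}
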