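make_records <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    species = "speckled_hind",
    gear = sample(c("DW-ROV", "HBS", "MARMAP"), n, replace = TRUE),
    lat = runif(n, 28, 32),
    lon = runif(n, -80.5, -79.5),
    depth_fm = runif(n, 25, 100),
    habitat_code = sample(c("HB", "NH", "UN"), n, replace = TRUE),
    detected = rbinom(n, 1, 0.3),
    stringsAsFactors = FALSE)
}

test_that("design matrix columns follow the coding rules", {
  r <- make_records(50)
  d <- build_design_matrix(r, model_spec(lat = "cont"))
  expect_identical(colnames(d$X),
                   c("(Intercept)", "gearHBS", "gearMARMAP", "lat_cont"))
  # DW-ROV rows are all-zero on the gear dummies (reference level)
  ref <- r$gear == "DW-ROV"
  expect_true(all(d$X[ref, c("gearHBS", "gearMARMAP")] == 0))
  expect_equal(d$X[, "lat_cont"], r$lat)

  d2 <- build_design_matrix(r, model_spec(lat = "cat1deg"))
  bins <- sort(unique(floor(r$lat)))
  expect_true(all(paste0("lat", bins[-1]) %in% colnames(d2$X)))
  i <- which(floor(r$lat) == 31)[1]
  expect_equal(unname(d2$X[i, "lat31"]), 1)
  expect_equal(unname(d2$X[i, "lat30"]), 0)

  d3 <- build_design_matrix(r, model_spec(depth = "sq", habitat = TRUE))
  expect_equal(d3$X[, "dep_sq"], (r$depth_fm - 62.5)^2)
  expect_identical(sum(d3$X[, "habNH"] + d3$X[, "habUN"] == 0),
                   sum(r$habitat_code == "HB"))
})

test_that("degenerate designs are rejected with informative errors", {
  r <- make_records(50)
  r$gear <- "HBS"   # constant dummy, collinear with intercept
  expect_error(build_design_matrix(r, model_spec()), "gearHBS",
               class = "reefsdm_validation_error")
  r2 <- make_records(50)
  r2$detected <- 0
  expect_error(build_design_matrix(r2, model_spec()), "single class",
               class = "reefsdm_validation_error")
})

test_that("intercept-only fit returns the logit of the sample proportion", {
  y <- rep(c(1, 0), c(25, 75))
  f <- fit_logistic(matrix(1, 100, 1, dimnames = list(NULL, "(Intercept)")), y)
  expect_equal(unname(f$coefficients), qlogis(0.25), tolerance = 1e-7)
  # null deviance equals the closed-form Bernoulli deviance at p-bar
  expect_equal(f$null_deviance,
               -2 * (25 * log(0.25) + 75 * log(0.75)), tolerance = 1e-8)
  expect_equal(f$deviance, f$null_deviance, tolerance = 1e-6)
  # AIC bookkeeping: 2k - 2 logLik
  expect_equal(f$aic, 2 * 1 - 2 * f$loglik)
})

test_that("separable toy data raises a separation error", {
  X <- cbind(`(Intercept)` = 1, x = c(-2, -1, -0.5, 0.5, 1, 2))
  y <- c(0, 0, 0, 1, 1, 1)
  expect_error(fit_logistic(X, y), "separation")
})

test_that("AIC comparison matches direct likelihood evaluation on a toy set", {
  r <- make_records(10, seed = 3)
  fit <- occurrence_model(r, model_spec(lat = "cont"))
  # independent likelihood evaluation at the fitted coefficients
  eta <- fit$coefficients[["(Intercept)"]] +
    fit$coefficients[["gearHBS"]] * (r$gear == "HBS") +
    fit$coefficients[["gearMARMAP"]] * (r$gear == "MARMAP") +
    fit$coefficients[["lat_cont"]] * r$lat
  ll <- sum(r$detected * eta - log(1 + exp(eta)))
  expect_equal(fit$loglik, ll, tolerance = 1e-8)
  expect_equal(fit$aic, 2 * length(fit$coefficients) - 2 * ll,
               tolerance = 1e-8)
  expect_equal(AIC(fit), fit$aic)
})

test_that("parameter recovery on synthetic ground truth at large n", {
  cfg <- sim_config(seed = 5, n_events = 20000)
  grid <- generate_grid(cfg)
  obs <- generate_observations(grid, cfg)
  tr <- attr(obs, "truth")
  fit <- occurrence_model(obs, model_spec(lat = "cont", depth = "sq",
                                          habitat = TRUE))
  truth <- c("(Intercept)" = tr$intercept, lat_cont = tr$lat,
             dep_sq = tr$depth_sq,
             habNH = unname(tr$habitat[["NH"]]),
             habUN = unname(tr$habitat[["UN"]]))
  for (nm in names(truth))
    expect_lt(abs(fit$coefficients[[nm]] - truth[[nm]]) / fit$se[[nm]], 3)
})

test_that("sequential deviance components sum to the total, any order", {
  ds <- small_dataset()
  fit <- occurrence_model(ds$observations,
                          model_spec(lat = "cont", depth = "sq",
                                     habitat = TRUE))
  de <- deviance_explained(fit)
  expect_equal(sum(de$pct_explained), attr(de, "total"), tolerance = 1e-8)
  de2 <- deviance_explained(fit, c("habitat", "depth", "latitude", "gear"))
  expect_equal(sum(de2$pct_explained), attr(de, "total"), tolerance = 1e-8)
  expect_false(isTRUE(all.equal(de$pct_explained,
                                de2$pct_explained[match(de$group, de2$group)])))
  # single-group model: component equals total
  fit_g <- occurrence_model(ds$observations, model_spec())
  de_g <- deviance_explained(fit_g)
  expect_equal(de_g$pct_explained, attr(de_g, "total"), tolerance = 1e-10)
  expect_error(deviance_explained(fit, c("gear", "latitude")),
               class = "reefsdm_validation_error")
})

test_that("prediction reproduces hand-evaluated published-style coefficients", {
  # forge a fitted object holding printed coefficient values:
  # intercept -20.00, lat_cont 0.59, gear HBS 0.67, dep_sq 0
  fit <- structure(list(
    coefficients = c("(Intercept)" = -20, gearHBS = 0.67,
                     lat_cont = 0.59, dep_sq = 0),
    spec = model_spec(lat = "cont", depth = "sq"),
    centers = c(lat = 30, depth = 62.5),
    levels = list(gear = "HBS"),
    domain = list(lat = c(26, 34), depth_fm = c(25, 100))),
    class = "occurrence_model")
  p <- predict_probability(fit, lat = 34, depth_fm = 62.5, gear = "HBS")
  expect_equal(unname(p), plogis(0.73), tolerance = 1e-10)
  expect_equal(unname(p), 0.674805, tolerance = 1e-6)
  # all-zero coefficients give probability one half
  fit0 <- fit
  fit0$coefficients[] <- 0
  expect_equal(unname(predict_probability(fit0, 30, 50, gear = "HBS")), 0.5)
  # monotone increasing in latitude under a positive latitude coefficient
  ps <- predict_probability(fit, c(27, 30, 33), 62.5, gear = "HBS")
  expect_true(all(diff(ps) > 0))
})

test_that("prediction refuses covariates outside the fitted domain", {
  ds <- small_dataset()
  fit <- occurrence_model(ds$observations, model_spec(lat = "cont"),
                          domain = list(lat = c(28, 32),
                                        depth_fm = c(25, 100)))
  expect_error(predict_probability(fit, lat = 35, depth_fm = 50),
               "domain", class = "reefsdm_validation_error")
  expect_error(predict_probability(fit, lat = 30, depth_fm = 150),
               class = "reefsdm_validation_error")
  p <- predict_probability(fit, lat = 30, depth_fm = 50)
  expect_true(p > 0 && p < 1)
})

test_that("surface prediction matches element-wise prediction on a toy grid", {
  ds <- small_dataset()
  fit <- occurrence_model(ds$observations,
                          model_spec(lat = "cont", depth = "sq"))
  cells <- filter_analysis_domain(ds$grid)[1:5, ]
  surf <- predict_surface(fit, cells, check_domain = FALSE)
  expect_identical(surf$cell_id, cells$cell_id)
  expect_true(all(surf$p > 0 & surf$p < 1))
  for (i in 1:5) {
    p_i <- predict_probability(fit, (cells$lat_min[i] + cells$lat_max[i]) / 2,
                               cells$depth_fm[i], cells$habitat_code[i],
                               check_domain = FALSE)
    expect_equal(surf$p[i], unname(p_i))
  }
  # uniform covariates give a uniform surface (single latitude row)
  uni <- toy_cells(1, 4, depth_fm = 50)
  s_uni <- predict_surface(fit, uni, check_domain = FALSE)
  expect_equal(diff(range(s_uni$p)), 0, tolerance = 1e-12)
})

test_that("species domain restriction applies the latitude rules", {
  cells <- toy_cells(3, 1, lat0_min = 27.5 * 60 - 1, depth_fm = 50)
  # centroids around 27.5 deg N
  expect_identical(nrow(restrict_domain(cells, "warsaw_grouper")), 0L)
  expect_identical(nrow(restrict_domain(cells, "speckled_hind")), 3L)
  c30 <- toy_cells(1, 1, lat0_min = 30 * 60, depth_fm = 50)
  expect_identical(nrow(restrict_domain(c30, "speckled_hind")), 1L)
  c24 <- toy_cells(1, 1, lat0_min = 24 * 60, depth_fm = 50)
  expect_identical(nrow(restrict_domain(c24, "speckled_hind")), 0L)
  expect_identical(nrow(restrict_domain(c24, "warsaw_grouper")), 0L)
  expect_error(restrict_domain(c24, "grouper"))
})

test_that("model methods behave like standard fitted-model accessors", {
  ds <- small_dataset()
  fit <- occurrence_model(ds$observations, model_spec(lat = "cont"))
  expect_identical(coef(fit), fit$coefficients)
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  expect_identical(nobs(fit), nrow(ds$observations))
  expect_equal(deviance(fit), -2 * fit$loglik, tolerance = 1e-8)
  expect_output(print(fit), "lat_cont")
  expect_output(print(summary(fit)), "Deviance explained")
  r <- residuals(fit)
  expect_equal(sum(r^2), fit$deviance, tolerance = 1e-8)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_identical(dim(sims), c(nrow(ds$observations), 2L))
  expect_true(all(unlist(sims) %in% 0:1))
})
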