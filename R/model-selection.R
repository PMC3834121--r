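#' Seeded k-fold partition
#'
#' Randomly partitions `1:n` into `k` folds of near-equal size (sizes
#' differ by at most one). With `stratified = TRUE`, positive and negative
#' labels are partitioned separately so positive counts per fold also
#' differ by at most one — useful for very sparse detections.
#'
#' @param n number of observations.
#' @param k number of folds (default 10).
#' @param seed integer seed; the partition is reproducible.
#' @param stratified logical; stratify on `labels`.
#' @param labels binary labels, required when `stratified = TRUE`.
#' @return list of `k` disjoint integer index vectors covering `1:n`.
#' @export
make_folds <- function(n, k = 10, seed = 1, stratified = FALSE,
                       labels = NULL) {
  if (n < k) stop_validation("n must be at least k")
  if (k < 2) stop_validation("k must be at least 2")
  set.seed(seed)
  assign_fold <- function(idx) {
    f <- factor(rep_len(seq_len(k), length(idx)), levels = seq_len(k))
    split(idx[sample.int(length(idx))], f)
  }
  if (stratified) {
    if (is.null(labels)) stop_validation("stratified folds require labels")
    pos <- assign_fold(which(labels == 1))
    neg <- assign_fold(which(labels == 0))
    folds <- lapply(seq_len(k), function(i)
      sort(c(pos[[i]] %||% integer(0), neg[[i]] %||% integer(0))))
  } else {
    folds <- lapply(assign_fold(seq_len(n)), sort)
  }
  unname(folds)
}

#' ROC curve points over midpoint thresholds
#'
#' Builds the receiver operating characteristic of a score vector against
#' binary labels under the rule "predict positive iff score >= threshold".
#' Candidate thresholds are the midpoints between consecutive sorted unique
#' scores plus `-Inf` and `+Inf` sentinels, so every achievable
#' classification is represented exactly once.
#'
#' @param scores numeric classification scores (e.g. fitted probabilities).
#' @param labels binary labels (0/1) of the same length.
#' @return data frame with columns `threshold`, `tpr` (sensitivity) and
#'   `tnr` (specificity).
#' @export
roc_points <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop_validation("scores and labels must have equal length")
  if (length(unique(labels)) < 2L)
    stop_validation("labels must contain both classes")
  u <- sort(unique(scores))
  thr <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n_pos,
                numeric(1))
  tnr <- vapply(thr, function(t) sum(scores < t & labels == 0) / n_neg,
                numeric(1))
  data.frame(threshold = thr, tpr = tpr, tnr = tnr)
}

#' Threshold maximizing sensitivity plus specificity
#'
#' Selects the ROC threshold at which the proportion of correctly
#' classified positives (TPR) plus the proportion of correctly classified
#' negatives (TNR) is maximal — the Youden-style criterion. Ties are
#' broken by the smallest qualifying threshold, which favors sensitivity
#' for rare positives.
#'
#' @param roc data frame from [roc_points()].
#' @return the selected threshold (may be `-Inf`/`Inf` for degenerate
#'   score vectors).
#' @export
optimal_threshold <- function(roc) {
  if (nrow(roc) == 0L) stop_validation("empty ROC table")
  s <- roc$tpr + roc$tnr
  roc$threshold[which(s >= max(s) - 1e-12)[1]]
}

#' False positive and false negative rates of binary predictions
#'
#' @param predicted binary predictions (0/1).
#' @param labels binary true labels (0/1), both classes present.
#' @return named numeric `c(fpr=, fnr=)` with `fpr = FP/(FP+TN)` and
#'   `fnr = FN/(FN+TP)`.
#' @export
contingency_rates <- function(predicted, labels) {
  if (length(predicted) != length(labels))
    stop_validation("predicted and labels must have equal length")
  if (length(unique(labels)) < 2L)
    stop_validation("labels must contain both classes")
  fp <- sum(predicted == 1 & labels == 0)
  tn <- sum(predicted == 0 & labels == 0)
  fn <- sum(predicted == 0 & labels == 1)
  tp <- sum(predicted == 1 & labels == 1)
  c(fpr = fp / (fp + tn), fnr = fn / (fn + tp))
}

#' Repeated k-fold cross-validation of a candidate occurrence model
#'
#' For each fold of each re-randomization: fit the candidate on the
#' training records, derive the classification threshold from the ROC of
#' the \emph{training-set} fitted scores, classify the held-out testing
#' records at that threshold, and record the testing false-positive and
#' false-negative rates. Rates are aggregated as mean and SD over all
#' fold-by-repeat evaluations. Training folds that happen to contain a
#' single response class (possible on 2-7 percent occurrence data) trigger
#' re-randomization of that repeat's partition under a derived seed; after
#' 10 failed attempts an error advises `stratified = TRUE`.
#'
#' @param records observation data frame (see [occurrence_model()]).
#' @param spec a [model_spec()] candidate.
#' @param k folds (default 10; 5 also conventional).
#' @param n_repeats number of re-randomizations of the fold partition
#'   (default 10).
#' @param seed integer seed controlling all partitions.
#' @param stratified stratify folds on the response?
#' @param centers passed to [occurrence_model()].
#' @return object of class `"cv_result"`: list with `spec`, `fpr_mean`,
#'   `fpr_sd`, `fnr_mean`, `fnr_sd`, `thresholds` (per evaluation), and
#'   the per-evaluation `rates` matrix.
#' @export
cross_validate <- function(records, spec, k = 10, n_repeats = 10, seed = 1,
                           stratified = FALSE, centers = default_centers()) {
  n <- nrow(records)
  y <- records$detected
  fpr <- fnr <- thr_used <- numeric(0)
  for (r in seq_len(n_repeats)) {
    folds <- NULL
    for (attempt in 0:10) {
      if (attempt == 10)
        stop("could not draw a fold partition with both response classes ",
             "in every training set after 10 attempts; ",
             "consider stratified = TRUE")
      cand <- make_folds(n, k, seed = derive_seed(seed, 1000 * r + attempt),
                         stratified = stratified, labels = y)
      ok <- all(vapply(cand, function(f)
        length(unique(y[setdiff(seq_len(n), f)])) == 2L, logical(1)))
      if (ok) { folds <- cand; break }
    }
    for (f in folds) {
      if (length(f) == 0L) next
      train <- records[setdiff(seq_len(n), f), , drop = FALSE]
      test <- records[f, , drop = FALSE]
      fit <- occurrence_model(train, spec, centers = centers)
      thr <- optimal_threshold(roc_points(fit$fitted, train$detected))
      score <- predict(fit, test, check_domain = FALSE)
      pred <- as.numeric(score >= thr)
      # Record each rate whenever its denominator is non-empty, so sparse
      # test folds (or leave-one-out) still aggregate.
      neg <- test$detected == 0
      if (any(neg)) fpr <- c(fpr, mean(pred[neg] == 1))
      if (any(!neg)) fnr <- c(fnr, mean(pred[!neg] == 0))
      thr_used <- c(thr_used, thr)
    }
  }
  out <- list(spec = spec,
              fpr_mean = mean(fpr), fpr_sd = stats::sd(fpr),
              fnr_mean = mean(fnr), fnr_sd = stats::sd(fnr),
              thresholds = thr_used,
              rates = list(fpr = fpr, fnr = fnr),
              k = k, n_repeats = n_repeats)
  class(out) <- "cv_result"
  out
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("CV (%d-fold x %d repeats) of %s\n", x$k, x$n_repeats,
              format(x$spec)))
  cat(sprintf("  FPR %.3f +/- %.3f   FNR %.3f +/- %.3f\n",
              x$fpr_mean, x$fpr_sd, x$fnr_mean, x$fnr_sd))
  invisible(x)
}

#' Select the best candidate by cross-validation and by AIC
#'
#' The best predictive model minimizes the summed mean false-positive and
#' false-negative rate; the best-fitting model minimizes AIC. Both are
#' returned because they need not coincide, and downstream protection
#' reports present the pair as an inter-model uncertainty range. Ties on
#' FPR+FNR go to the lower-AIC spec.
#'
#' @param cv_results list of [cross_validate()] results, one per candidate.
#' @param fitted_models list of [occurrence_model()] fits for the same
#'   candidates, in the same order.
#' @return list with elements `best_by_cv` and `best_by_aic` (indices into
#'   the candidate list) and the corresponding `spec_cv`, `spec_aic`.
#' @export
select_best <- function(cv_results, fitted_models) {
  if (length(cv_results) == 0L) stop_validation("empty candidate set")
  if (length(cv_results) != length(fitted_models))
    stop_validation("cv_results and fitted_models must align")
  loss <- vapply(cv_results, function(r) r$fpr_mean + r$fnr_mean, numeric(1))
  aic <- vapply(fitted_models, function(f) f$aic, numeric(1))
  tied <- which(loss <= min(loss) + 1e-12)
  best_cv <- tied[which.min(aic[tied])]
  best_aic <- which.min(aic)
  list(best_by_cv = best_cv, best_by_aic = best_aic,
       spec_cv = cv_results[[best_cv]]$spec,
       spec_aic = fitted_models[[best_aic]]$spec)
}

#' Fit, cross-validate and rank the full candidate set
#'
#' Fits every candidate spec, cross-validates each, and returns a ranking
#' table (one row per candidate with AIC and FPR/FNR mean and SD, with the
#' AIC-best and CV-best candidates flagged), alongside the fits and CV
#' results.
#'
#' @inheritParams cross_validate
#' @param specs list of candidates; default [candidate_specs()] (32).
#' @return list with `table` (data frame), `fits`, `cv`, and `best`
#'   (from [select_best()]).
#' @export
rank_candidates <- function(records, specs = candidate_specs(), k = 10,
                            n_repeats = 10, seed = 1, stratified = FALSE,
                            centers = default_centers()) {
  fits <- lapply(specs, function(s)
    occurrence_model(records, s, centers = centers))
  cv <- lapply(seq_along(specs), function(i)
    cross_validate(records, specs[[i]], k = k, n_repeats = n_repeats,
                   seed = derive_seed(seed, i), stratified = stratified,
                   centers = centers))
  best <- select_best(cv, fits)
  tab <- data.frame(
    model = vapply(specs, format, character(1)),
    n_par = vapply(fits, function(f) f$df, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    fpr_mean = vapply(cv, function(r) r$fpr_mean, numeric(1)),
    fpr_sd = vapply(cv, function(r) r$fpr_sd, numeric(1)),
    fnr_mean = vapply(cv, function(r) r$fnr_mean, numeric(1)),
    fnr_sd = vapply(cv, function(r) r$fnr_sd, numeric(1)),
    best_by_aic = FALSE, best_by_cv = FALSE,
    stringsAsFactors = FALSE
  )
  tab$best_by_aic[best$best_by_aic] <- TRUE
  tab$best_by_cv[best$best_by_cv] <- TRUE
  list(table = tab, fits = fits, cv = cv, best = best)
}
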