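#' Leave-last-visit-out split
#'
#' For every eye with at least `min_visits` visits, the chronologically last
#' visit is held out; all other visits (including the baseline) remain in the
#' training set. Eyes with fewer visits contribute to training only.
#'
#' @param ecc Table from [visit_to_ecc()].
#' @param min_visits Minimum visits per eye for that eye to contribute a
#'   held-out visit (default 3).
#' @return A list with `train` and `test` (both subsets of `ecc`).
#' @export
holdout_last_visit <- function(ecc, min_visits = 3) {
  stopifnot(is.data.frame(ecc))
  need <- c("patient_id", "eye", "t_years")
  miss <- setdiff(need, names(ecc))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  key <- paste(ecc$patient_id, ecc$eye, sep = "/")
  test_rows <- integer(0)
  for (k in unique(key)) {
    rows <- which(key == k)
    if (length(rows) < min_visits) next
    tmax <- max(ecc$t_years[rows])
    last <- rows[ecc$t_years[rows] == tmax]
    if (length(last) > 1) {
      stop("tied last-visit times for eye ", k, "; disambiguate the visits")
    }
    test_rows <- c(test_rows, last)
  }
  if (length(test_rows) == 0) {
    stop("no eye has ", min_visits, " or more visits; nothing to hold out")
  }
  list(train = ecc[-test_rows, , drop = FALSE],
       test = ecc[test_rows, , drop = FALSE])
}

#' Hold-out predictions of composite change
#'
#' Runs the leave-last-visit-out protocol: the model is trained on all but
#' the last visit of each qualifying eye, and the held-out composite change
#' is predicted from the training fit's conditional (BLUP) slopes. Measured
#' changes for held-out visits are computed against each eye's baseline with
#' the same weights.
#'
#' @param ecc Table from [visit_to_ecc()].
#' @param weights Five non-negative weights in canonical [biomarkers()]
#'   order.
#' @param min_visits Passed to [holdout_last_visit()].
#' @param method Estimation method for the training fit.
#' @return A list with `pairs` (tibble: patient_id, eye, dt_years,
#'   predicted, measured), the training `fit` and the `split`.
#' @export
holdout_predictions <- function(ecc, weights, min_visits = 3,
                                method = c("REML", "ML")) {
  method <- match.arg(method)
  split <- holdout_last_visit(ecc, min_visits = min_visits)
  train_deltas <- composite_deltas(deltas_from_baseline(split$train), weights)
  fit <- fit_progression(train_deltas, method = method, warn_pinned = FALSE)

  # measured change of held-out visits: deltas against the full table's
  # baselines (baselines are always in the training split)
  all_deltas <- composite_deltas(deltas_from_baseline(ecc), weights)
  key <- function(d) paste(d$patient_id, d$eye, d$dt_years, sep = "/")
  test_key <- paste(split$test$patient_id, split$test$eye,
                    split$test$t_years, sep = "/")
  test_deltas <- all_deltas[match(test_key, key(all_deltas)), , drop = FALSE]
  keep <- !is.na(test_deltas$delta_c)
  test_deltas <- test_deltas[keep, , drop = FALSE]
  pred <- suppressWarnings(predict_change(fit, test_deltas$patient_id,
                                          test_deltas$eye,
                                          test_deltas$dt_years))
  pairs <- tibble::tibble(
    patient_id = test_deltas$patient_id,
    eye = test_deltas$eye,
    dt_years = test_deltas$dt_years,
    predicted = as.numeric(pred),
    measured = test_deltas$delta_c
  )
  list(pairs = pairs, fit = fit, split = split)
}

#' Calibration of predicted vs measured change
#'
#' Regresses measured on predicted composite change by ordinary least
#' squares and reports the squared Pearson correlation together with the
#' slope and intercept and their Wald 95% confidence intervals. Perfect
#' prediction gives `r_squared = 1`, slope 1, intercept 0.
#'
#' @param predicted,measured Numeric vectors of equal length (at least 3
#'   pairs).
#' @return A `calibration_result` list: `r_squared`, `slope`, `slope_ci`,
#'   `intercept`, `intercept_ci`, `n_pairs`, `pairs`.
#' @export
calibrate <- function(predicted, measured) {
  stopifnot(is.numeric(predicted), is.numeric(measured),
            length(predicted) == length(measured))
  keep <- !is.na(predicted) & !is.na(measured)
  predicted <- predicted[keep]
  measured <- measured[keep]
  n <- length(predicted)
  if (n < 3) stop("at least 3 prediction pairs are required (got ", n, ")")
  if (stats::var(predicted) <= 0) stop("zero variance in predictions")
  ols <- stats::lm(measured ~ predicted)
  cf <- summary(ols)$coefficients
  z <- 1.959964
  out <- list(
    r_squared = stats::cor(predicted, measured)^2,
    slope = cf["predicted", "Estimate"],
    slope_ci = cf["predicted", "Estimate"] + c(-z, z) * cf["predicted", "Std. Error"],
    intercept = cf["(Intercept)", "Estimate"],
    intercept_ci = cf["(Intercept)", "Estimate"] + c(-z, z) * cf["(Intercept)", "Std. Error"],
    n_pairs = n,
    pairs = tibble::tibble(predicted = predicted, measured = measured)
  )
  class(out) <- "calibration_result"
  out
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Prediction calibration on %d pairs\n", x$n_pairs))
  cat(sprintf("  R^2       : %.3f\n", x$r_squared))
  cat(sprintf("  slope     : %.2f (95%% CI %.2f to %.2f)\n",
              x$slope, x$slope_ci[1], x$slope_ci[2]))
  cat(sprintf("  intercept : %.2f (95%% CI %.2f to %.2f)\n",
              x$intercept, x$intercept_ci[1], x$intercept_ci[2]))
  invisible(x)
}

#' Hold-out validation of a weighted composite
#'
#' Convenience wrapper chaining [holdout_predictions()] and [calibrate()].
#' With frozen development weights this is also the external-replication
#' protocol: the second cohort gets its own model fit but no re-optimization.
#'
#' @inheritParams holdout_predictions
#' @return A list with `calibration`, `fit` and `pairs`.
#' @export
validate_composite <- function(ecc, weights, min_visits = 3,
                               method = c("REML", "ML")) {
  hp <- holdout_predictions(ecc, weights, min_visits = min_visits,
                            method = method)
  cal <- calibrate(hp$pairs$predicted, hp$pairs$measured)
  list(calibration = cal, fit = hp$fit, pairs = hp$pairs)
}
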