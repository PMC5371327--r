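#' Fit the zero-intercept random-slope progression model
#'
#' Models the composite change from baseline of eye `j` in patient `i` at
#' follow-up time `dt` as
#' `delta_c = (s + s_i + s_ij) * dt + e`,
#' where `s` is the population slope (degrees/year), `s_i ~ N(0, sd_patient^2)`
#' are independent patient-level slope deviations, `s_ij ~ N(0, sd_eye^2)` are
#' independent eye-within-patient deviations and `e ~ N(0, rmse^2)` is the
#' residual. The intercept is zero because changes from baseline are
#' modelled; baseline rows (`dt == 0`, deterministically zero) are excluded
#' from the fit so they cannot deflate the residual variance. Estimation is
#' restricted maximum likelihood by default (ML available for likelihood
#' comparisons), with the two variance ratios profiled on the log scale,
#' deterministic starting values (OLS slope, variance ratios 1) and a
#' quasi-Newton search.
#'
#' @param deltas Table with columns `patient_id`, `eye`, `dt_years` and
#'   `delta_c` (e.g. from [composite_deltas()]). Rows with missing `delta_c`
#'   are dropped.
#' @param method `"REML"` (default) or `"ML"`.
#' @param start Optional length-2 numeric: starting values for the
#'   log variance ratios (patient, eye) relative to the residual variance;
#'   used to warm-start repeated fits.
#' @param warn_pinned Warn when a variance component is estimated at the zero
#'   boundary.
#' @return A `progression_fit` object: population slope `s` with Wald 95% CI,
#'   random-slope SDs `sd_patient` and `sd_eye`, residual `rmse`, per-eye
#'   conditional (BLUP) slopes, conditional residuals, log-likelihood and
#'   fit metadata.
#' @export
fit_progression <- function(deltas, method = c("REML", "ML"), start = NULL,
                            warn_pinned = TRUE) {
  method <- match.arg(method)
  stopifnot(is.data.frame(deltas))
  need <- c("patient_id", "eye", "dt_years", "delta_c")
  miss <- setdiff(need, names(deltas))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  d <- deltas[!is.na(deltas$delta_c) & deltas$dt_years > 0, need, drop = FALSE]
  if (nrow(d) == 0) {
    stop("no usable records: model fitting needs follow-up visits ",
         "(dt_years > 0) with a non-missing composite change")
  }
  pid <- droplevels(factor(d$patient_id))
  eid <- droplevels(factor(paste(d$patient_id, d$eye, sep = "/")))
  if (nlevels(pid) < 2) {
    stop("model fitting needs at least 2 patients (got ", nlevels(pid), ")")
  }
  res <- reml_fit(y = d$delta_c, t = d$dt_years, pid = pid, eid = eid,
                  method = method, start = start)
  if (!res$converged) {
    stop("mixed-model fit did not converge: ", res$message,
         " (objective ", format(res$objective), ")")
  }
  if (warn_pinned && any(res$pinned)) {
    warning("variance component(s) estimated at the zero boundary: ",
            paste(c("patient", "eye")[res$pinned], collapse = ", "))
  }

  eye_levels <- levels(eid)
  eye_pid <- vapply(strsplit(eye_levels, "/", fixed = TRUE), `[`, character(1), 1)
  eye_eye <- vapply(strsplit(eye_levels, "/", fixed = TRUE),
                    function(p) paste(p[-1], collapse = "/"), character(1))
  cond <- tibble::tibble(
    patient_id = eye_pid,
    eye = eye_eye,
    slope = res$s + res$u_patient[match(eye_pid, levels(pid))] + res$u_eye
  )

  z <- 1.959964
  fit <- list(
    s = res$s,
    se_s = res$se_s,
    ci_s = c(res$s - z * res$se_s, res$s + z * res$se_s),
    sd_patient = res$sd_patient,
    sd_eye = res$sd_eye,
    rmse = res$rmse,
    conditional_slopes = cond,
    n_obs = nrow(d),
    n_patients = nlevels(pid),
    n_eyes = nlevels(eid),
    logLik = res$loglik,
    method = method,
    theta = res$theta,
    pinned = res$pinned,
    residuals = tibble::tibble(
      patient_id = d$patient_id, eye = d$eye, dt_years = d$dt_years,
      delta_c = d$delta_c, fitted = res$fitted, resid = res$resid
    )
  )
  class(fit) <- "progression_fit"
  fit
}

# Profiled REML/ML for y = s*t + Zp u_p + Ze u_e + e with V = sigma^2 *
# (I + g_p Zp Zp' + g_e Ze Ze'). Two log variance ratios are optimized;
# slope and residual variance have closed forms given the ratios.
reml_fit <- function(y, t, pid, eid, method = "REML", start = NULL,
                     Zp = NULL, Ze = NULL, Gp = NULL, Ge = NULL) {
  n <- length(y)
  if (is.null(Zp)) Zp <- t * stats::model.matrix(~ pid - 1)
  if (is.null(Ze)) Ze <- t * stats::model.matrix(~ eid - 1)
  if (is.null(Gp)) Gp <- tcrossprod(Zp)
  if (is.null(Ge)) Ge <- tcrossprod(Ze)
  stt <- sum(t * t)
  s0 <- sum(t * y) / stt
  rss0 <- sum((y - s0 * t)^2)
  df <- if (method == "REML") n - 1L else n

  # exact-fit degenerate case: all variance collapses
  if (rss0 <= 1e-18 * max(1, sum(y^2))) {
    np <- ncol(Zp)
    ne <- ncol(Ze)
    return(list(s = s0, se_s = 0, sd_patient = 0, sd_eye = 0, rmse = 0,
                u_patient = numeric(np), u_eye = numeric(ne),
                fitted = s0 * t, resid = y - s0 * t,
                loglik = Inf, theta = c(-30, -30), pinned = c(TRUE, TRUE),
                converged = TRUE, message = "exact fit", objective = -Inf))
  }

  eval_at <- function(lg) {
    g <- exp(lg)
    V0 <- diag(n) + g[1] * Gp + g[2] * Ge
    R <- tryCatch(chol(V0), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    ldet <- 2 * sum(log(diag(R)))
    wx <- backsolve(R, t, transpose = TRUE)
    wy <- backsolve(R, y, transpose = TRUE)
    xvx <- sum(wx * wx)
    xvy <- sum(wx * wy)
    yvy <- sum(wy * wy)
    rss <- max(yvy - xvy^2 / xvx, 1e-300)
    list(R = R, ldet = ldet, xvx = xvx, s = xvy / xvx, rss = rss)
  }
  objective <- function(lg) {
    ev <- eval_at(lg)
    if (is.null(ev)) return(1e10)
    if (method == "REML") {
      ev$ldet + log(ev$xvx) + df * log(ev$rss)
    } else {
      ev$ldet + df * log(ev$rss)
    }
  }

  if (is.null(start)) start <- c(0, 0)
  opt <- stats::nlminb(start, objective, lower = -30, upper = 25,
                       control = list(rel.tol = 1e-10, iter.max = 500,
                                      eval.max = 1000))
  ev <- eval_at(opt$par)
  if (is.null(ev)) {
    return(list(converged = FALSE, message = "singular covariance",
                objective = opt$objective))
  }
  g <- exp(opt$par)
  sigma2 <- ev$rss / df
  s <- ev$s
  r <- y - s * t
  v0inv_r <- backsolve(ev$R, backsolve(ev$R, r, transpose = TRUE))
  u_p <- as.numeric(g[1] * crossprod(Zp, v0inv_r))
  u_e <- as.numeric(g[2] * crossprod(Ze, v0inv_r))
  pid_idx <- as.integer(pid)
  eid_idx <- as.integer(eid)
  fitted <- (s + u_p[pid_idx] + u_e[eid_idx]) * t
  loglik <- if (method == "REML") {
    -0.5 * (df * log(2 * pi * sigma2) + ev$ldet + log(ev$xvx) + df)
  } else {
    -0.5 * (df * log(2 * pi * sigma2) + ev$ldet + df)
  }
  pinned <- opt$par <= -29
  list(s = s, se_s = sqrt(sigma2 / ev$xvx),
       sd_patient = sqrt(g[1] * sigma2), sd_eye = sqrt(g[2] * sigma2),
       rmse = sqrt(sigma2),
       u_patient = u_p, u_eye = u_e, fitted = fitted, resid = y - fitted,
       loglik = loglik, theta = opt$par, pinned = pinned,
       converged = opt$convergence == 0 ||
         grepl("relative convergence|both X|singular convergence", opt$message),
       message = opt$message, objective = opt$objective)
}

#' @export
print.progression_fit <- function(x, ...) {
  cat("Zero-intercept random-slope progression model (", x$method, ")\n", sep = "")
  cat(sprintf("  population slope s : %.4f deg/year (95%% CI %.4f to %.4f)\n",
              x$s, x$ci_s[1], x$ci_s[2]))
  cat(sprintf("  sd(patient slope)  : %.4f deg/year\n", x$sd_patient))
  cat(sprintf("  sd(eye slope)      : %.4f deg/year\n", x$sd_eye))
  cat(sprintf("  residual RMSE      : %.4f deg\n", x$rmse))
  cat(sprintf("  MSDR               : %.3f\n", x$s / x$rmse))
  cat(sprintf("  %d observations, %d patients, %d eyes\n",
              x$n_obs, x$n_patients, x$n_eyes))
  invisible(x)
}

#' @export
logLik.progression_fit <- function(object, ...) {
  structure(object$logLik, df = 4, class = "logLik")
}

#' Mean-to-standard-deviation ratio of a fitted model
#'
#' The responsiveness criterion used to rank endpoint weightings: the
#' population slope divided by the residual standard deviation,
#' `MSDR = s / RMSE`. A zero residual SD is signalled as an infinite MSDR
#' with a flag rather than an error.
#'
#' @param fit A [fit_progression()] result.
#' @return An `msdr_result` list: `msdr`, `slope`, `rmse`, `infinite`.
#' @export
msdr <- function(fit) {
  stopifnot(inherits(fit, "progression_fit"))
  out <- list(
    msdr = if (fit$rmse > 0) fit$s / fit$rmse else Inf,
    slope = fit$s,
    rmse = fit$rmse,
    infinite = fit$rmse <= 0
  )
  class(out) <- "msdr_result"
  out
}

#' @export
print.msdr_result <- function(x, ...) {
  cat(sprintf("MSDR = %.3f (slope %.4f deg/year, residual SD %.4f deg)%s\n",
              x$msdr, x$slope, x$rmse,
              if (x$infinite) " [residual SD is zero]" else ""))
  invisible(x)
}

#' Predict composite change for an eye
#'
#' Conditional (BLUP-based) prediction of the composite change over `dt`
#' years: `(s + s_i + s_ij) * dt` for eyes in the fit; eyes unseen at fitting
#' time fall back to the population slope `s * dt` and are flagged.
#'
#' @param fit A [fit_progression()] result.
#' @param patient_id,eye Character vectors identifying the eye(s).
#' @param dt Non-negative horizon(s) in years.
#' @return Predicted change in degrees, with attribute
#'   `"population_fallback"` marking predictions for unseen eyes.
#' @export
predict_change <- function(fit, patient_id, eye, dt) {
  stopifnot(inherits(fit, "progression_fit"))
  if (any(dt < 0)) stop("`dt` must be non-negative")
  m <- max(length(patient_id), length(eye), length(dt))
  patient_id <- rep_len(as.character(patient_id), m)
  eye <- rep_len(as.character(eye), m)
  dt <- rep_len(dt, m)
  key <- paste(patient_id, eye, sep = "/")
  fit_key <- paste(fit$conditional_slopes$patient_id,
                   fit$conditional_slopes$eye, sep = "/")
  idx <- match(key, fit_key)
  slope <- fit$conditional_slopes$slope[idx]
  fallback <- is.na(idx)
  if (any(fallback)) {
    warning("eye(s) not in the fit use the population slope: ",
            paste(unique(key[fallback]), collapse = ", "))
    slope[fallback] <- fit$s
  }
  structure(slope * dt, population_fallback = fallback)
}

#' Adjusted residual RMSE over follow-up records
#'
#' Root-mean-square of the conditional residuals over records with
#' `dt_years > 0` only. Baseline records are deterministically zero under the
#' zero-intercept model, so including them would understate the noise; this
#' adjusted RMSE is the noise scale used by the trial simulation.
#'
#' @param fit A [fit_progression()] result.
#' @param deltas Optional table (as for [fit_progression()]) to evaluate on;
#'   defaults to the fit's own training records.
#' @return Adjusted RMSE in degrees.
#' @export
adjusted_rmse <- function(fit, deltas = NULL) {
  stopifnot(inherits(fit, "progression_fit"))
  if (is.null(deltas)) {
    r <- fit$residuals$resid
    if (length(r) == 0) stop("no follow-up records in the fit")
    return(sqrt(mean(r^2)))
  }
  keep <- !is.na(deltas$delta_c) & deltas$dt_years > 0
  if (!any(keep)) stop("no follow-up (dt_years > 0) records with a composite change")
  d <- deltas[keep, , drop = FALSE]
  pred <- suppressWarnings(predict_change(fit, d$patient_id, d$eye, d$dt_years))
  sqrt(mean((d$delta_c - pred)^2))
}
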