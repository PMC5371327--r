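#' Parameters for the synthetic cohort generator
#'
#' Defines the statistical structure of a generated longitudinal cohort:
#' per-biomarker linear progression on the eccentricity scale with patient-
#' and eye-level random slopes, biomarker-specific residual noise at
#' follow-up visits, baseline eccentricities drawn per patient (shared
#' between fellow eyes up to jitter, inducing the between-eye correlation
#' observed clinically) and ellipsoid-zone missingness when the lesion
#' exceeds the scanned half-width. Defaults are the development-cohort
#' conditions; see [cohort_preset()].
#'
#' @param n_patients Number of patients.
#' @param visits_range Integer range of visits per eye, e.g. `c(2, 4)`.
#' @param followup_range Range of total follow-up in years (minimum at least
#'   1 year, the inclusion criterion).
#' @param slopes Named per-biomarker population slopes, degrees/year.
#' @param resid_sd Named per-biomarker residual SDs, degrees.
#' @param sd_patient_slope,sd_eye_slope SDs of the patient- and eye-level
#'   random slope deviations, degrees/year; one deviation is drawn per
#'   patient (and per eye) and shared across biomarkers, modelling the
#'   patient's overall progression rate.
#' @param baseline_range 5 x 2 matrix (rows in [biomarkers()] order) of
#'   baseline eccentricity ranges, degrees.
#' @param baseline_cor Between-eye correlation of baseline eccentricities
#'   (default 0.8).
#' @param ez_scan_halfwidth_deg EZ loss is unmeasurable (missing) beyond this
#'   eccentricity, emulating lesions that outgrow the OCT scan (default 9).
#' @param seed Integer seed.
#' @param cohort_label Label for the generated table.
#' @return A `generator_params` list.
#' @export
generator_params <- function(n_patients = 14,
                             visits_range = c(2L, 4L),
                             followup_range = c(1.13, 9.71),
                             slopes = c(bcva = 0.31, qdaf = 0.32, ddaf = 0.58,
                                        ez = 0.38, elm = 0.34),
                             resid_sd = c(bcva = 3.77, qdaf = 0.14, ddaf = 0.33,
                                          ez = 0.20, elm = 0.17),
                             sd_patient_slope = 0.15,
                             sd_eye_slope = 0.05,
                             baseline_range = rbind(bcva = c(9.85, 24.00),
                                                    qdaf = c(1.68, 7.67),
                                                    ddaf = c(0.00, 5.60),
                                                    ez = c(2.99, 7.83),
                                                    elm = c(2.50, 10.71)),
                             baseline_cor = 0.8,
                             ez_scan_halfwidth_deg = 9,
                             seed = 1,
                             cohort_label = "synthetic") {
  slopes <- slopes[biomarkers()]
  resid_sd <- resid_sd[biomarkers()]
  baseline_range <- baseline_range[biomarkers(), , drop = FALSE]
  stopifnot(n_patients >= 1,
            length(visits_range) == 2, visits_range[1] >= 2,
            visits_range[1] <= visits_range[2],
            length(followup_range) == 2, followup_range[1] >= 1,
            followup_range[1] <= followup_range[2],
            !anyNA(slopes), !anyNA(resid_sd), all(resid_sd >= 0),
            sd_patient_slope >= 0, sd_eye_slope >= 0,
            all(baseline_range[, 1] >= 0),
            all(baseline_range[, 1] <= baseline_range[, 2]),
            baseline_cor > 0, baseline_cor <= 1,
            ez_scan_halfwidth_deg > 0)
  out <- list(n_patients = as.integer(n_patients),
              visits_range = as.integer(visits_range),
              followup_range = followup_range,
              slopes = slopes, resid_sd = resid_sd,
              sd_patient_slope = sd_patient_slope,
              sd_eye_slope = sd_eye_slope,
              baseline_range = baseline_range,
              baseline_cor = baseline_cor,
              ez_scan_halfwidth_deg = ez_scan_halfwidth_deg,
              seed = as.integer(seed),
              cohort_label = cohort_label)
  class(out) <- "generator_params"
  out
}

#' Generator presets for the two study cohorts
#'
#' Returns [generator_params()] matching the published cohort conditions:
#' `"development"` (14 patients, 2-4 visits per eye, follow-up 1.13-9.71
#' years) or `"validation"` (18 patients, 2-6 visits, follow-up 1.0-10.99
#' years, its own baseline ranges). Progression slopes and residual SDs use
#' the development-cohort estimates in both presets.
#'
#' @param label `"development"` or `"validation"`.
#' @param seed Integer seed stored in the preset.
#' @return A `generator_params` object.
#' @export
cohort_preset <- function(label, seed = 1) {
  switch(label,
    development = generator_params(seed = seed, cohort_label = "development"),
    validation = generator_params(
      n_patients = 18,
      visits_range = c(2L, 6L),
      followup_range = c(1.00, 10.99),
      baseline_range = rbind(bcva = c(6.31, 18.94),
                             qdaf = c(1.44, 9.98),
                             ddaf = c(0.00, 6.41),
                             ez = c(3.86, 8.58),
                             elm = c(2.06, 7.71)),
      seed = seed, cohort_label = "validation"),
    stop("unknown cohort preset '", label,
         "'; expected \"development\" or \"validation\"")
  )
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws a cohort with the generative structure the progression model
#' assumes: for each biomarker, eccentricity follows
#' `baseline + (slope + s_i + s_ij) * t` with residual noise at follow-up
#' visits (baseline visits are measured exactly, matching the change-from-
#' baseline model in which baseline residuals are identically zero), floored
#' at 0 degrees. Fellow eyes share the patient-level baseline draw up to
#' jitter and share visit dates. Eccentricities are converted back to raw
#' clinical units (decimal acuity, mm^2 areas, mm transverse losses) so the
#' table exercises the full standardization path, and EZ loss is set missing
#' whenever its eccentricity exceeds the scanned half-width.
#'
#' The generating truth (internal eccentricities and per-eye slopes) is
#' attached as attribute `"truth"` for parameter-recovery checks.
#'
#' @param params A [generator_params()] object.
#' @return A [cohort_table()]; same seed gives a byte-identical table.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  set.seed(params$seed)
  bms <- biomarkers()
  rho <- params$baseline_cor
  rows <- vector("list", params$n_patients)
  truth_rows <- vector("list", params$n_patients)
  slope_rows <- vector("list", params$n_patients)
  n_floored <- 0L

  for (i in seq_len(params$n_patients)) {
    id <- sprintf("P%02d", i)
    nv <- params$visits_range[1] +
      sample.int(params$visits_range[2] - params$visits_range[1] + 1L, 1L) - 1L
    total <- stats::runif(1, params$followup_range[1], params$followup_range[2])
    times <- c(0, if (nv > 2) sort(stats::runif(nv - 2, 0.25 * total, 0.95 * total)),
               total)

    # one slope deviation per patient and per eye, shared across biomarkers:
    # it represents the patient's overall progression rate, so the weighted
    # composite itself follows the single-random-slope model exactly
    pdev <- stats::rnorm(1, 0, params$sd_patient_slope)
    edev <- stats::rnorm(2, 0, params$sd_eye_slope)
    base_eye <- matrix(NA_real_, 2, 5, dimnames = list(c("OD", "OS"), bms))
    slope_eye <- matrix(NA_real_, 2, 5, dimnames = list(c("OD", "OS"), bms))
    for (b in seq_along(bms)) {
      lo <- params$baseline_range[b, 1]
      hi <- params$baseline_range[b, 2]
      pb <- stats::runif(1, lo, hi)
      jit_sd <- if (rho < 1 && hi > lo) {
        sqrt((hi - lo)^2 / 12 * (1 - rho) / rho)
      } else 0
      be <- pmax(pb + stats::rnorm(2, 0, jit_sd), 0)
      base_eye[, b] <- be
      slope_eye[, b] <- params$slopes[b] + pdev + edev
    }

    for (e in 1:2) {
      eye <- c("OD", "OS")[e]
      eps <- matrix(NA_real_, length(times), 5, dimnames = list(NULL, bms))
      for (b in seq_along(bms)) {
        noise <- c(0, stats::rnorm(length(times) - 1, 0, params$resid_sd[b]))
        val <- base_eye[e, b] + slope_eye[e, b] * times + noise
        n_floored <- n_floored + sum(val < 0)
        eps[, b] <- pmax(val, 0)
      }
      ez_missing <- eps[, "ez"] > params$ez_scan_halfwidth_deg
      rows[[i]] <- c(rows[[i]], list(tibble::tibble(
        patient_id = id, eye = eye, t_years = times,
        bcva = bcva_from_ecc(eps[, "bcva"]),
        qdaf_area_mm2 = area_from_ecc(eps[, "qdaf"]),
        ddaf_area_mm2 = area_from_ecc(eps[, "ddaf"]),
        ez_loss_mm = ifelse(ez_missing, NA_real_,
                            transverse_from_ecc(eps[, "ez"])),
        elm_loss_mm = transverse_from_ecc(eps[, "elm"])
      )))
      truth_rows[[i]] <- c(truth_rows[[i]], list(tibble::tibble(
        patient_id = id, eye = eye, t_years = times,
        eps_bcva = eps[, "bcva"], eps_qdaf = eps[, "qdaf"],
        eps_ddaf = eps[, "ddaf"], eps_ez = eps[, "ez"],
        eps_elm = eps[, "elm"]
      )))
      slope_rows[[i]] <- c(slope_rows[[i]], list(tibble::tibble(
        patient_id = id, eye = eye,
        slope_bcva = slope_eye[e, "bcva"], slope_qdaf = slope_eye[e, "qdaf"],
        slope_ddaf = slope_eye[e, "ddaf"], slope_ez = slope_eye[e, "ez"],
        slope_elm = slope_eye[e, "elm"]
      )))
    }
  }

  tab <- do.call(rbind, lapply(rows, function(x) do.call(rbind, x)))
  out <- cohort_table(tab, cohort_label = params$cohort_label)
  attr(out, "truth") <- list(
    params = params,
    eps = do.call(rbind, lapply(truth_rows, function(x) do.call(rbind, x))),
    slopes = do.call(rbind, lapply(slope_rows, function(x) do.call(rbind, x))),
    n_floored = n_floored
  )
  out
}
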