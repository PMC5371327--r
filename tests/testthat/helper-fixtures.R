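# Deterministic fixtures built in code.

# Minimal noise-free eccentricity table: each eye progresses linearly in
# every biomarker at `slope` deg/year from the given baselines.
noise_free_ecc <- function(slope = 0.5, n_patients = 3,
                           times = c(0, 1, 2.5)) {
  rows <- list()
  for (i in seq_len(n_patients)) {
    for (eye in c("OD", "OS")) {
      base <- c(10, 4, 2, 3.5, 5) + i * 0.3
      for (t in times) {
        eps <- base + slope * t
        rows[[length(rows) + 1]] <- tibble::tibble(
          patient_id = sprintf("P%02d", i), eye = eye, t_years = t,
          eps_bcva = eps[1], eps_qdaf = eps[2], eps_ddaf = eps[3],
          eps_ez = eps[4], eps_elm = eps[5]
        )
      }
    }
  }
  do.call(rbind, rows)
}

# Small cohort CSV written to a temp file, returned as the path.
write_fixture_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

cohort_header <- paste("patient_id,eye,t_years,bcva,qdaf_area_mm2,",
                       "ddaf_area_mm2,ez_loss_mm,elm_loss_mm", sep = "")

# Development-preset synthetic pipeline up to the delta table, cached per
# seed within a test file run.
dev_deltas <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 42) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) {
      co <- generate_cohort(cohort_preset("development", seed = seed))
      cache[[key]] <- deltas_from_baseline(visit_to_ecc(co))
    }
    cache[[key]]
  }
})

# A hand-built progression fit with prescribed conditional slopes, for
# simulation tests that need full control of the generative truth.
manual_fit <- function(slopes_by_eye, s = mean(slopes_by_eye$slope),
                       rmse = 0.13) {
  fit <- list(
    s = s, se_s = 0, ci_s = c(s, s),
    sd_patient = 0, sd_eye = 0, rmse = rmse,
    conditional_slopes = slopes_by_eye,
    n_obs = nrow(slopes_by_eye), n_patients = length(unique(slopes_by_eye$patient_id)),
    n_eyes = nrow(slopes_by_eye), logLik = NA_real_, method = "REML",
    theta = c(0, 0), pinned = c(FALSE, FALSE),
    residuals = tibble::tibble(patient_id = character(0), eye = character(0),
                               dt_years = numeric(0), delta_c = numeric(0),
                               fitted = numeric(0), resid = numeric(0))
  )
  class(fit) <- "progression_fit"
  fit
}
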