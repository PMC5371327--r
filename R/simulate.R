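#' Specify a simulated interventional trial
#'
#' Captures the design of a Monte-Carlo power analysis: a cohort of patients
#' followed for `follow_up_years` after their last observed visit, with one
#' eye per patient treated. In the paired design the fellow eye is the
#' within-patient control and a two-sided paired t-test is used; in the
#' non-paired design patients are randomized 1:1 to treatment vs observation,
#' one eye per patient enters the analysis, and a two-sided pooled two-sample
#' t-test is used.
#'
#' @param n_patients Number of patients (default 14).
#' @param follow_up_years Trial duration in years (default 2).
#' @param paired Fellow-eye control design (default `TRUE`).
#' @param assignment `"random_bernoulli"` (treated eye drawn per patient each
#'   replicate) or `"worse_eye_treated"` (the eye with the larger baseline
#'   composite eccentricity is always treated).
#' @param endpoint Label of the endpoint the supplied fit represents; carried
#'   through to outputs.
#' @param alpha Two-sided significance level (default 0.05).
#' @param effect_sizes Proportional treatment effects to sweep (default 0 to
#'   1 by 0.05); each treated eye's predicted increment is reduced by
#'   `effect * increment`.
#' @param n_sims Monte-Carlo replicates per effect size (default 10,000).
#' @param seed Integer seed; every random draw derives from it.
#' @param noise `"gaussian"` draws the residual of each simulated increment
#'   as `N(0, adjusted_rmse^2)` (default); `"rademacher"` uses the literal
#'   plus-or-minus `adjusted_rmse` with equal probability.
#' @return A `trial_design` list.
#' @export
trial_design <- function(n_patients = 14, follow_up_years = 2, paired = TRUE,
                         assignment = c("random_bernoulli", "worse_eye_treated"),
                         endpoint = "optimal_weighted", alpha = 0.05,
                         effect_sizes = seq(0, 1, by = 0.05), n_sims = 10000,
                         seed = 1, noise = c("gaussian", "rademacher")) {
  assignment <- match.arg(assignment)
  noise <- match.arg(noise)
  stopifnot(n_patients >= 2, follow_up_years > 0,
            alpha > 0, alpha < 1, n_sims >= 1,
            all(effect_sizes >= 0), all(effect_sizes <= 1))
  out <- list(n_patients = as.integer(n_patients),
              follow_up_years = follow_up_years, paired = isTRUE(paired),
              assignment = assignment, endpoint = endpoint, alpha = alpha,
              effect_sizes = effect_sizes, n_sims = as.integer(n_sims),
              seed = as.integer(seed), noise = noise)
  class(out) <- "trial_design"
  out
}

#' Monte-Carlo power of a simulated trial
#'
#' For each replicate, every eye's change over the trial period is simulated
#' as its conditional predicted increment (BLUP slope times follow-up) plus
#' independent residual noise with SD `adjusted_rmse`; the treated eye's
#' increment is additionally reduced by `effect` times its predicted
#' increment. Rejections of the two-sided t-test at `alpha` are tallied over
#' replicates; power is the rejection fraction and its Monte-Carlo standard
#' error is `sqrt(p (1 - p) / n_sims)`. Replicates with a degenerate test
#' statistic (zero variance) count as non-rejections and are tallied.
#'
#' @param fit A [fit_progression()] result for the chosen endpoint.
#' @param adjusted_rmse Residual noise SD in degrees (see [adjusted_rmse()]).
#' @param design A [trial_design()].
#' @param baseline Data frame with `patient_id`, `eye`, `value` (baseline
#'   composite eccentricity, degrees); required for the
#'   `"worse_eye_treated"` assignment.
#' @return A `power_curve` tibble: `effect_size`, `power`, `mc_se`,
#'   `rejections`, `n_sims`, `degenerate`.
#' @export
simulate_trial <- function(fit, adjusted_rmse, design, baseline = NULL) {
  stopifnot(inherits(fit, "progression_fit"), inherits(design, "trial_design"),
            is.numeric(adjusted_rmse), adjusted_rmse >= 0)
  eyes <- eye_layout(fit, design, baseline)
  np <- nrow(eyes)
  x <- design$follow_up_years
  mu1 <- eyes$slope1 * x
  mu2 <- eyes$slope2 * x
  ns <- design$n_sims

  res <- lapply(seq_along(design$effect_sizes), function(k) {
    e <- design$effect_sizes[k]
    set.seed((design$seed + 7919L * k) %% 2147483647L)
    if (design$assignment == "random_bernoulli") {
      B <- matrix(stats::rbinom(np * ns, 1L, 0.5), np, ns)
    } else {
      B <- matrix(rep(eyes$eye1_worse, ns), np, ns)
    }
    N1 <- noise_matrix(np, ns, adjusted_rmse, design$noise)
    N2 <- noise_matrix(np, ns, adjusted_rmse, design$noise)
    treated_mu <- B * mu1 + (1 - B) * mu2
    control_mu <- B * mu2 + (1 - B) * mu1
    treated_noise <- B * N1 + (1 - B) * N2
    control_noise <- B * N2 + (1 - B) * N1

    if (design$paired) {
      diffs <- (treated_mu * (1 - e) + treated_noise) -
        (control_mu + control_noise)
      m <- colMeans(diffs)
      v <- (colSums(diffs^2) - np * m^2) / (np - 1)
      ok <- v > 0
      tstat <- ifelse(ok, m / sqrt(v / np), 0)
      p <- ifelse(ok, 2 * stats::pt(-abs(tstat), np - 1), 1)
    } else {
      n1 <- np %/% 2L
      n0 <- np - n1
      U <- matrix(stats::runif(np * ns), np, ns)
      Tm <- apply(U, 2, function(u) as.numeric(rank(u, ties.method = "first") <= n1))
      y <- treated_mu * (1 - e * Tm) + treated_noise
      m1 <- colSums(y * Tm) / n1
      m0 <- colSums(y * (1 - Tm)) / n0
      ss <- colSums(y^2 * Tm) - n1 * m1^2 + colSums(y^2 * (1 - Tm)) - n0 * m0^2
      v <- ss / (np - 2)
      ok <- v > 0
      tstat <- ifelse(ok, (m1 - m0) / sqrt(v * (1 / n1 + 1 / n0)), 0)
      p <- ifelse(ok, 2 * stats::pt(-abs(tstat), np - 2), 1)
    }
    rej <- sum(p < design$alpha)
    pw <- rej / ns
    c(power = pw, mc_se = sqrt(pw * (1 - pw) / ns), rejections = rej,
      degenerate = sum(!ok))
  })
  res <- do.call(rbind, res)
  out <- tibble::tibble(
    effect_size = design$effect_sizes,
    power = res[, "power"],
    mc_se = res[, "mc_se"],
    rejections = as.integer(res[, "rejections"]),
    n_sims = ns,
    degenerate = as.integer(res[, "degenerate"])
  )
  class(out) <- c("power_curve", class(out))
  attr(out, "design") <- design
  out
}

noise_matrix <- function(np, ns, sd, kind) {
  if (kind == "gaussian") {
    matrix(stats::rnorm(np * ns, 0, sd), np, ns)
  } else {
    matrix(sd * (2 * stats::rbinom(np * ns, 1L, 0.5) - 1), np, ns)
  }
}

# one row per patient with both eyes' conditional slopes; patients with a
# single fitted eye cannot enter a paired-eye simulation and are dropped
eye_layout <- function(fit, design, baseline) {
  cs <- fit$conditional_slopes
  cs <- cs[order(cs$patient_id, cs$eye), ]
  split_cs <- split(cs, cs$patient_id)
  two <- vapply(split_cs, nrow, integer(1)) == 2L
  if (any(!two)) {
    warning("dropping ", sum(!two), " patient(s) without two fitted eyes")
    split_cs <- split_cs[two]
  }
  if (length(split_cs) < 2) stop("need at least 2 patients with two fitted eyes")
  if (design$n_patients > length(split_cs)) {
    stop("design asks for ", design$n_patients, " patients but only ",
         length(split_cs), " are available in the fit")
  }
  split_cs <- split_cs[seq_len(design$n_patients)]
  eyes <- tibble::tibble(
    patient_id = names(split_cs),
    eye1 = vapply(split_cs, function(d) d$eye[1], character(1)),
    eye2 = vapply(split_cs, function(d) d$eye[2], character(1)),
    slope1 = vapply(split_cs, function(d) d$slope[1], numeric(1)),
    slope2 = vapply(split_cs, function(d) d$slope[2], numeric(1))
  )
  if (design$assignment == "worse_eye_treated") {
    if (is.null(baseline)) {
      stop("`baseline` (patient_id, eye, value) is required for worse_eye_treated")
    }
    bkey <- paste(baseline$patient_id, baseline$eye, sep = "/")
    v1 <- baseline$value[match(paste(eyes$patient_id, eyes$eye1, sep = "/"), bkey)]
    v2 <- baseline$value[match(paste(eyes$patient_id, eyes$eye2, sep = "/"), bkey)]
    if (anyNA(v1) || anyNA(v2)) stop("baseline values missing for some fitted eyes")
    eyes$eye1_worse <- as.numeric(v1 >= v2)
  } else {
    eyes$eye1_worse <- NA_real_
  }
  eyes
}

#' Power curves for a set of trial scenarios
#'
#' Runs [simulate_trial()] for the standard design variants of the paired
#' two-year trial — worse eye treated, one-year follow-up, unweighted
#' structural composite, non-paired design, acuity-only endpoint — using a
#' shared seed so the curves are comparable.
#'
#' @param fits Named list; each element is `list(fit =, adjusted_rmse =)`.
#'   The default scenario set expects names `optimal_weighted` and, when the
#'   corresponding scenarios are requested, `unweighted_structural` and
#'   `bcva_only`.
#' @param design Base [trial_design()] (paired, two-year).
#' @param scenarios Subset of `c("optimal_paired", "worse_eye_treated",
#'   "one_year", "unweighted_structural", "non_paired", "bcva_only")`.
#' @param baseline Passed to [simulate_trial()] for the worse-eye scenario.
#' @return A tibble of power curves with a `scenario` column.
#' @export
power_scenarios <- function(fits, design,
                            scenarios = c("optimal_paired", "worse_eye_treated",
                                          "one_year", "unweighted_structural",
                                          "non_paired", "bcva_only"),
                            baseline = NULL) {
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  endpoint_for <- function(sc) {
    switch(sc,
           unweighted_structural = "unweighted_structural",
           bcva_only = "bcva_only",
           "optimal_weighted")
  }
  out <- lapply(scenarios, function(sc) {
    ep <- endpoint_for(sc)
    if (is.null(fits[[ep]])) {
      stop("missing endpoint fit '", ep, "' for scenario '", sc, "'")
    }
    d <- design
    d$endpoint <- ep
    if (sc == "worse_eye_treated") d$assignment <- "worse_eye_treated"
    if (sc == "one_year") d$follow_up_years <- 1
    if (sc == "non_paired") d$paired <- FALSE
    pc <- simulate_trial(fits[[ep]]$fit, fits[[ep]]$adjusted_rmse, d,
                         baseline = baseline)
    pc$scenario <- sc
    pc
  })
  do.call(rbind, out)
}

#' Closed-form power of the paired t-test
#'
#' Exact power of the two-sided one-sample (paired-difference) t-test for a
#' normal difference with the given mean and SD, via the noncentral t
#' distribution. Used as the analytic check on the Monte-Carlo simulation.
#'
#' @param mean_diff,sd_diff Mean and SD of the per-patient difference.
#' @param n Number of pairs.
#' @param alpha Two-sided significance level.
#' @return Power in `[0, 1]`.
#' @export
paired_t_power <- function(mean_diff, sd_diff, n, alpha = 0.05) {
  stopifnot(sd_diff > 0, n >= 2)
  ncp <- mean_diff / (sd_diff / sqrt(n))
  tc <- stats::qt(1 - alpha / 2, n - 1)
  1 - stats::pt(tc, n - 1, ncp) + stats::pt(-tc, n - 1, ncp)
}
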