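# a 14-patient fit with mildly asymmetric fellow eyes, built by hand so the
# generative truth of the simulation is fully known
sim_fit <- function(base = 0.37, spread = 0.08, asym = 0.03) {
  set.seed(99)
  pid <- sprintf("P%02d", 1:14)
  ps <- base + rnorm(14, 0, spread)
  tibble::tibble(
    patient_id = rep(pid, each = 2),
    eye = rep(c("OD", "OS"), 14),
    slope = as.numeric(rbind(ps + rnorm(14, 0, asym), ps + rnorm(14, 0, asym)))
  )
}

test_that("null effect is calibrated to alpha and noiseless effects are certain", {
  fit <- manual_fit(sim_fit())
  des <- trial_design(effect_sizes = c(0, 0.5), n_sims = 4000, seed = 3)
  pc <- simulate_trial(fit, adjusted_rmse = 0.1, des)
  # effect 0: power within 3 MC SEs of alpha
  se0 <- sqrt(0.05 * 0.95 / 4000)
  expect_lt(abs(pc$power[1] - 0.05), 3 * se0)
  # vanishing noise with a positive effect: power -> 1
  pc0 <- simulate_trial(fit, adjusted_rmse = 1e-9, des)
  expect_equal(pc0$power[2], 1)
})

test_that("identical seed and design reproduce the curve bit-exactly", {
  fit <- manual_fit(sim_fit())
  des <- trial_design(effect_sizes = seq(0, 1, 0.25), n_sims = 500, seed = 11)
  expect_identical(simulate_trial(fit, 0.13, des),
                   simulate_trial(fit, 0.13, des))
  # the rademacher (literal plus-minus) noise reading also runs
  desr <- trial_design(effect_sizes = c(0.25), n_sims = 500, seed = 11,
                       noise = "rademacher")
  pr <- simulate_trial(fit, 0.13, desr)
  expect_true(pr$power >= 0 && pr$power <= 1)
})

test_that("power is monotone in effect size within Monte-Carlo error", {
  fit <- manual_fit(sim_fit())
  des <- trial_design(effect_sizes = seq(0, 1, 0.2), n_sims = 3000, seed = 5)
  pc <- simulate_trial(fit, 0.13, des)
  slack <- 3 * sqrt(pmax(pc$power * (1 - pc$power), 0.25 / pc$n_sims) / pc$n_sims)
  expect_true(all(diff(pc$power) >= -(slack[-1] + slack[-length(slack)])))
})

test_that("design variants order as expected", {
  fit <- manual_fit(sim_fit())
  des <- trial_design(effect_sizes = 0.25, n_sims = 4000, seed = 7)
  paired <- simulate_trial(fit, 0.13, des)
  # non-paired design discards the between-eye correlation
  desu <- des; desu$paired <- FALSE
  unpaired <- simulate_trial(fit, 0.13, desu)
  expect_gte(paired$power + 3 * paired$mc_se + 3 * unpaired$mc_se,
             unpaired$power)
  expect_gt(paired$power, unpaired$power)
  # shorter follow-up, same noise: less signal
  des1 <- des; des1$follow_up_years <- 1
  oneyr <- simulate_trial(fit, 0.13, des1)
  expect_lte(oneyr$power, paired$power + 3 * (oneyr$mc_se + paired$mc_se))
  expect_lt(oneyr$power, paired$power)
})

test_that("simulated paired-t power matches the closed form for homogeneous slopes", {
  # all eyes share the slope, so the per-patient difference is exactly
  # N(-effect * slope * x, 2 * rmse^2): analytic noncentral-t oracle
  slopes <- tibble::tibble(patient_id = rep(sprintf("P%02d", 1:14), each = 2),
                           eye = rep(c("OD", "OS"), 14), slope = 0.4)
  fit <- manual_fit(slopes, s = 0.4)
  adj <- 0.13
  des <- trial_design(effect_sizes = c(0.15, 0.3), n_sims = 10000, seed = 21)
  pc <- simulate_trial(fit, adj, des)
  for (i in seq_len(nrow(pc))) {
    analytic <- paired_t_power(mean_diff = -pc$effect_size[i] * 0.4 * 2,
                               sd_diff = sqrt(2) * adj, n = 14)
    expect_lt(abs(pc$power[i] - analytic), 3 * max(pc$mc_se[i], 1e-3))
  }
})

test_that("worse-eye assignment and scenario table behave", {
  fit <- manual_fit(sim_fit())
  baseline <- tibble::tibble(
    patient_id = fit$conditional_slopes$patient_id,
    eye = fit$conditional_slopes$eye,
    value = rep(c(5, 4), 14)  # OD always worse
  )
  des <- trial_design(effect_sizes = c(0, 0.25), n_sims = 1000, seed = 13,
                      assignment = "worse_eye_treated")
  pc <- simulate_trial(fit, 0.13, des, baseline = baseline)
  expect_true(all(pc$power >= 0 & pc$power <= 1))
  expect_error(simulate_trial(fit, 0.13, des), "baseline")

  fits <- list(
    optimal_weighted = list(fit = fit, adjusted_rmse = 0.13),
    unweighted_structural = list(fit = fit, adjusted_rmse = 0.30)
  )
  base_des <- trial_design(effect_sizes = 0.25, n_sims = 2000, seed = 17)
  tab <- power_scenarios(fits, base_des,
                         scenarios = c("optimal_paired", "one_year",
                                       "unweighted_structural"))
  expect_equal(tab$scenario,
               c("optimal_paired", "one_year", "unweighted_structural"))
  # noisier unweighted endpoint loses power at matched effect
  expect_lt(tab$power[tab$scenario == "unweighted_structural"],
            tab$power[tab$scenario == "optimal_paired"])
  expect_error(power_scenarios(fits, base_des, scenarios = "bcva_only"),
               "missing endpoint fit")
})
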