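test_that("noise-free common-slope data give an exact degenerate fit", {
  ecc <- noise_free_ecc(slope = 0.5)
  dc <- composite_deltas(deltas_from_baseline(ecc), optimal_weights())
  fit <- suppressWarnings(fit_progression(dc))
  expect_equal(fit$s, 0.5, tolerance = 1e-9)
  expect_equal(fit$sd_patient, 0, tolerance = 1e-6)
  expect_equal(fit$sd_eye, 0, tolerance = 1e-6)
  expect_equal(fit$rmse, 0, tolerance = 1e-6)
  expect_equal(adjusted_rmse(fit), 0, tolerance = 1e-6)
  # predictions: zero at dt = 0, exactly 2x the slope at dt = 2
  expect_equal(as.numeric(predict_change(fit, "P01", "OD", 0)), 0)
  expect_equal(as.numeric(predict_change(fit, "P01", "OD", 2)), 1.0,
               tolerance = 1e-9)
})

test_that("the REML fitter agrees with lme4 on a synthetic cohort", {
  dc <- composite_deltas(dev_deltas(42), optimal_weights())
  fit <- suppressWarnings(fit_progression(dc))
  d <- dc[!is.na(dc$delta_c) & dc$dt_years > 0, ]
  d$eid <- paste(d$patient_id, d$eye)
  lf <- lme4::lmer(delta_c ~ 0 + dt_years + (0 + dt_years | patient_id) +
                     (0 + dt_years | eid), data = d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit$s, unname(lme4::fixef(lf)), tolerance = 1e-5)
  expect_equal(fit$se_s, sqrt(as.numeric(vcov(lf)[1, 1])), tolerance = 1e-4)
  expect_equal(fit$sd_patient, vc$sdcor[vc$grp == "patient_id"], tolerance = 1e-4)
  expect_equal(fit$sd_eye, vc$sdcor[vc$grp == "eid"], tolerance = 1e-4)
  expect_equal(fit$rmse, stats::sigma(lf), tolerance = 1e-4)
  # conditional slopes match lme4's BLUPs
  bl <- lme4::ranef(lf)
  ours <- fit$conditional_slopes
  lme4_slope <- lme4::fixef(lf) +
    bl$patient_id[ours$patient_id, 1] +
    bl$eid[paste(ours$patient_id, ours$eye), 1]
  expect_equal(ours$slope, unname(lme4_slope), tolerance = 1e-4)
})

test_that("fit scales equivariantly and MSDR is scale invariant", {
  dc <- composite_deltas(dev_deltas(42), optimal_weights())
  f1 <- suppressWarnings(fit_progression(dc))
  dck <- dc
  dck$delta_c <- 3.7 * dck$delta_c
  f2 <- suppressWarnings(fit_progression(dck))
  expect_equal(f2$s, 3.7 * f1$s, tolerance = 1e-6)
  expect_equal(f2$rmse, 3.7 * f1$rmse, tolerance = 1e-5)
  expect_equal(msdr(f2)$msdr, msdr(f1)$msdr, tolerance = 1e-5)
})

test_that("conditional residuals average to zero and likelihoods nest", {
  dc <- composite_deltas(dev_deltas(42), optimal_weights())
  fit <- suppressWarnings(fit_progression(dc))
  expect_lt(abs(mean(fit$residuals$resid)),
            2 * fit$rmse / sqrt(fit$n_obs) + 1e-8)
  # restricted likelihood at the optimum is at least that of the slope-only
  # model (variance ratios pinned at zero), computed in closed form
  d <- dc[!is.na(dc$delta_c) & dc$dt_years > 0, ]
  y <- d$delta_c; t <- d$dt_years; n <- length(y)
  s0 <- sum(t * y) / sum(t * t)
  sig0 <- sum((y - s0 * t)^2) / (n - 1)
  ll0 <- -0.5 * ((n - 1) * log(2 * pi * sig0) + log(sum(t * t)) + (n - 1))
  expect_gte(fit$logLik, ll0 - 1e-8)
})

test_that("msdr handles the degenerate residual cases", {
  flat <- manual_fit(tibble::tibble(patient_id = c("A", "A"),
                                    eye = c("OD", "OS"), slope = c(0, 0)),
                     s = 0, rmse = 0.2)
  expect_equal(msdr(flat)$msdr, 0)
  exact <- manual_fit(tibble::tibble(patient_id = c("A", "A"),
                                     eye = c("OD", "OS"), slope = c(1, 1)),
                      s = 1, rmse = 0)
  expect_true(msdr(exact)$infinite)
  expect_equal(msdr(exact)$msdr, Inf)
})

test_that("predictions fall back to the population slope for unseen eyes", {
  dc <- composite_deltas(dev_deltas(42), optimal_weights())
  fit <- suppressWarnings(fit_progression(dc))
  expect_warning(p <- predict_change(fit, "NOPE", "OD", 2), "population")
  expect_equal(as.numeric(p), fit$s * 2)
  expect_true(attr(p, "population_fallback"))
  expect_error(predict_change(fit, "P01", "OD", -1), "non-negative")
})

test_that("BLUP prediction error shrinks with more visits per eye", {
  # simulated truth oracle: eyes with known random effects, conditional
  # slope estimates should approach the simulated eye slope as replication
  # grows
  err <- sapply(c(2L, 6L), function(nv) {
    e <- numeric(25)
    for (r in 1:25) {
      p <- generator_params(n_patients = 10, visits_range = c(nv, nv),
                            seed = 5000 + r)
      co <- generate_cohort(p)
      truth <- attr(co, "truth")$slopes
      dc <- composite_deltas(deltas_from_baseline(visit_to_ecc(co)),
                             c(0, 1, 0, 0, 0))
      fit <- suppressWarnings(fit_progression(dc, warn_pinned = FALSE))
      m <- merge(fit$conditional_slopes, truth, by = c("patient_id", "eye"))
      e[r] <- mean(abs(m$slope - m$slope_qdaf))
    }
    mean(e)
  })
  expect_lt(err[2], err[1])
})

test_that("adjusted RMSE has its closed forms and recovers the truth", {
  # residuals {+r, -r} -> r
  f <- manual_fit(tibble::tibble(patient_id = c("A", "A"), eye = c("OD", "OS"),
                                 slope = c(0.4, 0.4)))
  f$residuals <- tibble::tibble(patient_id = c("A", "A"), eye = c("OD", "OS"),
                                dt_years = c(1, 1), delta_c = c(1, 1),
                                fitted = c(1 - 0.3, 1 + 0.3),
                                resid = c(0.3, -0.3))
  expect_equal(adjusted_rmse(f), 0.3)
  # simulation-truth oracle: with rich per-eye replication the conditional
  # residual RMS approaches the generating residual SD (within 15%)
  vals <- sapply(1:10, function(s) {
    p <- generator_params(n_patients = 20, visits_range = c(4L, 6L), seed = s)
    co <- generate_cohort(p)
    dc <- composite_deltas(deltas_from_baseline(visit_to_ecc(co)),
                           c(0, 1, 0, 0, 0))
    fit <- suppressWarnings(fit_progression(dc, warn_pinned = FALSE))
    expect_gte(nrow(fit$residuals), 50)
    adjusted_rmse(fit)
  })
  expect_lt(abs(mean(vals) - 0.14) / 0.14, 0.15)
})

test_that("eye-level variance is detected as null when absent", {
  p <- generator_params(n_patients = 24, visits_range = c(3L, 5L),
                        sd_eye_slope = 0, seed = 9)
  co <- generate_cohort(p)
  dc <- composite_deltas(deltas_from_baseline(visit_to_ecc(co)),
                         c(0, 1, 0, 0, 0))
  fit <- suppressWarnings(fit_progression(dc, warn_pinned = FALSE))
  expect_lt(fit$sd_eye, 0.05)
})
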