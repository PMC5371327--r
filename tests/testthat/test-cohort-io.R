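test_that("read_cohort parses the documented schema including Snellen acuity", {
  path <- write_fixture_csv(c(
    cohort_header,
    "P9,OD,0.0,20/100,1.37,0.33,2.24,1.75",
    "P9,OD,1.5,0.15,2.10,0.50,2.80,2.10",
    "P9,OS,0.0,0.2,1.00,0.20,,1.50"
  ))
  co <- read_cohort(path)
  expect_s3_class(co, "cohort_table")
  expect_equal(co$bcva[co$eye == "OD" & co$t_years == 0], 0.2)
  expect_equal(co$qdaf_area_mm2[1], 1.37)
  expect_true(is.na(co$ez_loss_mm[co$eye == "OS"]))
})

test_that("write_cohort / read_cohort round-trips validated tables", {
  co <- generate_cohort(cohort_preset("development", seed = 3))
  path <- tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path, cohort_label = attr(co, "cohort_label"))
  expect_identical(back$patient_id, co$patient_id)
  expect_identical(back$eye, co$eye)
  for (col in c("t_years", "bcva", "qdaf_area_mm2", "ddaf_area_mm2",
                "ez_loss_mm", "elm_loss_mm")) {
    expect_equal(back[[col]], co[[col]], tolerance = 1e-9)
  }
})

test_that("malformed input is rejected with row-level diagnostics", {
  expect_error(read_cohort(write_fixture_csv(cohort_header)), "no records")
  # duplicate (patient, eye, time)
  dup <- write_fixture_csv(c(
    cohort_header,
    "P1,OD,0,0.2,1,0.3,2,1.5",
    "P1,OD,0,0.3,1,0.3,2,1.5"
  ))
  expect_error(read_cohort(dup), "duplicate")
  # malformed numeric cell names its row
  bad <- write_fixture_csv(c(
    cohort_header,
    "P1,OD,0,0.2,oops,0.3,2,1.5"
  ))
  expect_error(read_cohort(bad), "row\\(s\\): 1")
  # eye without a baseline visit
  nob <- write_fixture_csv(c(
    cohort_header,
    "P1,OD,1.0,0.2,1,0.3,2,1.5"
  ))
  expect_error(read_cohort(nob), "baseline")
  # non-numeric acuity categories are rejected, not imputed
  expect_error(parse_bcva(c("20/100", "CF")), "unparseable")
  expect_equal(parse_bcva(c("20/100", "0.5", "")), c(0.2, 0.5, NA))
})

test_that("a baseline-only cohort validates but cannot be fit", {
  path <- write_fixture_csv(c(
    cohort_header,
    "P1,OD,0,0.2,1,0.3,2,1.5",
    "P1,OS,0,0.2,1,0.3,2,1.5",
    "P2,OD,0,0.3,2,0.5,3,2.0",
    "P2,OS,0,0.3,2,0.5,3,2.0"
  ))
  co <- read_cohort(path)
  expect_s3_class(co, "cohort_table")
  dc <- composite_deltas(deltas_from_baseline(visit_to_ecc(co)),
                         optimal_weights())
  expect_error(fit_progression(dc), "follow-up")
})

test_that("reconcile_graders averages and flags discrepancies beyond 1 degree", {
  p <- data.frame(label = c("QDAF", "DDAF", "EZ"),
                  value_a_deg = c(4.0, 4.0, 2.2),
                  value_b_deg = c(4.2, 5.5, 2.2))
  r <- reconcile_graders(p)
  expect_equal(r$mean_deg, c(4.1, 4.75, 2.2))
  expect_equal(r$needs_consensus, c(FALSE, TRUE, FALSE))
  # symmetric in (a, b)
  swapped <- reconcile_graders(data.frame(label = p$label,
                                          value_a_deg = p$value_b_deg,
                                          value_b_deg = p$value_a_deg))
  expect_equal(swapped$mean_deg, r$mean_deg)
  expect_equal(swapped$needs_consensus, r$needs_consensus)
  expect_error(reconcile_graders(data.frame(label = "EZ", value_a_deg = -1,
                                            value_b_deg = 1)), ">= 0")
  expect_error(reconcile_graders(p, threshold_deg = 0))
})

test_that("agreement_stats matches a two-way ANOVA decomposition oracle", {
  # fixed 5-pair fixture; oracle: aov() mean squares + the ICC(A,1) formula
  a <- c(1.2, 3.4, 2.2, 5.0, 4.1)
  b <- c(1.5, 3.1, 2.6, 4.8, 4.5)
  y <- c(a, b)
  subj <- factor(rep(1:5, 2))
  rater <- factor(rep(c("a", "b"), each = 5))
  ms <- summary(stats::aov(y ~ subj + rater))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  icc_oracle <- (msr - mse) / (msr + mse + (2 / 5) * (msc - mse))
  s <- agreement_stats(data.frame(label = "ELM", value_a_deg = a,
                                  value_b_deg = b))
  expect_equal(s$icc, icc_oracle, tolerance = 1e-12)
  expect_equal(s$mean_abs_diff, mean(abs(a - b)))
  expect_equal(s$sd_abs_diff, sd(abs(a - b)))
  # consistency form oracle on the same fixture
  sc <- agreement_stats(data.frame(label = "ELM", value_a_deg = a,
                                   value_b_deg = b), type = "consistency")
  expect_equal(sc$icc, (msr - mse) / (msr + mse), tolerance = 1e-12)
})

test_that("ICC behaves at the agreement extremes and under shifts", {
  # perfect agreement with between-subject variance
  a <- c(1, 2, 3, 4, 6)
  perf <- agreement_stats(data.frame(label = "EZ", value_a_deg = a,
                                     value_b_deg = a))
  expect_equal(perf$icc, 1)
  expect_equal(perf$mean_abs_diff, 0)
  # grader b independent of grader a (fixed decorrelated fixture) -> near 0
  set.seed(1)
  av <- runif(10, 0, 8)
  bv <- sample(av)  # same marginal, destroyed pairing
  lo <- agreement_stats(data.frame(label = "EZ", value_a_deg = av,
                                   value_b_deg = bv))
  expect_lt(abs(lo$icc), 0.5)
  # invariance to a common constant shift; bounded in [-1, 1]
  sh <- agreement_stats(data.frame(label = "EZ", value_a_deg = av + 5,
                                   value_b_deg = bv + 5))
  expect_equal(sh$icc, lo$icc, tolerance = 1e-10)
  expect_true(all(abs(c(lo$icc, sh$icc, perf$icc)) <= 1))
  # guard rails
  expect_error(agreement_stats(data.frame(label = "EZ", value_a_deg = 1:2,
                                          value_b_deg = 1:2)), "3")
  expect_warning(
    und <- agreement_stats(data.frame(label = "EZ", value_a_deg = rep(2, 4),
                                      value_b_deg = rep(2, 4))),
    class = "retcomp_icc_undefined")
  expect_true(is.na(und$icc))
})
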