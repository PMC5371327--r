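#' Reconcile duplicate grader measurements
#'
#' Two independent graders delineate each lesion; the arithmetic mean of the
#' two measurements is used for analysis, and pairs whose absolute
#' discrepancy exceeds a threshold (default 1 degree) are flagged for
#' consensus review.
#'
#' @param pairs Data frame with columns `label` (one of `QDAF`, `DDAF`, `EZ`,
#'   `ELM`), `value_a_deg` and `value_b_deg` (degrees, non-negative).
#' @param threshold_deg Flagging threshold in degrees, strictly positive.
#' @return A tibble with the input columns plus `mean_deg` and
#'   `needs_consensus`.
#' @export
#' @examples
#' reconcile_graders(data.frame(label = "QDAF", value_a_deg = 4, value_b_deg = 5.5))
reconcile_graders <- function(pairs, threshold_deg = 1.0) {
  pairs <- check_grader_pairs(pairs)
  stopifnot(is.numeric(threshold_deg), length(threshold_deg) == 1L,
            threshold_deg > 0)
  out <- tibble::as_tibble(pairs)
  out$mean_deg <- (out$value_a_deg + out$value_b_deg) / 2
  out$needs_consensus <- abs(out$value_a_deg - out$value_b_deg) > threshold_deg
  out
}

check_grader_pairs <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  need <- c("value_a_deg", "value_b_deg")
  miss <- setdiff(need, names(pairs))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  a <- pairs$value_a_deg
  b <- pairs$value_b_deg
  if (anyNA(a) || anyNA(b)) stop("grader values must not be missing")
  if (any(a < 0) || any(b < 0)) stop("grader values must be >= 0")
  pairs
}

#' Inter-grader agreement statistics
#'
#' Summarizes agreement between two graders by the mean (and SD) of absolute
#' differences and by the intraclass correlation coefficient with its 95%
#' confidence interval. The default ICC form is the two-way, absolute-
#' agreement, single-measure coefficient ICC(A,1), matching an interest in
#' absolute inter-grader differences; the consistency form ICC(C,1) is
#' available via `type`.
#'
#' @inheritParams reconcile_graders
#' @param type `"agreement"` (ICC(A,1), default) or `"consistency"`
#'   (ICC(C,1)).
#' @param conf_level Confidence level for the ICC interval.
#' @return A list with `mean_abs_diff`, `sd_abs_diff`, `icc`, `icc_ci`
#'   (length-2), `type` and `n_pairs`. When the between- and within-subject
#'   variance are both zero the ICC is undefined: `icc` is `NA` and a warning
#'   of class `retcomp_icc_undefined` is raised.
#' @export
agreement_stats <- function(pairs, type = c("agreement", "consistency"),
                            conf_level = 0.95) {
  type <- match.arg(type)
  pairs <- check_grader_pairs(pairs)
  n <- nrow(pairs)
  if (n < 3) stop("at least 3 grader pairs are required (got ", n, ")")
  a <- pairs$value_a_deg
  b <- pairs$value_b_deg
  d <- abs(a - b)

  # two-way ANOVA decomposition, n subjects x k = 2 raters
  y <- cbind(a, b)
  k <- 2L
  gm <- mean(y)
  row_m <- rowMeans(y)
  col_m <- colMeans(y)
  ssr <- k * sum((row_m - gm)^2)
  ssc <- n * sum((col_m - gm)^2)
  sst <- sum((y - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  if (sst < .Machine$double.eps * max(1, gm^2) * n * k) {
    warning(structure(
      class = c("retcomp_icc_undefined", "warning", "condition"),
      list(message = "total variance is zero; ICC is undefined",
           call = sys.call())))
    icc <- NA_real_
    ci <- c(NA_real_, NA_real_)
  } else if (type == "agreement") {
    icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    ci <- icc_a1_ci(icc, msr, msc, mse, n, k, conf_level)
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    ci <- icc_c1_ci(msr, mse, n, k, conf_level)
  }

  list(mean_abs_diff = mean(d), sd_abs_diff = stats::sd(d),
       icc = icc, icc_ci = ci, type = type, n_pairs = n)
}

# McGraw & Wong confidence bounds for ICC(A,1)
icc_a1_ci <- function(icc, msr, msc, mse, n, k, conf_level) {
  alpha <- 1 - conf_level
  if (mse <= 0 && icc >= 1) return(c(1, 1))
  aa <- (k * icc) / (n * (1 - icc))
  bb <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (aa * msc + bb * mse)^2 /
    ((aa * msc)^2 / (k - 1) + (bb * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  pmin(pmax(c(lower, upper), -1), 1)
}

# Shrout & Fleiss style bounds for the consistency form ICC(C,1)
icc_c1_ci <- function(msr, mse, n, k, conf_level) {
  alpha <- 1 - conf_level
  if (mse <= 0) return(c(1, 1))
  fo <- msr / mse
  f_l <- fo / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
  f_u <- fo * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
  c((f_l - 1) / (f_l + k - 1), (f_u - 1) / (f_u + k - 1))
}
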