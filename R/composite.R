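#' Per-biomarker eccentricity changes from baseline
#'
#' For every eye-visit, computes the change of each standardized biomarker
#' from that eye's baseline (`t_years == 0`) visit. A per-biomarker change is
#' defined only when the biomarker is present at both baseline and follow-up;
#' otherwise it is missing. Baseline rows themselves are kept (all-zero
#' deltas, `dt_years == 0`) and flagged so that model fitting can exclude
#' them.
#'
#' @param ecc Table from [visit_to_ecc()]: one row per eye-visit with
#'   `patient_id`, `eye`, `t_years` and the five `eps_*` columns.
#' @return A tibble with `patient_id`, `eye`, `dt_years`, the five
#'   `delta_*` columns (degrees) and `is_baseline`.
#' @export
deltas_from_baseline <- function(ecc) {
  stopifnot(is.data.frame(ecc))
  need <- c("patient_id", "eye", "t_years", eps_columns())
  miss <- setdiff(need, names(ecc))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  ecc <- tibble::as_tibble(ecc[need])
  eye_key <- paste(ecc$patient_id, ecc$eye, sep = "/")
  base_idx <- integer(nrow(ecc))
  for (key in unique(eye_key)) {
    rows <- which(eye_key == key)
    b <- rows[ecc$t_years[rows] == 0]
    if (length(b) == 0) stop("eye without baseline visit: ", key)
    base_idx[rows] <- b[1]
  }
  out <- tibble::tibble(
    patient_id = ecc$patient_id,
    eye = ecc$eye,
    dt_years = ecc$t_years
  )
  for (bm in biomarkers()) {
    eps <- ecc[[paste0("eps_", bm)]]
    out[[paste0("delta_", bm)]] <- eps - eps[base_idx]
  }
  out$is_baseline <- out$dt_years == 0
  out
}

#' Weighted composite change score
#'
#' The composite change is the weighted mean of the available per-biomarker
#' eccentricity changes, divided by the total weight of the biomarkers that
#' are available (so a missing biomarker simply drops out and the remaining
#' weights are renormalized). Weights are non-negative and only their
#' proportions matter. If no biomarker with positive weight is available the
#' composite is missing.
#'
#' @param deltas Numeric vector of five per-biomarker changes in canonical
#'   [biomarkers()] order (possibly with `NA`), or a matrix / data frame with
#'   five such columns (rows are eye-visits).
#' @param weights Numeric vector of five non-negative weights in canonical
#'   order (any positive-sum scale: proportions, percentages or grid units).
#' @return Composite change in degrees; one value per row of `deltas`.
#' @export
#' @examples
#' composite_change(c(NA, 1, NA, 2, NA), c(0, 25, 5, 55, 15))
composite_change <- function(deltas, weights) {
  w <- check_weights(weights)
  if (is.data.frame(deltas)) deltas <- as.matrix(deltas)
  if (!is.matrix(deltas)) deltas <- matrix(deltas, nrow = 1)
  if (ncol(deltas) != 5L) stop("`deltas` must have five columns")
  avail <- !is.na(deltas)
  num <- rowSums(sweep(deltas, 2, w, `*`), na.rm = TRUE)
  den <- as.numeric(avail %*% w)
  out <- ifelse(den > 0, num / den, NA_real_)
  as.numeric(out)
}

check_weights <- function(weights) {
  if (!is.numeric(weights) || length(weights) != 5L) {
    stop("`weights` must be a numeric vector of length 5 (order: ",
         paste(biomarkers(), collapse = ", "), ")")
  }
  if (anyNA(weights) || any(weights < 0)) stop("weights must be non-negative")
  if (sum(weights) <= 0) stop("weights must have a positive sum")
  if (!is.null(names(weights))) {
    if (!setequal(names(weights), biomarkers())) {
      stop("weight names must be exactly: ", paste(biomarkers(), collapse = ", "))
    }
    weights <- weights[biomarkers()]
  }
  unname(weights)
}

#' Append the composite change to a delta table
#'
#' Convenience wrapper: evaluates [composite_change()] row-wise on a table
#' from [deltas_from_baseline()] and appends it as `delta_c`.
#'
#' @param deltas Table from [deltas_from_baseline()].
#' @inheritParams composite_change
#' @return `deltas` with a `delta_c` column (degrees).
#' @export
composite_deltas <- function(deltas, weights) {
  stopifnot(is.data.frame(deltas))
  miss <- setdiff(delta_columns(), names(deltas))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  out <- tibble::as_tibble(deltas)
  out$delta_c <- composite_change(as.matrix(out[delta_columns()]), weights)
  out
}

#' Enumerate the weight grid
#'
#' All ways of distributing `1/grid_step` integer units over the biomarkers,
#' i.e. every weight combination on a simplex grid with the given step. With
#' five biomarkers and 5% steps this is `choose(24, 4) = 10626` combinations.
#' Enumeration is deterministic lexicographic (the first biomarker varies
#' slowest), so optimization tie-breaks are reproducible.
#'
#' @param n_biomarkers Number of biomarkers (grid dimensions), default 5.
#' @param grid_step Grid resolution as a proportion; `1/grid_step` must be a
#'   positive integer. Default 0.05 (5% steps).
#' @return A numeric matrix with `n_biomarkers` columns whose rows are weight
#'   vectors summing to 1; integer grid units are attached as attribute
#'   `"units"` and the step as `"grid_step"`.
#' @export
#' @examples
#' nrow(enumerate_weight_grid(5, 0.05)) # 10626
enumerate_weight_grid <- function(n_biomarkers = 5, grid_step = 0.05) {
  stopifnot(is.numeric(n_biomarkers), length(n_biomarkers) == 1L,
            n_biomarkers >= 1, n_biomarkers == round(n_biomarkers))
  n_units <- 1 / grid_step
  if (abs(n_units - round(n_units)) > 1e-9) {
    stop("1/grid_step must be a positive integer (got step ", grid_step, ")")
  }
  n_units <- as.integer(round(n_units))
  units <- compositions(n_units, as.integer(n_biomarkers))
  grid <- units / n_units
  if (n_biomarkers == 5) colnames(grid) <- biomarkers()
  attr(grid, "units") <- units
  attr(grid, "grid_step") <- grid_step
  grid
}

# all compositions of n units into a ordered parts, lexicographic
compositions <- function(n, a) {
  if (a == 1L) return(matrix(n, nrow = 1L))
  blocks <- lapply(0:n, function(i) {
    rest <- compositions(n - i, a - 1L)
    cbind(rep.int(i, nrow(rest)), rest, deparse.level = 0)
  })
  do.call(rbind, blocks)
}

#' Packaged optimal composite weights
#'
#' The development-cohort optimum of the weighting search: 0% acuity, 25%
#' QDAF area, 5% DDAF area, 55% EZ loss, 15% ELM loss.
#'
#' @return Named numeric vector of five proportions summing to 1.
#' @export
optimal_weights <- function() {
  c(bcva = 0, qdaf = 0.25, ddaf = 0.05, ez = 0.55, elm = 0.15)
}
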