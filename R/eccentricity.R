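#' Conversion constants for the eccentricity scale
#'
#' All measurements are standardized to retinal eccentricity (degrees of
#' visual angle from the foveal center). Two constants govern the
#' conversions: the retinal magnification factor (one degree of eccentricity
#' corresponds to approximately 0.3 mm on the retina) and the per-degree
#' acuity decay factor (decimal acuity shrinks by a factor 1/1.2 for every
#' degree of eccentricity).
#'
#' @param mm_per_degree Retinal distance subtended by one degree of
#'   eccentricity, in mm. Default 0.3.
#' @param acuity_decay Per-degree multiplicative decay of decimal acuity;
#'   acuity at eccentricity `e` is `(1/acuity_decay)^e`. Default 1.2.
#' @return A named list with components `mm_per_degree` and `acuity_decay`.
#' @export
conversion_constants <- function(mm_per_degree = 0.3, acuity_decay = 1.2) {
  stopifnot(is.numeric(mm_per_degree), length(mm_per_degree) == 1L,
            is.finite(mm_per_degree), mm_per_degree > 0,
            is.numeric(acuity_decay), length(acuity_decay) == 1L,
            is.finite(acuity_decay), acuity_decay > 1)
  list(mm_per_degree = mm_per_degree, acuity_decay = acuity_decay)
}

#' Eccentricity equivalent of decimal visual acuity
#'
#' Converts decimal best-corrected visual acuity (Snellen
#' numerator/denominator) to its retinal-eccentricity equivalent. Acuity
#' decays by a factor `1/1.2` per degree of eccentricity, so
#' `ecc = log(bcva) / log(1/1.2)`. Acuity better than 1.0 (20/20) is clamped
#' to 0 degrees with a warning, since eccentricity is a non-negative spatial
#' extent.
#'
#' @param bcva Decimal acuity, strictly positive. Vectorized; `NA` propagates.
#' @param constants See [conversion_constants()].
#' @return Eccentricity in degrees (same length as `bcva`).
#' @export
#' @examples
#' ecc_from_bcva(20 / 205) # about 12.76 degrees
ecc_from_bcva <- function(bcva, constants = conversion_constants()) {
  stopifnot(is.numeric(bcva))
  bad <- !is.na(bcva) & (bcva <= 0 | !is.finite(bcva))
  if (any(bad)) {
    stop("`bcva` must be strictly positive and finite (offending index: ",
         paste(which(bad), collapse = ", "), ")")
  }
  out <- log(bcva) / log(1 / constants$acuity_decay)
  clamped <- !is.na(out) & out < 0
  if (any(clamped)) {
    warning(sum(clamped), " acuity value(s) better than 1.0 clamped to 0 degrees")
    out[clamped] <- 0
  }
  out
}

#' Decimal acuity at a given eccentricity
#'
#' Inverse of [ecc_from_bcva()]: `bcva = (1/1.2)^ecc`.
#'
#' @param ecc Eccentricity in degrees, non-negative. `NA` propagates.
#' @inheritParams ecc_from_bcva
#' @return Decimal acuity.
#' @export
bcva_from_ecc <- function(ecc, constants = conversion_constants()) {
  check_nonneg(ecc, "ecc")
  (1 / constants$acuity_decay)^ecc
}

#' Eccentricity equivalent of an atrophy area
#'
#' An autofluorescence lesion area (mm^2) is summarized by the radius of its
#' circular equivalent, expressed in degrees:
#' `ecc = sqrt(area / pi) / 0.3`. Applies identically to questionably and
#' definitely decreased autofluorescence areas.
#'
#' @param area Lesion area in mm^2, non-negative. Vectorized; `NA` propagates.
#' @inheritParams ecc_from_bcva
#' @return Eccentricity in degrees.
#' @export
#' @examples
#' ecc_from_area(5.03) # about 4.22 degrees
ecc_from_area <- function(area, constants = conversion_constants()) {
  check_nonneg(area, "area")
  sqrt(area / pi) / constants$mm_per_degree
}

#' Area equivalent of an eccentricity
#'
#' Inverse of [ecc_from_area()]: `area = pi * (0.3 * ecc)^2`.
#'
#' @inheritParams bcva_from_ecc
#' @return Area in mm^2.
#' @export
area_from_ecc <- function(ecc, constants = conversion_constants()) {
  check_nonneg(ecc, "ecc")
  pi * (constants$mm_per_degree * ecc)^2
}

#' Eccentricity equivalent of a transverse loss
#'
#' Transverse (horizontal) loss of a retinal band on the OCT scan through the
#' fovea is the diameter of a circular equivalent, so its eccentricity is the
#' corresponding radius in degrees: `ecc = (loss / 2) / 0.3`. Applies
#' identically to ellipsoid-zone and external-limiting-membrane loss.
#'
#' @param loss Transverse loss in mm, non-negative. Vectorized; `NA`
#'   propagates.
#' @inheritParams ecc_from_bcva
#' @return Eccentricity in degrees.
#' @export
#' @examples
#' ecc_from_transverse(3.05) # about 5.08 degrees
ecc_from_transverse <- function(loss, constants = conversion_constants()) {
  check_nonneg(loss, "loss")
  loss / (2 * constants$mm_per_degree)
}

#' Transverse-loss equivalent of an eccentricity
#'
#' Inverse of [ecc_from_transverse()]: `loss = 2 * 0.3 * ecc` (the equivalent
#' diameter).
#'
#' @inheritParams bcva_from_ecc
#' @return Transverse loss (equivalent diameter) in mm.
#' @export
#' @examples
#' transverse_from_ecc(12.76) # about 7.7 mm equivalent diameter
transverse_from_ecc <- function(ecc, constants = conversion_constants()) {
  check_nonneg(ecc, "ecc")
  2 * constants$mm_per_degree * ecc
}

check_nonneg <- function(x, name) {
  stopifnot(is.numeric(x))
  bad <- !is.na(x) & (x < 0 | !is.finite(x))
  if (any(bad)) {
    stop("`", name, "` must be non-negative and finite (offending index: ",
         paste(which(bad), collapse = ", "), ")")
  }
  invisible(x)
}

#' Standardize a cohort table to the eccentricity scale
#'
#' Applies the acuity, area and transverse transforms field-wise to every
#' record of a cohort table, appending the five eccentricity columns
#' `eps_bcva`, `eps_qdaf`, `eps_ddaf`, `eps_ez`, `eps_elm` (degrees). Missing
#' measurements stay missing.
#'
#' @param cohort A [cohort_table()] or data frame with the cohort schema.
#' @inheritParams ecc_from_bcva
#' @return The input table with the five `eps_*` columns appended.
#' @export
visit_to_ecc <- function(cohort, constants = conversion_constants()) {
  stopifnot(is.data.frame(cohort))
  need <- measure_columns()
  miss <- setdiff(need, names(cohort))
  if (length(miss) > 0) {
    stop("cohort is missing measurement column(s): ", paste(miss, collapse = ", "))
  }
  out <- tibble::as_tibble(cohort)
  out$eps_bcva <- ecc_from_bcva(out$bcva, constants)
  out$eps_qdaf <- ecc_from_area(out$qdaf_area_mm2, constants)
  out$eps_ddaf <- ecc_from_area(out$ddaf_area_mm2, constants)
  out$eps_ez   <- ecc_from_transverse(out$ez_loss_mm, constants)
  out$eps_elm  <- ecc_from_transverse(out$elm_loss_mm, constants)
  out
}
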