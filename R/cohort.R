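#' Construct and validate a longitudinal cohort table
#'
#' A cohort table holds one row per eye-visit in raw clinical units:
#' `patient_id`, `eye` (`"OD"`/`"OS"`), `t_years` (time since that eye's
#' baseline visit), decimal acuity `bcva`, autofluorescence areas
#' `qdaf_area_mm2` and `ddaf_area_mm2` (mm^2) and transverse band losses
#' `ez_loss_mm` and `elm_loss_mm` (mm). Any measurement may be missing, but
#' every record must carry at least one, every eye must have a `t_years == 0`
#' baseline row, and `(patient_id, eye, t_years)` must be unique.
#'
#' @param data Data frame with the schema above.
#' @param cohort_label Free-text label stored as an attribute.
#' @return A validated `cohort_table` (a tibble subclass).
#' @export
cohort_table <- function(data, cohort_label = "") {
  stopifnot(is.data.frame(data))
  required <- c("patient_id", "eye", "t_years", measure_columns())
  miss <- setdiff(required, names(data))
  if (length(miss) > 0) {
    stop("missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(data) == 0) stop("no records")
  out <- tibble::as_tibble(data[required])
  out$patient_id <- as.character(out$patient_id)
  out$eye <- as.character(out$eye)
  for (col in c("t_years", measure_columns())) {
    out[[col]] <- as.numeric(out[[col]])
  }

  problems <- character(0)
  bad_eye <- which(!out$eye %in% c("OD", "OS"))
  if (length(bad_eye) > 0) {
    problems <- c(problems, paste0("rows ", paste(bad_eye, collapse = ","),
                                   ": eye must be OD or OS"))
  }
  bad_t <- which(is.na(out$t_years) | out$t_years < 0)
  if (length(bad_t) > 0) {
    problems <- c(problems, paste0("rows ", paste(bad_t, collapse = ","),
                                   ": t_years must be >= 0"))
  }
  bad_bcva <- which(!is.na(out$bcva) & out$bcva <= 0)
  if (length(bad_bcva) > 0) {
    problems <- c(problems, paste0("rows ", paste(bad_bcva, collapse = ","),
                                   ": bcva must be > 0"))
  }
  for (col in measure_columns()[-1]) {
    bad <- which(!is.na(out[[col]]) & out[[col]] < 0)
    if (length(bad) > 0) {
      problems <- c(problems, paste0("rows ", paste(bad, collapse = ","),
                                     ": ", col, " must be >= 0"))
    }
  }
  none <- which(rowSums(!is.na(out[measure_columns()])) == 0)
  if (length(none) > 0) {
    problems <- c(problems, paste0("rows ", paste(none, collapse = ","),
                                   ": no measurement present"))
  }
  if (length(problems) > 0) {
    stop("invalid cohort rows:\n  ", paste(problems, collapse = "\n  "))
  }

  key <- paste(out$patient_id, out$eye, format(out$t_years, digits = 15))
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop("duplicate (patient_id, eye, t_years) records at rows: ",
         paste(dup, collapse = ", "))
  }
  eye_key <- paste(out$patient_id, out$eye)
  has_baseline <- tapply(out$t_years, eye_key, function(t) any(t == 0))
  if (!all(has_baseline)) {
    stop("eye(s) without a t_years == 0 baseline visit: ",
         paste(names(has_baseline)[!has_baseline], collapse = ", "))
  }

  out <- out[order(out$patient_id, out$eye, out$t_years), ]
  class(out) <- c("cohort_table", class(out))
  attr(out, "cohort_label") <- cohort_label
  out
}

#' @export
print.cohort_table <- function(x, ...) {
  n_eyes <- length(unique(paste(x$patient_id, x$eye)))
  cat("Longitudinal cohort",
      if (nzchar(attr(x, "cohort_label") %||% "")) paste0("'", attr(x, "cohort_label"), "'"),
      ": ", length(unique(x$patient_id)), " patients, ",
      n_eyes, " eyes, ", nrow(x), " eye-visits\n", sep = "")
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse best-corrected visual acuity notations
#'
#' Accepts decimal acuity (`"0.2"`, `0.2`) or a Snellen fraction
#' (`"20/100"`), returning decimal acuity. Empty strings and `NA` stay
#' missing. Non-numeric acuity categories (e.g. counting fingers) are
#' rejected rather than imputed.
#'
#' @param x Character or numeric vector.
#' @return Numeric vector of decimal acuities.
#' @export
#' @examples
#' parse_bcva(c("20/100", "0.5", NA))
parse_bcva <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  blank <- is.na(x) | x == ""
  snellen <- !blank & grepl("^[0-9.]+\\s*/\\s*[0-9.]+$", x)
  if (any(snellen)) {
    parts <- strsplit(x[snellen], "/")
    out[snellen] <- vapply(parts, function(p) {
      as.numeric(p[1]) / as.numeric(p[2])
    }, numeric(1))
  }
  plain <- !blank & !snellen
  if (any(plain)) {
    val <- suppressWarnings(as.numeric(x[plain]))
    if (anyNA(val)) {
      stop("unparseable acuity value(s): ",
           paste(unique(x[plain][is.na(val)]), collapse = ", "))
    }
    out[plain] <- val
  }
  out
}

#' Read a cohort table from CSV or XLSX
#'
#' The documented CSV header is `patient_id, eye, t_years, bcva,
#' qdaf_area_mm2, ddaf_area_mm2, ez_loss_mm, elm_loss_mm`; empty cells are
#' missing; `eye` is `OD`/`OS`; `bcva` may be decimal or a Snellen fraction
#' `"N/D"`. An XLSX sheet with the same (or mapped) columns is accepted when
#' the readxl package is installed.
#'
#' @param path File path.
#' @param format `"csv"` or `"xlsx"` (default guessed from the extension).
#' @param cohort_label Stored on the returned table.
#' @param col_map Optional named character vector mapping schema names to the
#'   file's column names, e.g. `c(qdaf_area_mm2 = "QDAF")`, for ingesting
#'   externally formatted sheets.
#' @param sheet Sheet index or name for XLSX input.
#' @return A validated [cohort_table()].
#' @export
read_cohort <- function(path, format = c("auto", "csv", "xlsx"),
                        cohort_label = basename(path), col_map = NULL,
                        sheet = 1) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx" else "csv"
  }
  if (format == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading XLSX requires the 'readxl' package")
    }
    raw <- readxl::read_excel(path, sheet = sheet,
                              col_types = "text", .name_repair = "minimal")
    raw <- as.data.frame(raw, stringsAsFactors = FALSE)
  } else {
    raw <- utils::read.csv(path, colClasses = "character",
                           check.names = FALSE, strip.white = TRUE)
  }
  if (nrow(raw) == 0) stop("no records in ", path)
  if (!is.null(col_map)) {
    for (schema_name in names(col_map)) {
      src <- col_map[[schema_name]]
      if (!src %in% names(raw)) stop("mapped column not found: ", src)
      names(raw)[names(raw) == src] <- schema_name
    }
  }
  required <- c("patient_id", "eye", "t_years", measure_columns())
  miss <- setdiff(required, names(raw))
  if (length(miss) > 0) {
    stop("header mismatch; missing column(s): ", paste(miss, collapse = ", "))
  }
  raw <- raw[required]
  raw[raw == ""] <- NA

  parsed <- raw
  parsed$bcva <- parse_bcva(raw$bcva)
  for (col in c("t_years", measure_columns()[-1])) {
    val <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(val))
    if (length(bad) > 0) {
      stop("malformed numeric value(s) in '", col, "' at data row(s): ",
           paste(bad, collapse = ", "))
    }
    parsed[[col]] <- val
  }
  cohort_table(parsed, cohort_label = cohort_label)
}

#' Write a cohort table to CSV
#'
#' Writes the documented schema with empty cells for missing values, so that
#' `read_cohort(write_cohort(x))` round-trips (text fields exactly, numerics
#' to full double precision).
#'
#' @param cohort A [cohort_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  cols <- c("patient_id", "eye", "t_years", measure_columns())
  out <- as.data.frame(cohort)[cols]
  for (col in c("t_years", measure_columns())) {
    num <- out[[col]]
    txt <- vapply(num, function(v) {
      if (is.na(v)) "" else format(v, digits = 17, scientific = FALSE, trim = TRUE)
    }, character(1))
    out[[col]] <- txt
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
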