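#' Effective quantum yield of PSII (Yield II)
#'
#' Light-adapted effective quantum yield dF/Fm' = (Fm' - F) / Fm', where Fm'
#' is the maximal fluorescence under a saturating pulse and F the
#' steady-state fluorescence. Vectorised.
#'
#' @param f steady-state fluorescence (instrument units, >= 0).
#' @param fm_prime light-adapted maximal fluorescence (> 0).
#' @return unitless yield in [0, 1] for QC-valid records (f <= fm_prime).
#'   Records with f > fm_prime (instrument noise) yield negative values;
#'   flag them with [pam_qc_valid()] rather than using them.
#' @export
effective_quantum_yield <- function(f, fm_prime) {
  if (any(fm_prime <= 0, na.rm = TRUE)) stop("fm_prime must be > 0", call. = FALSE)
  if (any(f < 0, na.rm = TRUE)) stop("f must be >= 0", call. = FALSE)
  (fm_prime - f) / fm_prime
}

#' Maximal quantum yield of PSII (Fv/Fm)
#'
#' Dark-adapted maximal quantum yield (Fm - Fo) / Fm, with Fv = Fm - Fo.
#' An indicator of photoinhibition: healthy phototrophic mats sit near
#' 0.7-0.83 and midday light stress depresses the value.
#'
#' @param fo dark-adapted basal fluorescence (>= 0).
#' @param fm dark-adapted maximal fluorescence (> 0).
#' @return unitless Fv/Fm in [0, 1] when fo <= fm.
#' @export
max_quantum_yield <- function(fo, fm) {
  if (any(fm <= 0, na.rm = TRUE)) stop("fm must be > 0", call. = FALSE)
  if (any(fo < 0, na.rm = TRUE)) stop("fo must be >= 0", call. = FALSE)
  (fm - fo) / fm
}

#' Relative electron transport rate through PSII
#'
#' rETR (relative units) = Yield II x incident E-PAR. Uses incident
#' irradiance with no absorptance factor (the "relative" convention).
#'
#' @param yield_ii effective quantum yield in [0, 1].
#' @param e_par incident PAR (umol photons m-2 s-1, >= 0).
#' @return rETR, relative units.
#' @export
retr <- function(yield_ii, e_par) {
  if (any(yield_ii < 0 | yield_ii > 1, na.rm = TRUE)) {
    stop("yield_ii must be in [0, 1]", call. = FALSE)
  }
  if (any(e_par < 0, na.rm = TRUE)) stop("e_par must be >= 0", call. = FALSE)
  yield_ii * e_par
}

#' QC flag for PAM records
#'
#' A record is QC-valid when the saturating-pulse maxima exceed the
#' corresponding steady-state / basal fluorescence (F <= Fm', Fo <= Fm).
#' Violations occur with instrument noise; they are retained but flagged,
#' so negative yields never corrupt diel summaries.
#'
#' @param records data.frame with columns `f`, `fm_prime` and optionally
#'   `fo`, `fm` (NA where not measured).
#' @return logical vector, one flag per row.
#' @export
pam_qc_valid <- function(records) {
  ok <- records$f <= records$fm_prime & records$fm_prime > 0
  if (all(c("fo", "fm") %in% names(records))) {
    dark <- !is.na(records$fo) & !is.na(records$fm)
    ok[dark] <- ok[dark] & records$fo[dark] <= records$fm[dark] & records$fm[dark] > 0
  }
  ok & !is.na(ok)
}

#' Per-record PAM photophysiology indices
#'
#' Computes Yield II, Fv/Fm (where dark-adapted readings exist) and rETR for
#' every fluorescence record, plus the QC flag.
#'
#' @param records data.frame with `timestamp` (POSIXct or "HH:MM" character),
#'   `f`, `fm_prime`, optional `fo`, `fm`, and `e_par`.
#' @return the records with added columns `yield_ii`, `fvfm`, `retr_rel`,
#'   `qc_valid`.
#' @export
pam_indices <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("timestamp", "f", "fm_prime", "e_par")
  if (!all(need %in% names(records))) {
    stop("records must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  records$yield_ii <- (records$fm_prime - records$f) / records$fm_prime
  records$fvfm <- NA_real_
  if (all(c("fo", "fm") %in% names(records))) {
    dark <- !is.na(records$fo) & !is.na(records$fm)
    records$fvfm[dark] <- (records$fm[dark] - records$fo[dark]) / records$fm[dark]
  }
  records$retr_rel <- pmax(records$yield_ii, 0) * records$e_par
  records$qc_valid <- pam_qc_valid(records)
  records
}

# hour-of-day as decimal hours, accepting POSIXct or "HH:MM" strings
hour_of_day <- function(ts) {
  if (inherits(ts, "POSIXt")) {
    lt <- as.POSIXlt(ts)
    lt$hour + lt$min / 60 + lt$sec / 3600
  } else {
    parts <- strsplit(as.character(ts), ":", fixed = TRUE)
    vapply(parts, function(p) as.numeric(p[1]) + as.numeric(p[2]) / 60, numeric(1))
  }
}

#' Diel photoinhibition and recovery summary
#'
#' Summarises a day of PAM records into the two diel photophysiology
#' statistics: the fractional midday depression of Fv/Fm relative to the
#' morning maximum, and the afternoon recovery fraction (last afternoon
#' Fv/Fm over the morning maximum). QC-invalid records are excluded from
#' both statistics.
#'
#' @param records fluorescence records as for [pam_indices()]; must span
#'   morning, the noon window and afternoon (>= 3 timepoints) with
#'   dark-adapted readings for the Fv/Fm statistics.
#' @param noon_window numeric length-2, decimal hours of the midday window;
#'   default `c(11, 15)`, the interval in which diel minima occur.
#' @return An object of class `"diel_photo_summary"`: list with the indexed
#'   record table (`indices`), `midday_depression`, `recovery_fraction`,
#'   `fvfm_noon_min`, `fvfm_morning_max`, and the hour of minimal Yield II
#'   (`hour_min_yield`).
#' @export
diel_summary <- function(records, noon_window = c(11, 15)) {
  if (length(noon_window) != 2 || noon_window[1] >= noon_window[2]) {
    stop("noon_window must be an increasing pair of decimal hours", call. = FALSE)
  }
  idx <- pam_indices(records)
  idx$hour <- hour_of_day(idx$timestamp)
  if (nrow(idx) < 3) stop("need at least 3 timepoints spanning the day", call. = FALSE)
  ok <- idx[idx$qc_valid, , drop = FALSE]
  has_fvfm <- !is.na(ok$fvfm)
  morning <- ok$hour < noon_window[1] & has_fvfm
  noon <- ok$hour >= noon_window[1] & ok$hour <= noon_window[2] & has_fvfm
  afternoon <- ok$hour > noon_window[2] & has_fvfm

  fvfm_fields_ok <- any(morning) && any(noon)
  if (!any(has_fvfm)) {
    warning("no dark-adapted (Fo, Fm) records: Fv/Fm summary fields are NA", call. = FALSE)
  } else if (!fvfm_fields_ok) {
    warning("Fv/Fm records do not cover both morning and the noon window; summary fields are NA",
            call. = FALSE)
  }
  morning_max <- if (any(morning)) max(ok$fvfm[morning]) else NA_real_
  noon_min <- if (any(noon)) min(ok$fvfm[noon]) else NA_real_
  depression <- if (fvfm_fields_ok) 1 - noon_min / morning_max else NA_real_
  recovery <- if (fvfm_fields_ok && any(afternoon)) {
    ok$fvfm[afternoon][which.max(ok$hour[afternoon])] / morning_max
  } else NA_real_

  out <- list(
    indices = idx,
    midday_depression = depression,
    recovery_fraction = recovery,
    fvfm_morning_max = morning_max,
    fvfm_noon_min = noon_min,
    hour_min_yield = ok$hour[which.min(ok$yield_ii)]
  )
  class(out) <- "diel_photo_summary"
  out
}

#' @export
print.diel_photo_summary <- function(x, ...) {
  cat(sprintf(
    "Diel PAM summary: %d records; Fv/Fm morning max %.3f, noon min %.3f\n  midday depression %.3f, afternoon recovery %.3f, Yield II minimum at %.1f h\n",
    nrow(x$indices), x$fvfm_morning_max, x$fvfm_noon_min,
    x$midday_depression, x$recovery_fraction, x$hour_min_yield))
  invisible(x)
}
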