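#' Endpoint rate of change
#'
#' Net rate over a dark endpoint incubation: (final - initial) / duration.
#' Positive = accumulation, negative = consumption.
#'
#' @param initial_um,final_um concentrations (uM) at the start and end of
#'   the incubation.
#' @param duration_h incubation duration (h, > 0).
#' @return rate, uM h-1. Vectorised.
#' @export
endpoint_rate <- function(initial_um, final_um, duration_h) {
  if (any(duration_h <= 0)) stop("duration_h must be > 0", call. = FALSE)
  (final_um - initial_um) / duration_h
}

# per-treatment replicate spread: SD for n > 2, half-range for duplicates
# (which equals the standard error of a duplicate mean), 0 for singletons
.rate_spread <- function(x) {
  n <- length(x)
  if (n == 1) c(spread = 0, type = 1)
  else if (n == 2) c(spread = abs(diff(x)) / 2, type = 2)
  else c(spread = stats::sd(x), type = 3)
}

#' Per-treatment endpoint rates
#'
#' Mean replicate endpoint rate per inhibitor treatment, with a replicate
#' spread (SD for n > 2, half-range for duplicates, 0 for singletons —
#' flagged via `spread_type`).
#'
#' @param experiment data.frame with columns `treatment`, `initial_um`,
#'   `final_um`, `duration_h`, and optionally `session`, `analyte`,
#'   `replicate`. `CONTROL` must be among the treatments.
#' @return data.frame of class `"treatment_rates"`: one row per treatment
#'   with `rate` (uM h-1), `spread`, `spread_type` (`"sd"`, `"half_range"`,
#'   `"none"`), `n`. Session/analyte labels carried as attributes.
#' @export
treatment_rates <- function(experiment) {
  stopifnot(is.data.frame(experiment))
  need <- c("treatment", "initial_um", "final_um", "duration_h")
  if (!all(need %in% names(experiment))) {
    stop("experiment must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!"CONTROL" %in% experiment$treatment) {
    stop("experiment must include a CONTROL treatment", call. = FALSE)
  }
  r <- endpoint_rate(experiment$initial_um, experiment$final_um, experiment$duration_h)
  by_trt <- split(r, experiment$treatment)
  sp <- t(vapply(by_trt, .rate_spread, numeric(2)))
  out <- data.frame(
    treatment = names(by_trt),
    rate = vapply(by_trt, mean, numeric(1)),
    spread = sp[, 1],
    spread_type = c("none", "half_range", "sd")[sp[, 2]],
    n = lengths(by_trt),
    row.names = NULL
  )
  attr(out, "session") <- if (!is.null(experiment$session)) unique(experiment$session)[1] else NA
  attr(out, "analyte") <- if (!is.null(experiment$analyte)) unique(experiment$analyte)[1] else NA
  class(out) <- c("treatment_rates", "data.frame")
  out
}

# default mapping of partition components to the inhibitor treatment whose
# rate is differenced against the control
.PARTITION_EQS <- c(aob = "AZIDE_GC7", aoa = "AZIDE_ATU", other = "AZIDE")

#' Partition the nitrite rate into AOB, AOA and other-process contributions
#'
#' Inhibitor-difference partitioning of the net nitrite rate of change:
#' each contribution is the difference between an inhibitor-treatment rate
#' and the control rate —
#' AOB = R(azide+GC7) - R(control), AOA = R(azide+ATU) - R(control),
#' other processes = R(azide) - R(control). Contributions may be negative
#' (net consumption) and are reported as-is.
#'
#' Uncertainties: the standard uncertainty is the quadrature sum of the two
#' operand replicate spreads (independent flasks); `ci_lo`/`ci_hi` give a
#' 95% expanded interval using a Student-t coverage factor with
#' Welch-Satterthwaite effective degrees of freedom, which has close to
#' nominal coverage even for duplicate flasks, where the 1-sigma quadrature
#' interval does not.
#'
#' @param rates a `"treatment_rates"` table containing `CONTROL` and every
#'   treatment named in `equations`.
#' @param equations named character vector mapping components to treatment
#'   labels; default `c(aob = "AZIDE_GC7", aoa = "AZIDE_ATU", other = "AZIDE")`.
#' @return data.frame of class `"nitrification_partition"`: one row per
#'   component with `rate` (uM h-1), `u` (standard uncertainty), `ci_lo`,
#'   `ci_hi`, `session`.
#' @export
partition_nitrification <- function(rates, equations = .PARTITION_EQS) {
  stopifnot(inherits(rates, "data.frame"))
  missing_trt <- setdiff(c("CONTROL", unname(equations)), rates$treatment)
  if (length(missing_trt)) {
    stop("missing treatment(s): ", paste(missing_trt, collapse = ", "), call. = FALSE)
  }
  row_of <- function(trt) rates[match(trt, rates$treatment), ]
  ctrl <- row_of("CONTROL")
  res <- lapply(names(equations), function(comp) {
    trt <- row_of(equations[[comp]])
    val <- trt$rate - ctrl$rate
    u <- sqrt(trt$spread^2 + ctrl$spread^2)
    df_t <- max(trt$n - 1, 1)
    df_c <- max(ctrl$n - 1, 1)
    if (u > 0) {
      nu <- u^4 / (trt$spread^4 / df_t + ctrl$spread^4 / df_c)
      k <- stats::qt(0.975, nu)
    } else {
      k <- 0
    }
    data.frame(component = comp, rate = val, u = u,
               ci_lo = val - k * u, ci_hi = val + k * u)
  })
  out <- do.call(rbind, res)
  out$session <- attr(rates, "session")
  class(out) <- c("nitrification_partition", "data.frame")
  out
}

#' Morning-versus-afternoon contrast of rates or partitions
#'
#' Differences (morning - afternoon) for each shared quantity, with the
#' combined uncertainty in quadrature and a `morning_higher` flag.
#'
#' @param morning,afternoon two `"nitrification_partition"` tables (matched
#'   on `component`) or two `"treatment_rates"` tables (matched on
#'   `treatment`).
#' @return data.frame with per-quantity morning and afternoon values, the
#'   difference, its combined uncertainty, and `morning_higher`.
#' @export
session_contrast <- function(morning, afternoon) {
  if (is.null(morning) || is.null(afternoon)) {
    stop("both sessions are required", call. = FALSE)
  }
  key <- if (inherits(morning, "nitrification_partition")) "component" else "treatment"
  ucol <- if (key == "component") "u" else "spread"
  shared <- intersect(morning[[key]], afternoon[[key]])
  if (!length(shared)) stop("sessions share no quantities to contrast", call. = FALSE)
  m <- morning[match(shared, morning[[key]]), ]
  a <- afternoon[match(shared, afternoon[[key]]), ]
  data.frame(
    quantity = shared,
    morning = m$rate,
    afternoon = a$rate,
    difference = m$rate - a$rate,
    u = sqrt(m[[ucol]]^2 + a[[ucol]]^2),
    morning_higher = m$rate > a$rate,
    row.names = NULL
  )
}
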