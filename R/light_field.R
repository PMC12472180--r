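#' Validate a depth-irradiance profile
#'
#' Checks the structural invariants of an underwater PAR profile before the
#' attenuation fit: strictly increasing depths starting at the subsurface
#' reference (z = 0), and positive irradiance readings. Non-positive
#' irradiance values (sensor dropouts, below-detection readings) are dropped
#' with a warning; they cannot enter a log-space fit.
#'
#' @param profile data.frame with columns `depth_cm` (cm, non-negative,
#'   strictly increasing, first value 0) and `e_par` (downwelling PAR,
#'   umol photons m-2 s-1).
#' @return The QC-passed profile (rows with positive `e_par` only),
#'   invisibly classed as `"irradiance_profile"`.
#' @export
validate_profile <- function(profile) {
  stopifnot(is.data.frame(profile))
  if (!all(c("depth_cm", "e_par") %in% names(profile))) {
    stop("profile must have columns 'depth_cm' and 'e_par'", call. = FALSE)
  }
  z <- profile$depth_cm
  if (anyNA(z) || any(z < 0)) stop("depths must be non-negative and non-missing", call. = FALSE)
  if (any(diff(z) <= 0)) stop("depths must be strictly increasing", call. = FALSE)
  if (z[1] != 0) stop("first depth must be 0 (subsurface reference)", call. = FALSE)
  bad <- is.na(profile$e_par) | profile$e_par <= 0
  if (any(bad)) {
    warning(sprintf("dropping %d non-positive irradiance reading(s) before fitting", sum(bad)),
            call. = FALSE)
    profile <- profile[!bad, , drop = FALSE]
  }
  class(profile) <- c("irradiance_profile", "data.frame")
  invisible(profile)
}

#' Fit the diffuse PAR attenuation coefficient
#'
#' Fits the Beer-Lambert decay E_d(z) = E_d(0) * exp(-Kd * z) to a
#' depth-irradiance profile by ordinary least squares in log space:
#' the slope of ln E_d(z) versus depth is -Kd. The log-linear fit is the
#' standard limnological practice, is closed-form, and is stable on the
#' short profiles a 15-20 cm pond allows.
#'
#' @param profile data.frame with `depth_cm` and `e_par`; validated and QC'd
#'   via [validate_profile()].
#' @param nonlinear if `TRUE`, refine the log-space estimate by nonlinear
#'   least squares on the untransformed exponential (optional refit).
#' @return An object of class `"kd_estimate"`: list with `kd` (cm-1), `se`,
#'   `r_squared`, `n_points`.
#' @examples
#' prof <- data.frame(depth_cm = 0:3, e_par = 1000 * exp(-0.32 * 0:3))
#' fit_kd(prof)$kd  # 0.32
#' @export
fit_kd <- function(profile, nonlinear = FALSE) {
  profile <- validate_profile(profile)
  if (nrow(profile) < 3) {
    stop("fit infeasible: fewer than 3 positive-irradiance points", call. = FALSE)
  }
  z <- profile$depth_cm
  y <- log(profile$e_par)
  if (diff(range(y)) == 0) {
    # transparent water: zero slope, R^2 undefined for a constant response
    out <- list(kd = 0, se = 0, r_squared = NA_real_, n_points = length(z))
    class(out) <- "kd_estimate"
    return(out)
  }
  fit <- stats::lm(y ~ z)
  kd <- -unname(stats::coef(fit)[2])
  sm <- quiet_perfect_fit(summary(fit))
  se <- unname(sm$coefficients[2, 2])
  r2 <- sm$r.squared
  if (nonlinear) {
    st <- list(e0 = exp(unname(stats::coef(fit)[1])), kd = kd)
    nls_fit <- try(stats::nls(e_par ~ e0 * exp(-kd * depth_cm),
                              data = profile, start = st), silent = TRUE)
    if (!inherits(nls_fit, "try-error")) {
      kd <- unname(stats::coef(nls_fit)["kd"])
      se <- unname(summary(nls_fit)$coefficients["kd", 2])
    }
  }
  out <- list(kd = kd, se = se, r_squared = r2, n_points = length(z))
  class(out) <- "kd_estimate"
  out
}

#' @export
print.kd_estimate <- function(x, ...) {
  cat(sprintf("Kd(PAR) = %.4g cm-1  (se %.3g, r2 %.4g, n = %d)\n",
              x$kd, x$se, if (is.na(x$r_squared)) NA else x$r_squared, x$n_points))
  invisible(x)
}

#' Depth at which a given fraction of surface PAR remains
#'
#' Inverts the Beer-Lambert law: the depth where irradiance has fallen to
#' `retained_fraction` of the subsurface value is z = -ln(f) / Kd.
#'
#' @param kd attenuation coefficient (cm-1), > 0.
#' @param retained_fraction fraction of subsurface irradiance remaining,
#'   in (0, 1].
#' @return depth in cm.
#' @examples
#' attenuation_depth(0.32, 0.8)  # depth of 20% attenuation, ~0.70 cm
#' @export
attenuation_depth <- function(kd, retained_fraction) {
  if (any(kd <= 0)) stop("kd must be > 0", call. = FALSE)
  if (any(retained_fraction <= 0) || any(retained_fraction > 1)) {
    stop("retained_fraction must be in (0, 1]", call. = FALSE)
  }
  -log(retained_fraction) / kd
}

#' Beer-Lambert attenuation of irradiance with depth
#'
#' @param e0 subsurface irradiance (>= 0).
#' @param kd attenuation coefficient (cm-1, >= 0).
#' @param z depth (cm, >= 0).
#' @return irradiance at depth z: e0 * exp(-kd * z).
#' @export
attenuate <- function(e0, kd, z) {
  if (any(e0 < 0) || any(kd < 0) || any(z < 0)) {
    stop("e0, kd and z must all be non-negative", call. = FALSE)
  }
  e0 * exp(-kd * z)
}
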