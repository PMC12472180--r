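# Ideal gas constant, L atm K-1 mol-1
.R_GAS <- 0.08205736

# Litres of ideal gas per mole at STP, used to convert Bunsen coefficients
.V_STP <- 22.414

# Solubility coefficient sets, ln(sol) = A1 + A2*(100/T) + A3*ln(T/100)
#                                        + S*(B1 + B2*(T/100) + B3*(T/100)^2)
# CO2 and N2O give K0 in mol L-1 atm-1 directly (Weiss 1974; Weiss & Price
# 1980); CH4 gives the Bunsen coefficient (L gas STP L-1 atm-1, Wiesenburg &
# Guinasso 1979), divided by 22.414 to reach mol L-1 atm-1.
.SOL_COEF <- list(
  CO2 = list(A = c(-58.0931, 90.5069, 22.2940),
             B = c(0.027766, -0.025888, 0.0050578), bunsen = FALSE),
  CH4 = list(A = c(-67.1962, 99.1624, 27.9015),
             B = c(-0.072909, 0.041674, -0.0064603), bunsen = TRUE),
  N2O = list(A = c(-62.7062, 97.3066, 24.1406),
             B = c(-0.058420, 0.033193, -0.0051313), bunsen = FALSE)
)

# Modern global-mean atmospheric mole fractions (ppm), the default
# equilibrium reference when no local air measurement exists
.ATM_PPM <- c(CO2 = 420, CH4 = 1.9, N2O = 0.336)

# Reporting units per gas: CO2 in umol/L, CH4 and N2O in nmol/L
.GAS_UNIT_SCALE <- c(CO2 = 1e6, CH4 = 1e9, N2O = 1e9)
.GAS_UNIT_NAME <- c(CO2 = "umol/L", CH4 = "nmol/L", N2O = "nmol/L")

#' Equilibrium solubility of CO2, CH4 or N2O
#'
#' Henry-law solubility (mol L-1 atm-1) from the standard seawater
#' coefficient polynomials in temperature and salinity, used both to invert
#' headspace equilibration and to compute the air-equilibrium concentration
#' for percent saturation. Strictly decreasing in temperature and in
#' salinity (salting-out).
#'
#' @param gas one of `"CO2"`, `"CH4"`, `"N2O"` (vectorised).
#' @param temp_c temperature, deg C; values outside \[-2, 40\] warn and
#'   extrapolate.
#' @param salinity practical salinity; values outside \[0, 40\] warn.
#' @return solubility, mol L-1 atm-1.
#' @export
equilibrium_solubility <- function(gas, temp_c, salinity = 0) {
  gas <- as.character(gas)
  bad <- setdiff(unique(gas), names(.SOL_COEF))
  if (length(bad)) stop("unsupported gas: ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(temp_c < -2 | temp_c > 40)) {
    warning("temperature outside [-2, 40] C: solubility extrapolated", call. = FALSE)
  }
  if (any(salinity < 0 | salinity > 40)) {
    warning("salinity outside [0, 40]: solubility extrapolated", call. = FALSE)
  }
  tk <- temp_c + 273.15
  n <- max(length(gas), length(tk), length(salinity))
  gas <- rep_len(gas, n); tk <- rep_len(tk, n); s <- rep_len(salinity, n)
  vapply(seq_len(n), function(i) {
    cf <- .SOL_COEF[[gas[i]]]
    t100 <- tk[i] / 100
    v <- exp(cf$A[1] + cf$A[2] * (100 / tk[i]) + cf$A[3] * log(t100) +
               s[i] * (cf$B[1] + cf$B[2] * t100 + cf$B[3] * t100^2))
    if (cf$bunsen) v / .V_STP else v
  }, numeric(1))
}

#' Forward headspace partitioning (simulation)
#'
#' Given an original dissolved concentration, computes the headspace mole
#' fraction that helium-headspace equilibration would produce: the analyte
#' partitions between the gas phase (ideal gas at T, P) and the residual
#' water phase (Henry's law), conserving total moles. The exact inverse of
#' [headspace_to_dissolved()]; used by the synthetic generator and the
#' round-trip property tests.
#'
#' @param conc_mol_l original dissolved concentration (mol/L).
#' @param gas gas name.
#' @param vial_volume_ml,headspace_volume_ml vial geometry (mL),
#'   0 < headspace < vial.
#' @param temp_c,salinity,pressure_atm equilibration conditions.
#' @return headspace mole fraction after equilibrium, ppm.
#' @export
simulate_headspace <- function(conc_mol_l, gas, vial_volume_ml, headspace_volume_ml,
                               temp_c, salinity = 0, pressure_atm = 1) {
  .check_vial(vial_volume_ml, headspace_volume_ml, pressure_atm)
  v_w <- (vial_volume_ml - headspace_volume_ml) / 1000
  v_hs <- headspace_volume_ml / 1000
  tk <- temp_c + 273.15
  k0 <- equilibrium_solubility(gas, temp_c, salinity)
  n_tot <- conc_mol_l * v_w
  p <- n_tot / (v_hs / (.R_GAS * tk) + k0 * v_w)   # partial pressure, atm
  p / pressure_atm * 1e6
}

.check_vial <- function(vial_volume_ml, headspace_volume_ml, pressure_atm) {
  if (any(headspace_volume_ml <= 0) || any(headspace_volume_ml >= vial_volume_ml)) {
    stop("need 0 < headspace_volume_ml < vial_volume_ml (water volume must be positive)",
         call. = FALSE)
  }
  if (any(pressure_atm <= 0)) stop("pressure_atm must be > 0", call. = FALSE)
}

#' Back-calculate dissolved gas from headspace equilibration
#'
#' Inverts the headspace mass balance: original dissolved amount = amount in
#' the equilibrated headspace (ideal gas at T, P) + residual dissolved
#' amount (Henry's law), referenced to the original water volume
#' (vial - headspace).
#'
#' @param samples data.frame with columns `gas`, `headspace_ppm`,
#'   `vial_volume_ml`, `headspace_volume_ml`, `temp_c`, and optionally
#'   `salinity` (default 0), `pressure_atm` (default 1), plus any label
#'   columns (`timestamp`, `replicate`, ...), which are carried through.
#' @return the samples with added columns `conc_mol_l` (mol/L),
#'   `concentration` (in the per-gas reporting unit) and `unit`
#'   (umol/L for CO2, nmol/L for CH4 and N2O).
#' @export
headspace_to_dissolved <- function(samples) {
  stopifnot(is.data.frame(samples))
  need <- c("gas", "headspace_ppm", "vial_volume_ml", "headspace_volume_ml", "temp_c")
  if (!all(need %in% names(samples))) {
    stop("samples must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (is.null(samples$salinity)) samples$salinity <- 0
  if (is.null(samples$pressure_atm)) samples$pressure_atm <- 1
  if (any(samples$headspace_ppm < 0)) stop("headspace_ppm must be >= 0", call. = FALSE)
  .check_vial(samples$vial_volume_ml, samples$headspace_volume_ml, samples$pressure_atm)
  v_w <- (samples$vial_volume_ml - samples$headspace_volume_ml) / 1000
  v_hs <- samples$headspace_volume_ml / 1000
  tk <- samples$temp_c + 273.15
  k0 <- equilibrium_solubility(samples$gas, samples$temp_c, samples$salinity)
  p <- samples$headspace_ppm * 1e-6 * samples$pressure_atm
  n_tot <- p * v_hs / (.R_GAS * tk) + k0 * p * v_w
  samples$conc_mol_l <- n_tot / v_w
  scale <- .GAS_UNIT_SCALE[samples$gas]
  samples$concentration <- samples$conc_mol_l * unname(scale)
  samples$unit <- unname(.GAS_UNIT_NAME[samples$gas])
  samples
}

#' Percent saturation of dissolved gases
#'
#' Compares dissolved concentrations against air equilibrium at in situ
#' temperature, salinity and ambient pressure: equilibrium concentration =
#' solubility x atmospheric partial pressure, saturation = 100 x
#' dissolved / equilibrium. At high altitude the ambient-pressure correction
#' is essential — at ~0.64 atm equilibrium concentrations are roughly two
#' thirds of their sea-level values.
#'
#' @param dissolved data.frame as returned by [headspace_to_dissolved()]
#'   (needs `gas`, `conc_mol_l`, `temp_c`, optional `salinity`). If a
#'   `water_temp_c` column is present it is used as the in situ temperature
#'   for the equilibrium reference; otherwise `temp_c` is used. The
#'   distinction matters when vials equilibrate in a warm lab but the pond
#'   is cold: solubility, and hence the equilibrium concentration, is
#'   evaluated at in situ conditions.
#' @param atmospheric_ppm named vector of air mole fractions (ppm) per gas;
#'   defaults to modern global means (CO2 420, CH4 1.9, N2O 0.336).
#' @param ambient_pressure_atm ambient (surface) pressure, atm; default
#'   0.64, typical of ~3800 m a.s.l.
#' @return `dissolved` with added `equilibrium_mol_l`, `saturation_pct` and
#'   `status` (supersaturated / equilibrium / subsaturated at the 100%
#'   threshold).
#' @export
saturation_percent <- function(dissolved,
                               atmospheric_ppm = .ATM_PPM,
                               ambient_pressure_atm = 0.64) {
  stopifnot(is.data.frame(dissolved))
  if (!all(c("gas", "conc_mol_l", "temp_c") %in% names(dissolved))) {
    stop("dissolved must have columns gas, conc_mol_l, temp_c", call. = FALSE)
  }
  if (any(atmospheric_ppm <= 0) || ambient_pressure_atm <= 0) {
    stop("atmospheric mole fractions and ambient pressure must be > 0", call. = FALSE)
  }
  s <- if (is.null(dissolved$salinity)) 0 else dissolved$salinity
  t_insitu <- if (is.null(dissolved$water_temp_c)) dissolved$temp_c else dissolved$water_temp_c
  k0 <- equilibrium_solubility(dissolved$gas, t_insitu, s)
  x_atm <- atmospheric_ppm[dissolved$gas]
  if (anyNA(x_atm)) stop("atmospheric_ppm missing an entry for some gas", call. = FALSE)
  dissolved$equilibrium_mol_l <- k0 * unname(x_atm) * 1e-6 * ambient_pressure_atm
  dissolved$saturation_pct <- 100 * dissolved$conc_mol_l / dissolved$equilibrium_mol_l
  # classify with a tiny numerical guard so exact-equilibrium inputs are not
  # tipped by floating-point rounding
  d <- dissolved$saturation_pct - 100
  dissolved$status <- ifelse(abs(d) < 1e-9, "equilibrium",
                             ifelse(d > 0, "supersaturated", "subsaturated"))
  dissolved
}

#' Floating-chamber gas flux
#'
#' Ordinary least-squares slope of chamber mole fraction against time,
#' converted to an areal flux with the ideal-gas molar density at chamber
#' temperature and ambient pressure and the chamber geometry. Positive flux
#' = emission to the atmosphere.
#'
#' @param times_min sampling times, minutes since deployment, strictly
#'   increasing, >= 3 points.
#' @param ppm chamber mole fractions (ppm).
#' @param chamber_volume_l chamber headspace volume (L).
#' @param chamber_area_m2 water surface area covered (m2).
#' @param temp_c,pressure_atm chamber air temperature (C) and ambient
#'   pressure (atm).
#' @param alpha significance level for the trend call; slope
#'   indistinguishable from zero at `alpha` classifies as `"no-trend"`.
#' @return object of class `"flux_estimate"`: `flux` (umol m-2 h-1),
#'   `slope_ppm_min`, `slope_se` (flux units), `r_squared`, `p_value`,
#'   `classification` (accumulation / loss / no-trend), `n`.
#' @export
chamber_flux <- function(times_min, ppm, chamber_volume_l, chamber_area_m2,
                         temp_c, pressure_atm, alpha = 0.05) {
  if (length(times_min) < 3) stop("need >= 3 chamber timepoints", call. = FALSE)
  if (length(ppm) != length(times_min)) stop("times and mole fractions differ in length", call. = FALSE)
  if (anyDuplicated(times_min)) stop("duplicate chamber times", call. = FALSE)
  if (is.unsorted(times_min, strictly = TRUE)) stop("chamber times must be strictly increasing", call. = FALSE)
  if (stats::var(ppm) == 0) {
    out <- list(flux = 0, slope_ppm_min = 0, slope_se = 0, r_squared = NA_real_,
                p_value = NA_real_, classification = "no-trend", n = length(times_min))
    class(out) <- "flux_estimate"
    return(out)
  }
  fit <- stats::lm(ppm ~ times_min)
  sm <- quiet_perfect_fit(summary(fit))
  slope <- unname(stats::coef(fit)[2])
  se <- unname(sm$coefficients[2, 2])
  p <- unname(sm$coefficients[2, 4])
  # ppm min-1 -> umol m-2 h-1: x1e-6 atm x V/(R T) mol, x60 to hours, x1e6 to umol
  conv <- pressure_atm * chamber_volume_l * 60 /
    (.R_GAS * (temp_c + 273.15) * chamber_area_m2)
  no_trend <- is.na(p) || p >= alpha
  out <- list(
    flux = slope * conv,
    slope_ppm_min = slope,
    slope_se = se * conv,
    r_squared = sm$r.squared,
    p_value = p,
    classification = if (no_trend) "no-trend" else if (slope > 0) "accumulation" else "loss",
    n = length(times_min)
  )
  class(out) <- "flux_estimate"
  out
}

#' @export
print.flux_estimate <- function(x, ...) {
  cat(sprintf("Chamber flux: %.4g umol m-2 h-1 (se %.3g, r2 %.3g, n = %d) — %s\n",
              x$flux, x$slope_se, x$r_squared, x$n, x$classification))
  invisible(x)
}
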