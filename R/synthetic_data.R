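#' Ground-truth parameter set for the synthetic diel pond
#'
#' Assembles the generator's ground truth: a clear shallow pond under an
#' extreme high-altitude diel radiation cycle. Defaults encode the study
#' conditions the pipeline targets — strong PAR attenuation (Kd 0.32 cm-1),
#' a unimodal radiation day peaking near 1100 umol m-2 s-1 PAR (165 / 58
#' W m-2 UVA / UVB), air temperature from -5 to 18 C, a noon wind ramp from
#' 1 to 6 m s-1, midday Fv/Fm depression from 0.80 to 0.75 with high
#' afternoon recovery, dissolved-gas means of 23.4 uM CO2, 163.1 nM CH4 and
#' 7.3 nM N2O, a positive afternoon CH4 chamber slope, and morning
#' nitrification rates above afternoon ones.
#'
#' @param seed integer seed; the same seed and parameters give a
#'   bit-identical bundle. Sub-streams per table are derived as seed + a
#'   fixed per-table offset.
#' @param ... named overrides of any top-level component (`light`,
#'   `forcing`, `photo`, `gas`, `incubation`), each a list merged over the
#'   defaults.
#' @return list of class `"synthetic_truth"`.
#' @export
synth_truth <- function(seed = 1L, ...) {
  truth <- list(
    seed = as.integer(seed),
    light = list(
      kd_true = 0.32,          # cm-1
      e0 = 1000,               # subsurface PAR, umol m-2 s-1
      depths_cm = seq(0, 14, by = 2),
      noise_sdlog = 0.05       # multiplicative lognormal sensor noise
    ),
    forcing = list(
      sunrise_h = 7, sunset_h = 19,
      peak_par = 1100,         # umol m-2 s-1
      peak_uva = 165, peak_uvb = 58,  # W m-2
      temp_min_c = -5, temp_max_c = 18, temp_lag_h = 1,
      wind_low_ms = 1, wind_high_ms = 6
    ),
    photo = list(
      baseline_yield = 0.78,
      yield_coupling = 0.23,   # fractional yield loss at peak irradiance
      baseline_fvfm = 0.80,
      midday_depression = 0.0625,  # 0.80 -> 0.75 at solar noon
      recovery_fraction = 0.98,
      fm_prime_scale = 1000,
      noise_sd = 0.01,
      interval_h = 2
    ),
    gas = list(
      mean_conc = c(CO2 = 23.4e-6, CH4 = 163.1e-9, N2O = 7.3e-9),  # mol/L
      # signed fractional diel modulation: CH4 accumulates towards the
      # evening, CO2 and N2O are higher in the morning
      diel_amplitude = c(CO2 = -0.15, CH4 = 0.15, N2O = -0.15),
      sample_hours = c(8, 11, 15, 18),  # symmetric about 13:00
      n_replicates = 3,
      vial_volume_ml = 20, headspace_volume_ml = 5,
      equilibration_temp_c = 20,   # lab headspace equilibration
      water_temp_c = 8,        # in situ pond water (equilibrium reference)
      salinity = 1.5,          # brackish pond water
      pressure_atm = 0.64,     # ~3800 m a.s.l.
      headspace_noise_rel = 0.01,
      chamber = list(
        start_ppm = c(CO2 = 420, CH4 = 1.9, N2O = 0.336),
        slope_ppm_min = c(CO2 = -0.5, CH4 = 0.05, N2O = 0),
        noise_sd_ppm = c(CO2 = 2, CH4 = 0.15, N2O = 0.002),
        times_min = seq(0, 80, by = 20),   # every 20 min, 16:00-17:20
        volume_l = 20, area_m2 = 0.25, temp_c = 15
      )
    ),
    incubation = list(
      morning = list(r_control = 0.3, r_aob = 0.4, r_aoa = 0.2, r_other = -0.05),
      afternoon = list(r_control = 0.12, r_aob = 0.16, r_aoa = 0.08, r_other = -0.02),
      efficacy = c(azide = 1, gc7 = 1, atu_aob = 1, atu_aoa = 0),
      initial_um = 0.1, duration_h = 5.5,
      noise_sd_um = 0.05, n_replicates = 2
    )
  )
  over <- list(...)
  for (nm in names(over)) truth[[nm]] <- utils::modifyList(truth[[nm]], over[[nm]])
  class(truth) <- "synthetic_truth"
  truth
}

# fixed per-table seed offsets (documented sub-stream derivation)
.SUBSTREAM <- c(forcing = 0L, profile = 1L, pam = 2L, vials = 3L,
                chamber = 4L, incubation_morning = 5L, incubation_afternoon = 6L)

# normalised half-sine solar elevation proxy: 0 outside daylight
.half_sine <- function(h, sunrise, sunset) {
  s <- sin(pi * (h - sunrise) / (sunset - sunrise))
  ifelse(h >= sunrise & h <= sunset, pmax(s, 0), 0)
}

#' Synthetic environmental sensor log
#'
#' Unimodal half-sine radiation curves (PAR, UVA, UVB) peaking at solar
#' noon, a lagged half-sine air-temperature curve between the configured
#' extremes, and a step-ramp wind increase at noon. Deterministic (the
#' sensor log carries no noise).
#'
#' @param truth a [synth_truth()] object.
#' @param timestep_min sampling interval, minutes (> 0).
#' @return data.frame: `time_h`, `par`, `uva`, `uvb`, `air_temp_c`, `wind_ms`.
#' @export
gen_forcing <- function(truth, timestep_min = 10) {
  fc <- truth$forcing
  if (timestep_min <= 0) stop("timestep_min must be > 0", call. = FALSE)
  if (fc$sunrise_h >= fc$sunset_h) stop("sunrise must precede sunset", call. = FALSE)
  h <- seq(0, 24, by = timestep_min / 60)
  s <- .half_sine(h, fc$sunrise_h, fc$sunset_h)
  s_temp <- .half_sine(h, fc$sunrise_h + fc$temp_lag_h, fc$sunset_h + fc$temp_lag_h)
  noon <- (fc$sunrise_h + fc$sunset_h) / 2
  ramp <- pmin(pmax(h - (noon - 0.5), 0), 1)   # 1-hour ramp centred on noon
  data.frame(
    time_h = h,
    par = fc$peak_par * s,
    uva = fc$peak_uva * s,
    uvb = fc$peak_uvb * s,
    air_temp_c = fc$temp_min_c + (fc$temp_max_c - fc$temp_min_c) * s_temp,
    wind_ms = fc$wind_low_ms + (fc$wind_high_ms - fc$wind_low_ms) * ramp
  )
}

#' Synthetic depth-irradiance profiles
#'
#' Beer-Lambert profiles at the true attenuation coefficient with optional
#' multiplicative lognormal sensor noise.
#'
#' @param truth a [synth_truth()] object.
#' @param n_profiles number of replicate profiles.
#' @param noise_sdlog lognormal sigma; 0 gives noiseless profiles.
#' @return data.frame: `profile_id`, `depth_cm`, `e_par`, `site_id`,
#'   `timestamp`.
#' @export
gen_profiles <- function(truth, n_profiles = 1,
                         noise_sdlog = truth$light$noise_sdlog) {
  lt <- truth$light
  set.seed(truth$seed + .SUBSTREAM[["profile"]])
  z <- lt$depths_cm
  out <- do.call(rbind, lapply(seq_len(n_profiles), function(i) {
    e <- lt$e0 * exp(-lt$kd_true * z)
    if (noise_sdlog > 0) e <- e * exp(stats::rnorm(length(z), 0, noise_sdlog))
    data.frame(profile_id = i, depth_cm = z, e_par = e,
               site_id = "pond", timestamp = "12:00")
  }))
  out
}

#' Synthetic diel PAM fluorescence trace
#'
#' Yield II follows `baseline * (1 - coupling * E / E_peak)` plus Gaussian
#' noise, so the yield minimum coincides with the irradiance maximum
#' (photoinhibition coupling by construction). Dark-adapted Fv/Fm carries
#' the configured fractional midday depression (irradiance-shaped) and an
#' afternoon recovery shortfall `1 - recovery_fraction` that accrues
#' linearly over the day. F and Fm' (and Fo, Fm) are back-solved from the
#' yields at the configured Fm' scale.
#'
#' @param truth a [synth_truth()] object.
#' @param forcing sensor log from [gen_forcing()] (regenerated if missing).
#' @return data.frame of fluorescence records: `timestamp` ("HH:MM"), `f`,
#'   `fm_prime`, `fo`, `fm`, `e_par`, `compartment`.
#' @export
gen_pam_trace <- function(truth, forcing = gen_forcing(truth)) {
  ph <- truth$photo
  fc <- truth$forcing
  if (ph$midday_depression < 0 || ph$midday_depression >= 1) {
    stop("midday depression fraction must be in [0, 1)", call. = FALSE)
  }
  set.seed(truth$seed + .SUBSTREAM[["pam"]])
  hours <- seq(fc$sunrise_h, fc$sunset_h, by = ph$interval_h)
  e_par <- stats::approx(forcing$time_h, forcing$par, xout = hours)$y
  s <- e_par / fc$peak_par
  frac_day <- (hours - fc$sunrise_h) / (fc$sunset_h - fc$sunrise_h)
  yield <- ph$baseline_yield * (1 - ph$yield_coupling * s) +
    stats::rnorm(length(hours), 0, ph$noise_sd)
  fvfm <- ph$baseline_fvfm * (1 - ph$midday_depression * s -
                                (1 - ph$recovery_fraction) * frac_day) +
    stats::rnorm(length(hours), 0, ph$noise_sd)
  yield <- pmin(pmax(yield, 0), 1)
  fvfm <- pmin(pmax(fvfm, 0), 1)
  fmp <- ph$fm_prime_scale
  data.frame(
    timestamp = sprintf("%02d:%02d", floor(hours), round((hours %% 1) * 60)),
    f = (1 - yield) * fmp,
    fm_prime = fmp,
    fo = (1 - fvfm) * fmp,
    fm = fmp,
    e_par = e_par,
    compartment = "sediment_mat"
  )
}

#' Synthetic dissolved-gas vials and chamber series
#'
#' Dissolved concentrations follow diel sinusoids around the configured
#' per-gas means, are forward-partitioned into headspace mole fractions
#' ([simulate_headspace()]) and perturbed with multiplicative measurement
#' noise; chamber series are linear trends plus Gaussian noise.
#'
#' @param truth a [synth_truth()] object.
#' @return list with `vials` (a [headspace_to_dissolved()]-ready table, plus
#'   the generating `true_conc_mol_l`), `chambers` (per-gas list of
#'   `data.frame(time_min, ppm)`), and `chamber_geometry`.
#' @export
gen_gas_field <- function(truth) {
  gs <- truth$gas
  if (any(gs$mean_conc < 0)) stop("mean concentrations must be non-negative", call. = FALSE)
  set.seed(truth$seed + .SUBSTREAM[["vials"]])
  grid <- expand.grid(gas = names(gs$mean_conc), hour = gs$sample_hours,
                      replicate = seq_len(gs$n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mod <- 1 + unname(gs$diel_amplitude[grid$gas]) * sin(2 * pi * (grid$hour - 13) / 24)
  conc <- unname(gs$mean_conc[grid$gas]) * mod
  ppm <- simulate_headspace(conc, grid$gas, gs$vial_volume_ml, gs$headspace_volume_ml,
                            gs$equilibration_temp_c, gs$salinity, gs$pressure_atm)
  if (gs$headspace_noise_rel > 0) {
    ppm <- ppm * (1 + stats::rnorm(length(ppm), 0, gs$headspace_noise_rel))
  }
  vials <- data.frame(
    gas = grid$gas,
    headspace_ppm = ppm,
    vial_volume_ml = gs$vial_volume_ml,
    headspace_volume_ml = gs$headspace_volume_ml,
    temp_c = gs$equilibration_temp_c,
    water_temp_c = gs$water_temp_c,
    salinity = gs$salinity,
    pressure_atm = gs$pressure_atm,
    timestamp = sprintf("%02d:%02d", floor(grid$hour), round((grid$hour %% 1) * 60)),
    session = ifelse(grid$hour < 13, "morning", "afternoon"),
    replicate = grid$replicate,
    true_conc_mol_l = conc
  )
  set.seed(truth$seed + .SUBSTREAM[["chamber"]])
  ch <- gs$chamber
  chambers <- lapply(names(ch$start_ppm), function(g) {
    data.frame(
      time_min = ch$times_min,
      ppm = ch$start_ppm[[g]] + ch$slope_ppm_min[[g]] * ch$times_min +
        stats::rnorm(length(ch$times_min), 0, ch$noise_sd_ppm[[g]])
    )
  })
  names(chambers) <- names(ch$start_ppm)
  list(vials = vials,
       chambers = chambers,
       chamber_geometry = list(volume_l = ch$volume_l, area_m2 = ch$area_m2,
                               temp_c = ch$temp_c, pressure_atm = gs$pressure_atm))
}

# net nitrite rate for one treatment flask under the efficacy model:
# azide-combination flasks carry the guild signal the second inhibitor
# isolates (with leak terms for imperfect GC7/ATU); single inhibitors
# subtract the guild they suppress from the control balance
.treatment_rate_model <- function(trt, r, eff) {
  dev <- switch(trt,
    CONTROL   = 0,
    AZIDE     = eff[["azide"]] * r$r_other,
    AZIDE_GC7 = eff[["azide"]] * (r$r_aob + (1 - eff[["gc7"]]) * r$r_aoa),
    AZIDE_ATU = eff[["azide"]] * (r$r_aoa + (1 - eff[["atu_aob"]]) * r$r_aob -
                                    eff[["atu_aoa"]] * r$r_aoa),
    ATU       = -eff[["atu_aob"]] * r$r_aob - eff[["atu_aoa"]] * r$r_aoa,
    GC7       = -eff[["gc7"]] * r$r_aoa,
    stop("unknown treatment: ", trt, call. = FALSE)
  )
  r$r_control + dev
}

#' Synthetic endpoint incubation experiment
#'
#' Generates treatment-labelled initial/final nitrite concentrations from
#' the session's true (control, AOB, AOA, other) rates under the inhibitor
#' efficacy model. With ideal efficacies and zero noise, the
#' inhibitor-difference equations recover the configured rates exactly.
#'
#' @param truth a [synth_truth()] object.
#' @param session `"morning"` or `"afternoon"`.
#' @param treatments treatment labels to generate; default the control, the
#'   three azide combinations and the two single-inhibitor flasks.
#' @return data.frame: `session`, `analyte`, `treatment`, `replicate`,
#'   `initial_um`, `final_um`, `duration_h`.
#' @export
gen_incubation <- function(truth, session = c("morning", "afternoon"),
                           treatments = c("CONTROL", "ATU", "GC7", "AZIDE",
                                          "AZIDE_GC7", "AZIDE_ATU")) {
  session <- match.arg(session)
  inc <- truth$incubation
  if (any(inc$efficacy < 0 | inc$efficacy > 1)) {
    stop("efficacy entries must lie in [0, 1]", call. = FALSE)
  }
  set.seed(truth$seed + .SUBSTREAM[[paste0("incubation_", session)]])
  r <- inc[[session]]
  rows <- expand.grid(treatment = treatments, replicate = seq_len(inc$n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rate <- vapply(rows$treatment, .treatment_rate_model, numeric(1),
                 r = r, eff = inc$efficacy)
  final <- inc$initial_um + rate * inc$duration_h +
    stats::rnorm(nrow(rows), 0, inc$noise_sd_um)
  data.frame(
    session = session, analyte = "nitrite",
    treatment = rows$treatment, replicate = rows$replicate,
    initial_um = inc$initial_um, final_um = final,
    duration_h = inc$duration_h
  )
}

#' Full synthetic input bundle with ground truth
#'
#' Generates every stage input table (sensor log, irradiance profiles, PAM
#' trace, gas vials, chamber series, morning and afternoon incubations)
#' from one seeded truth object.
#'
#' @param seed integer seed.
#' @param truth optionally a pre-built [synth_truth()]; defaults to
#'   `synth_truth(seed)`.
#' @return list of class `"synthetic_bundle"`: `forcing`, `profiles`, `pam`,
#'   `vials`, `chambers`, `chamber_geometry`, `incubations`, `truth`.
#' @export
synth_bundle <- function(seed = 1L, truth = synth_truth(seed)) {
  forcing <- gen_forcing(truth)
  gas <- gen_gas_field(truth)
  out <- list(
    forcing = forcing,
    profiles = gen_profiles(truth),
    pam = gen_pam_trace(truth, forcing),
    vials = gas$vials,
    chambers = gas$chambers,
    chamber_geometry = gas$chamber_geometry,
    incubations = rbind(gen_incubation(truth, "morning"),
                        gen_incubation(truth, "afternoon")),
    truth = truth
  )
  class(out) <- "synthetic_bundle"
  out
}
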