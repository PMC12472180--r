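# required columns per input table
.SCHEMAS <- list(
  forcing = c("time_h", "par", "uva", "uvb", "air_temp_c", "wind_ms"),
  profiles = c("depth_cm", "e_par"),
  pam = c("timestamp", "f", "fm_prime", "e_par"),
  vials = c("gas", "headspace_ppm", "vial_volume_ml", "headspace_volume_ml", "temp_c"),
  chamber = c("time_min", "ppm"),
  incubations = c("treatment", "initial_um", "final_um", "duration_h")
)

.read_table <- function(path, what) {
  if (!file.exists(path)) stop("cannot read input file: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.SCHEMAS[[what]], names(d))
  if (length(miss)) {
    stop(sprintf("%s table missing column(s): %s", what, paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  d
}

#' Read stage input tables from CSV
#'
#' Thin CSV readers that enforce the per-table column schema on entry.
#'
#' @param path path to a CSV file.
#' @return data.frame with at least the schema columns for that table.
#' @name readers
NULL

#' @rdname readers
#' @export
read_profiles <- function(path) .read_table(path, "profiles")

#' @rdname readers
#' @export
read_pam_records <- function(path) .read_table(path, "pam")

#' @rdname readers
#' @export
read_gas_samples <- function(path) .read_table(path, "vials")

#' @rdname readers
#' @export
read_chamber_series <- function(path) .read_table(path, "chamber")

#' @rdname readers
#' @export
read_incubations <- function(path) .read_table(path, "incubations")

#' @rdname readers
#' @export
read_forcing <- function(path) .read_table(path, "forcing")

#' Write a synthetic bundle to CSV + JSON
#'
#' Writes every table of a [synth_bundle()] as plain CSV and the ground
#' truth as `truth.json`, so the bundle can be re-read with the package's
#' readers (or any other tool).
#'
#' @param bundle a `"synthetic_bundle"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(d, f) utils::write.csv(d, file.path(dir, f), row.names = FALSE)
  wr(bundle$forcing, "forcing.csv")
  wr(bundle$profiles, "profiles.csv")
  wr(bundle$pam, "pam.csv")
  wr(bundle$vials, "vials.csv")
  for (g in names(bundle$chambers)) wr(bundle$chambers[[g]], paste0("chamber_", g, ".csv"))
  wr(bundle$incubations, "incubations.csv")
  truth <- bundle$truth
  class(truth) <- NULL
  jsonlite::write_json(c(truth, list(chamber_geometry = bundle$chamber_geometry)),
                       file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a bundle directory written by [write_bundle()]
#'
#' @param dir directory containing the bundle CSVs.
#' @return list with the same table layout as [synth_bundle()] (without the
#'   truth object; `truth.json` is not re-parsed into a truth object).
#' @export
read_bundle <- function(dir) {
  chamber_files <- list.files(dir, pattern = "^chamber_.*\\.csv$", full.names = TRUE)
  chambers <- lapply(chamber_files, read_chamber_series)
  names(chambers) <- sub("^chamber_(.*)\\.csv$", "\\1", basename(chamber_files))
  geom <- NULL
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) geom <- jsonlite::read_json(tj, simplifyVector = TRUE)$chamber_geometry
  out <- list(
    forcing = read_forcing(file.path(dir, "forcing.csv")),
    profiles = read_profiles(file.path(dir, "profiles.csv")),
    pam = read_pam_records(file.path(dir, "pam.csv")),
    vials = read_gas_samples(file.path(dir, "vials.csv")),
    chambers = if (length(chambers)) chambers else NULL,
    chamber_geometry = geom,
    incubations = read_incubations(file.path(dir, "incubations.csv"))
  )
  class(out) <- "synthetic_bundle"
  out
}

.violation <- function(table, code, message) {
  data.frame(table = table, code = code, message = message)
}

#' Validate every input table of a bundle
#'
#' Checks each table against its schema and type invariants and returns a
#' row-per-violation report (empty when the bundle is clean). Nothing is
#' fixed or dropped here; downstream stage functions apply their own QC.
#'
#' @param bundle a bundle list (from [synth_bundle()] or [read_bundle()]).
#' @return data.frame with columns `table`, `code`, `message`.
#' @export
validate_inputs <- function(bundle) {
  v <- list()
  add <- function(x) v[[length(v) + 1]] <<- x

  p <- bundle$profiles
  if (!is.null(p)) {
    for (id in unique(if (is.null(p$profile_id)) 1 else p$profile_id)) {
      pr <- if (is.null(p$profile_id)) p else p[p$profile_id == id, ]
      if (any(diff(pr$depth_cm) <= 0)) {
        add(.violation("profiles", "depth_order", sprintf("profile %s: depths not strictly increasing", id)))
      }
      if (pr$depth_cm[1] != 0) {
        add(.violation("profiles", "no_surface_reference", sprintf("profile %s: first depth != 0", id)))
      }
      if (any(pr$e_par <= 0)) {
        add(.violation("profiles", "nonpositive_irradiance", sprintf("profile %s: non-positive e_par", id)))
      }
    }
  }
  pm <- bundle$pam
  if (!is.null(pm)) {
    if (any(pm$fm_prime <= 0)) add(.violation("pam", "nonpositive_fm_prime", "fm_prime must be > 0"))
    if (any(!pam_qc_valid(pm))) {
      add(.violation("pam", "qc_flagged", sprintf("%d record(s) with F > Fm' or Fo > Fm", sum(!pam_qc_valid(pm)))))
    }
  }
  vi <- bundle$vials
  if (!is.null(vi)) {
    bad_vol <- vi$headspace_volume_ml <= 0 | vi$headspace_volume_ml >= vi$vial_volume_ml
    if (any(bad_vol)) {
      add(.violation("vials", "volume_invariant", sprintf("%d row(s) with headspace_volume outside (0, vial_volume)", sum(bad_vol))))
    }
    if (any(vi$headspace_ppm < 0)) add(.violation("vials", "negative_ppm", "negative headspace mole fraction"))
    if (!all(unique(vi$gas) %in% c("CO2", "CH4", "N2O"))) {
      add(.violation("vials", "unknown_gas", "gas outside {CO2, CH4, N2O}"))
    }
  }
  for (g in names(bundle$chambers)) {
    ch <- bundle$chambers[[g]]
    if (nrow(ch) < 3) add(.violation(paste0("chamber_", g), "too_few_points", "fewer than 3 timepoints"))
    if (is.unsorted(ch$time_min, strictly = TRUE)) {
      add(.violation(paste0("chamber_", g), "time_order", "times not strictly increasing"))
    }
  }
  inc <- bundle$incubations
  if (!is.null(inc)) {
    sess <- if (is.null(inc$session)) list(all = inc) else split(inc, inc$session)
    for (s in names(sess)) {
      if (!"CONTROL" %in% sess[[s]]$treatment) {
        add(.violation("incubations", "missing_control", sprintf("session %s has no CONTROL", s)))
      }
    }
    if (any(inc$duration_h <= 0)) add(.violation("incubations", "nonpositive_duration", "duration_h must be > 0"))
  }
  if (!length(v)) return(.violation(character(0), character(0), character(0)))
  out <- do.call(rbind, v)
  rownames(out) <- NULL
  out
}

#' Run the full diel analysis pipeline
#'
#' Orchestrates light -> PAM -> gases -> rates -> stats on one bundle of
#' inputs and collects every stage output plus a QC log into a single
#' report. All computation happens in the stage functions; a stage whose
#' input is missing or fails is marked skipped/failed and the rest proceed.
#'
#' @param bundle input bundle ([synth_bundle()] or [read_bundle()]).
#' @param noon_window midday window (decimal hours) for the PAM summary.
#' @param alpha significance level for trend calls and group tests.
#' @param atmospheric_ppm,ambient_pressure_atm equilibrium reference for
#'   percent saturation (see [saturation_percent()]).
#' @return list of class `"diel_report"` with elements `validation`,
#'   `light`, `pam`, `gas`, `rates`, `stats`, `skipped`.
#' @export
run_pipeline <- function(bundle, noon_window = c(11, 15), alpha = 0.05,
                         atmospheric_ppm = .ATM_PPM, ambient_pressure_atm = 0.64) {
  skipped <- character(0)
  report <- list(validation = validate_inputs(bundle))

  # light: one Kd per profile, first profile reported as the headline value
  report$light <- if (is.null(bundle$profiles)) {
    skipped <- c(skipped, "light"); NULL
  } else {
    p <- bundle$profiles
    ids <- if (is.null(p$profile_id)) 1 else unique(p$profile_id)
    fits <- lapply(ids, function(id) {
      pr <- if (is.null(p$profile_id)) p else p[p$profile_id == id, ]
      fit_kd(pr)
    })
    kd <- fits[[1]]
    list(kd = kd$kd, se = kd$se, r_squared = kd$r_squared, n_points = kd$n_points,
         attenuation_depth_20pct_cm = attenuation_depth(kd$kd, 0.8),
         fits = fits)
  }

  report$pam <- if (is.null(bundle$pam)) {
    skipped <- c(skipped, "pam"); NULL
  } else {
    diel_summary(bundle$pam, noon_window = noon_window)
  }

  gas <- list()
  if (is.null(bundle$vials)) {
    skipped <- c(skipped, "gas_dissolved")
  } else {
    diss <- saturation_percent(headspace_to_dissolved(bundle$vials),
                               atmospheric_ppm = atmospheric_ppm,
                               ambient_pressure_atm = ambient_pressure_atm)
    gas$dissolved <- diss
    gas$saturation_summary <- do.call(rbind, lapply(split(diss, diss$gas), function(d) {
      data.frame(gas = d$gas[1],
                 mean_concentration = mean(d$concentration), unit = d$unit[1],
                 mean_saturation_pct = mean(d$saturation_pct),
                 status = c("subsaturated", "equilibrium", "supersaturated")[
                   sign(mean(d$saturation_pct) - 100) + 2])
    }))
    rownames(gas$saturation_summary) <- NULL
  }
  if (is.null(bundle$chambers) || is.null(bundle$chamber_geometry)) {
    skipped <- c(skipped, "gas_flux")
  } else {
    geom <- bundle$chamber_geometry
    gas$flux <- lapply(bundle$chambers, function(ch) {
      chamber_flux(ch$time_min, ch$ppm, geom$volume_l, geom$area_m2,
                   geom$temp_c, geom$pressure_atm, alpha = alpha)
    })
  }
  report$gas <- if (length(gas)) gas else NULL

  report$rates <- if (is.null(bundle$incubations)) {
    skipped <- c(skipped, "rates"); NULL
  } else {
    inc <- bundle$incubations
    sess <- if (is.null(inc$session)) list(all = inc) else split(inc, inc$session)
    tr <- lapply(sess, treatment_rates)
    part <- lapply(tr, partition_nitrification)
    contrast <- if (all(c("morning", "afternoon") %in% names(part))) {
      session_contrast(part$morning, part$afternoon)
    } else NULL
    list(treatment_rates = tr, partition = part, session_contrast = contrast)
  }

  stats_out <- list()
  if (!is.null(report$gas$dissolved) && !is.null(report$gas$dissolved$session)) {
    d <- report$gas$dissolved
    tidy <- data.frame(variable = d$gas, session = d$session, value = d$concentration)
    stats_out$gas_by_session <- compare_many(tidy, alpha = alpha)
  }
  if (!is.null(bundle$forcing) && !is.null(bundle$pam)) {
    idx <- pam_indices(bundle$pam)
    idx$hour <- hour_of_day(idx$timestamp)
    env <- data.frame(
      par = stats::approx(bundle$forcing$time_h, bundle$forcing$par, idx$hour)$y,
      uva = stats::approx(bundle$forcing$time_h, bundle$forcing$uva, idx$hour)$y,
      uvb = stats::approx(bundle$forcing$time_h, bundle$forcing$uvb, idx$hour)$y,
      air_temp_c = stats::approx(bundle$forcing$time_h, bundle$forcing$air_temp_c, idx$hour)$y,
      yield_ii = idx$yield_ii,
      fvfm = idx$fvfm
    )
    stats_out$spearman <- spearman_matrix(env, alpha = alpha)
  }
  report$stats <- if (length(stats_out)) stats_out else NULL
  if (is.null(report$stats)) skipped <- c(skipped, "stats")

  report$skipped <- skipped
  class(report) <- "diel_report"
  report
}

#' @export
print.diel_report <- function(x, ...) {
  cat("Diel pond report\n")
  if (!is.null(x$light)) {
    cat(sprintf("  Kd(PAR) %.3f cm-1 (r2 %.3f); 20%% PAR attenuation at %.2f cm\n",
                x$light$kd, x$light$r_squared, x$light$attenuation_depth_20pct_cm))
  }
  if (!is.null(x$pam)) {
    cat(sprintf("  Fv/Fm noon min %.3f (midday depression %.3f, recovery %.3f)\n",
                x$pam$fvfm_noon_min, x$pam$midday_depression, x$pam$recovery_fraction))
  }
  if (!is.null(x$gas$saturation_summary)) {
    s <- x$gas$saturation_summary
    cat(sprintf("  %s: %.4g %s, %.0f%% saturation (%s)\n",
                s$gas, s$mean_concentration, s$unit, s$mean_saturation_pct, s$status))
  }
  if (!is.null(x$gas$flux)) {
    for (g in names(x$gas$flux)) {
      f <- x$gas$flux[[g]]
      cat(sprintf("  %s chamber flux %.3g umol m-2 h-1 (%s)\n", g, f$flux, f$classification))
    }
  }
  if (!is.null(x$rates$session_contrast)) {
    sc <- x$rates$session_contrast
    cat(sprintf("  nitrification %s: morning %.3f vs afternoon %.3f uM h-1%s\n",
                sc$quantity, sc$morning, sc$afternoon,
                ifelse(sc$morning_higher, " (morning higher)", "")))
  }
  if (length(x$skipped)) cat("  skipped:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' Write a diel report to disk
#'
#' Serialises the report as one JSON file plus tidy CSVs for the tabular
#' stage outputs.
#'
#' @param report a `"diel_report"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_diel_report <- function(report, dir) {
  stopifnot(inherits(report, "diel_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json <- list(
    light = report$light[c("kd", "se", "r_squared", "n_points", "attenuation_depth_20pct_cm")],
    pam = report$pam[c("midday_depression", "recovery_fraction",
                       "fvfm_morning_max", "fvfm_noon_min", "hour_min_yield")],
    gas_flux = lapply(report$gas$flux, function(f) f[c("flux", "slope_se", "r_squared", "classification")]),
    skipped = report$skipped
  )
  jsonlite::write_json(json, file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  wr <- function(d, f) if (!is.null(d)) utils::write.csv(d, file.path(dir, f), row.names = FALSE)
  wr(report$gas$saturation_summary, "saturation.csv")
  wr(report$gas$dissolved, "dissolved_gases.csv")
  if (!is.null(report$rates)) {
    wr(do.call(rbind, report$rates$partition), "partition.csv")
    wr(report$rates$session_contrast, "session_contrast.csv")
  }
  wr(report$stats$gas_by_session, "stats_gas_by_session.csv")
  if (!is.null(report$pam)) wr(report$pam$indices, "pam_indices.csv")
  wr(report$validation, "validation.csv")
  invisible(dir)
}
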