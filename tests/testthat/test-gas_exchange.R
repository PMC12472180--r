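# independent re-evaluation of the published solubility polynomials,
# written out directly rather than through the package's dispatch
sol_oracle <- function(A, B, temp_c, S, bunsen = FALSE) {
  TK <- temp_c + 273.15
  v <- exp(A[1] + A[2] * 100 / TK + A[3] * log(TK / 100) +
             S * (B[1] + B[2] * TK / 100 + B[3] * (TK / 100)^2))
  if (bunsen) v / 22.414 else v
}

test_that("solubility matches an independent evaluation of the coefficient polynomials", {
  expect_equal(equilibrium_solubility("CO2", 20, 0),
               sol_oracle(c(-58.0931, 90.5069, 22.2940),
                          c(0.027766, -0.025888, 0.0050578), 20, 0),
               tolerance = 1e-4)
  expect_equal(equilibrium_solubility("N2O", 20, 0),
               sol_oracle(c(-62.7062, 97.3066, 24.1406),
                          c(-0.058420, 0.033193, -0.0051313), 20, 0),
               tolerance = 1e-4)
  expect_equal(equilibrium_solubility("CH4", 20, 0),
               sol_oracle(c(-67.1962, 99.1624, 27.9015),
                          c(-0.072909, 0.041674, -0.0064603), 20, 0, bunsen = TRUE),
               tolerance = 1e-4)
})

test_that("solubility decreases with temperature and with salinity", {
  for (g in c("CO2", "CH4", "N2O")) {
    expect_gt(equilibrium_solubility(g, 5, 0), equilibrium_solubility(g, 25, 0))
    expect_gt(equilibrium_solubility(g, 15, 0), equilibrium_solubility(g, 15, 35))
  }
  expect_error(equilibrium_solubility("O2", 15, 0), "unsupported gas")
  expect_warning(equilibrium_solubility("CO2", 45, 0), "extrapolated")
})

test_that("headspace inversion is the exact inverse of forward partitioning", {
  # grid of equilibration conditions and headspace fractions
  for (temp in c(0, 10, 20, 30)) {
    for (sal in c(0, 5, 35)) {
      for (frac in c(0.1, 0.5, 0.9)) {
        for (g in c("CO2", "CH4", "N2O")) {
          conc <- switch(g, CO2 = 25e-6, CH4 = 160e-9, N2O = 7e-9)
          ppm <- simulate_headspace(conc, g, 20, 20 * frac, temp, sal, 0.64)
          back <- headspace_to_dissolved(data.frame(
            gas = g, headspace_ppm = ppm, vial_volume_ml = 20,
            headspace_volume_ml = 20 * frac, temp_c = temp, salinity = sal,
            pressure_atm = 0.64))
          expect_equal(back$conc_mol_l, conc, tolerance = 1e-6)
        }
      }
    }
  }
})

test_that("headspace mass balance is linear and zero maps to zero", {
  s <- data.frame(gas = "CH4", headspace_ppm = 0, vial_volume_ml = 20,
                  headspace_volume_ml = 5, temp_c = 20)
  expect_identical(headspace_to_dissolved(s)$conc_mol_l, 0)
  s1 <- s; s1$headspace_ppm <- 12
  s2 <- s; s2$headspace_ppm <- 24
  expect_equal(headspace_to_dissolved(s2)$conc_mol_l,
               2 * headspace_to_dissolved(s1)$conc_mol_l, tolerance = 1e-12)
  bad <- s; bad$headspace_volume_ml <- 25
  expect_error(headspace_to_dissolved(bad), "water volume")
})

test_that("percent saturation classifies against the equilibrium reference", {
  eq <- equilibrium_solubility("CH4", 10, 0) * 1.9e-6 * 0.64
  d <- data.frame(gas = "CH4", conc_mol_l = c(eq, 2 * eq, 0.5 * eq), temp_c = 10)
  r <- saturation_percent(d, ambient_pressure_atm = 0.64)
  expect_equal(r$saturation_pct, c(100, 200, 50), tolerance = 1e-9)
  expect_identical(r$status, c("equilibrium", "supersaturated", "subsaturated"))
  # scale invariance: scaling dissolved and the reference together is neutral
  r2 <- saturation_percent(transform(d, conc_mol_l = conc_mol_l * 3),
                           atmospheric_ppm = c(CH4 = 1.9 * 3),
                           ambient_pressure_atm = 0.64)
  expect_equal(r2$saturation_pct, r$saturation_pct, tolerance = 1e-9)
})

test_that("chamber flux equals the closed-form ideal-gas conversion of the slope", {
  # hand-computed oracle: 1 ppm/min, V = 20 L, A = 0.25 m2, 15 C, 0.65 atm
  t <- seq(0, 80, 20)
  f <- chamber_flux(t, 400 + 1 * t, 20, 0.25, 15, 0.65)
  oracle <- 1e-6 * 0.65 * 20 / (0.08205736 * 288.15) * 60 * 1e6 / 0.25
  expect_equal(f$flux, oracle, tolerance = 1e-9)
  expect_identical(f$classification, "accumulation")
  expect_equal(f$r_squared, 1)
})

test_that("chamber flux trend classification and symmetry", {
  t <- seq(0, 80, 20)
  const <- chamber_flux(t, rep(400, 5), 20, 0.25, 15, 0.65)
  expect_identical(const$flux, 0)
  expect_identical(const$classification, "no-trend")

  set.seed(5)
  ppm <- 400 + 0.8 * t + rnorm(5, 0, 0.5)
  up <- chamber_flux(t, ppm, 20, 0.25, 15, 0.65)
  down <- chamber_flux(t, 800 - (ppm - 400), 20, 0.25, 15, 0.65)
  expect_equal(down$flux, -up$flux, tolerance = 1e-9)
  expect_identical(down$classification, "loss")

  expect_error(chamber_flux(c(0, 20), c(1, 2), 20, 0.25, 15, 0.65), ">= 3")
  expect_error(chamber_flux(c(0, 20, 20), c(1, 2, 3), 20, 0.25, 15, 0.65), "duplicate")
})
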