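test_that("endpoint rates follow (final - initial) / duration with sign symmetry", {
  expect_equal(endpoint_rate(1, 2, 5), 0.2)
  expect_identical(endpoint_rate(3, 3, 6), 0)
  expect_equal(endpoint_rate(2, 1, 5), -0.2)
  expect_equal(endpoint_rate(1, 2, 5), -endpoint_rate(2, 1, 5))
  expect_error(endpoint_rate(1, 2, 0), "duration")
})

make_exp <- function(rates_by_trt, duration = 5, initial = 1, session = "morning") {
  do.call(rbind, lapply(names(rates_by_trt), function(trt) {
    r <- rates_by_trt[[trt]]
    data.frame(session = session, analyte = "nitrite", treatment = trt,
               replicate = seq_along(r), initial_um = initial,
               final_um = initial + r * duration, duration_h = duration)
  }))
}

test_that("treatment rates summarise replicates with the right spread rule", {
  exp1 <- make_exp(list(CONTROL = c(0.2, 0.4), AZIDE = c(0.1, 0.1),
                        AZIDE_GC7 = c(0.5, 0.6, 0.7)))
  tr <- treatment_rates(exp1)
  ctrl <- tr[tr$treatment == "CONTROL", ]
  expect_equal(ctrl$rate, 0.3)
  expect_equal(ctrl$spread, 0.1)            # half-range for duplicates
  expect_identical(ctrl$spread_type, "half_range")
  expect_identical(tr$spread[tr$treatment == "AZIDE"], 0)
  expect_equal(tr$spread[tr$treatment == "AZIDE_GC7"], sd(c(0.5, 0.6, 0.7)))
  expect_identical(tr$spread_type[tr$treatment == "AZIDE_GC7"], "sd")
  expect_error(treatment_rates(make_exp(list(AZIDE = 0.1))), "CONTROL")
})

test_that("partitioning applies the inhibitor-difference equations", {
  ex <- make_exp(list(CONTROL = 0.1, AZIDE_GC7 = 0.5, AZIDE_ATU = 0.3, AZIDE = 0.05))
  p <- partition_nitrification(treatment_rates(ex))
  expect_equal(p$rate[p$component == "aob"], 0.4)
  expect_equal(p$rate[p$component == "aoa"], 0.2)
  expect_equal(p$rate[p$component == "other"], -0.05)

  # all treatments equal to control -> null partition
  ex0 <- make_exp(list(CONTROL = 0.2, AZIDE_GC7 = 0.2, AZIDE_ATU = 0.2, AZIDE = 0.2))
  expect_equal(partition_nitrification(treatment_rates(ex0))$rate, c(0, 0, 0))

  # missing treatment is named in the error
  exm <- make_exp(list(CONTROL = 0.1, AZIDE_GC7 = 0.5, AZIDE = 0.05))
  expect_error(partition_nitrification(treatment_rates(exm)), "AZIDE_ATU")
})

test_that("partitioning is linear in the treatment rates", {
  base <- list(CONTROL = c(0.1, 0.2), AZIDE_GC7 = c(0.5, 0.6),
               AZIDE_ATU = c(0.25, 0.35), AZIDE = c(0.0, 0.1))
  p1 <- partition_nitrification(treatment_rates(make_exp(base)))
  p3 <- partition_nitrification(treatment_rates(make_exp(lapply(base, `*`, 3))))
  expect_equal(p3$rate, 3 * p1$rate, tolerance = 1e-12)
  expect_equal(p3$u, 3 * p1$u, tolerance = 1e-12)
})

test_that("uncertainties combine in quadrature from the operand spreads", {
  ex <- make_exp(list(CONTROL = c(0.1, 0.3), AZIDE_GC7 = c(0.4, 0.8),
                      AZIDE_ATU = c(0.3, 0.3), AZIDE = c(0.0, 0.0)))
  tr <- treatment_rates(ex)
  p <- partition_nitrification(tr)
  expect_equal(p$u[p$component == "aob"], sqrt(0.2^2 + 0.1^2))
  expect_equal(p$u[p$component == "other"], 0.1)
  expect_true(all(p$u >= 0))
  expect_true(all(p$ci_lo <= p$rate & p$rate <= p$ci_hi))
})

test_that("generator round trip: ideal inhibitors and zero noise recover truth exactly", {
  truth <- synth_truth(2, incubation = list(noise_sd_um = 0))
  for (session in c("morning", "afternoon")) {
    p <- partition_nitrification(treatment_rates(gen_incubation(truth, session)))
    r <- truth$incubation[[session]]
    expect_equal(p$rate[p$component == "aob"], r$r_aob, tolerance = 1e-12)
    expect_equal(p$rate[p$component == "aoa"], r$r_aoa, tolerance = 1e-12)
    expect_equal(p$rate[p$component == "other"], r$r_other, tolerance = 1e-12)
  }
  # all-zero rates with zero noise: endpoints equal the initial value
  t0 <- synth_truth(2, incubation = list(
    noise_sd_um = 0,
    morning = list(r_control = 0, r_aob = 0, r_aoa = 0, r_other = 0)))
  inc <- gen_incubation(t0, "morning")
  expect_equal(inc$final_um, rep(t0$incubation$initial_um, nrow(inc)), tolerance = 1e-12)
})

test_that("recovered guild rates are unbiased as replicate count grows", {
  # ideal inhibitors: mean bias of AOB/AOA estimates shrinks with n
  bias_at_n <- sapply(c(2, 10, 50), function(n) {
    est <- sapply(1:40, function(i) {
      truth <- synth_truth(9000 + n * 100 + i, incubation = list(n_replicates = n))
      p <- partition_nitrification(treatment_rates(gen_incubation(truth, "morning")))
      p$rate[match(c("aob", "aoa"), p$component)]
    })
    tr <- synth_truth(1)$incubation$morning
    rowMeans(est) - c(tr$r_aob, tr$r_aoa)
  })
  # noise sd of a single guild estimate is sigma/duration * sqrt(2/n)
  s <- 0.05 / 5.5
  mc_se <- s * sqrt(2 / c(2, 10, 50)) / sqrt(40)
  expect_true(all(abs(bias_at_n[1, ]) < 4 * mc_se))
  expect_true(all(abs(bias_at_n[2, ]) < 4 * mc_se))
})

test_that("session contrast reports morning-minus-afternoon differences", {
  m <- make_exp(list(CONTROL = 0.1, AZIDE_GC7 = 0.5, AZIDE_ATU = 0.4, AZIDE = 0.05))
  a <- make_exp(list(CONTROL = 0.05, AZIDE_GC7 = 0.25, AZIDE_ATU = 0.15, AZIDE = 0.03),
                session = "afternoon")
  pm <- partition_nitrification(treatment_rates(m))
  pa <- partition_nitrification(treatment_rates(a))
  sc <- session_contrast(pm, pa)
  expect_equal(sc$difference[sc$quantity == "aoa"], 0.3 - 0.1)
  expect_true(sc$morning_higher[sc$quantity == "aob"])
  expect_equal(session_contrast(pm, pm)$difference, c(0, 0, 0))
  expect_error(session_contrast(pm, NULL), "both sessions")
})
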