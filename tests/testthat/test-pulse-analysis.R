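test_that("sinusoidal trace yields one peak per cycle with the full amplitude", {
  t <- seq(0, 60 - 0.01, by = 0.01)
  d <- 500 - 10 * cos(2 * pi * t)   # starts at the baseline trough
  s <- detect_pulses(t, d, min_prominence = 5)
  expect_equal(s$n_peaks, 60)
  expect_equal(s$mean_delta, 20, tolerance = 1e-3)
  expect_equal(s$baseline_diameter, 490, tolerance = 1e-3)
})

test_that("constant traces and short traces are handled without fabrication", {
  t <- seq(0, 10, by = 0.1)
  s <- detect_pulses(t, rep(500, length(t)))
  expect_equal(s$n_peaks, 0L)
  expect_length(s$per_pulse_delta, 0)
  expect_error(detect_pulses(c(0, 1), c(1, 2)), "3 samples")
})

test_that("peak count equals floor(duration x frequency) for phase-0 pulse trains", {
  for (bpm in c(50, 60, 63.6, 90, 120)) {
    tr <- generate_pulsatile_pressure(pulse_spec(80, 120, bpm, 60, 100))
    s <- detect_pulses(tr$time_s, tr$pressure_mmhg, min_prominence = 5)
    expect_equal(s$n_peaks, floor(60 * bpm / 60),
                 info = sprintf("beat rate %g", bpm))
  }
})

test_that("FFT frequency recovers known tones and the generator's beat rate", {
  t <- seq(0, 60 - 0.01, by = 0.01)   # integer number of cycles in window
  expect_equal(pulse_frequency(t, sin(2 * pi * 2 * t)), 2.0,
               tolerance = 1e-6)
  # fundamental rule: harmonic-rich two-tone resolves to the fundamental
  two <- sin(2 * pi * t) + 0.6 * sin(2 * pi * 2 * t)
  expect_lt(abs(pulse_frequency(t, two) - 1.0), 1 / 60 + 1e-9)
  expect_error(pulse_frequency(t, rep(3, length(t))), "constant")
  # sweep over physiological beat rates: recovered within the resolution
  for (bpm in seq(40, 180, by = 20)) {
    tr <- generate_pulsatile_pressure(pulse_spec(80, 120, bpm, 60, 100))
    f <- pulse_frequency(tr$time_s, tr$pressure_mmhg)
    expect_lt(abs(f - bpm / 60), 1 / 60 + 1e-9,
              label = sprintf("beat rate %g: |%g - %g|", bpm, f, bpm / 60))
  }
})

test_that("dynamic compliance formula: closed-form cases and invariances", {
  expect_equal(dynamic_compliance(550, 500, 120, 80), 0.0025)
  expect_equal(dynamic_compliance(500, 500, 120, 80), 0)
  # homogeneous in diameters, depends only on the pressure difference
  expect_equal(dynamic_compliance(550 * 3, 500 * 3, 120, 80), 0.0025)
  expect_equal(dynamic_compliance(550, 500, 130, 90), 0.0025)
  expect_error(dynamic_compliance(550, 500, 80, 80), "p_max")
  expect_error(dynamic_compliance(550, 0, 120, 80), "d_min")
})

test_that("zero-noise periodic recordings give per-pulse Dc with zero spread", {
  drv <- physio_drive(duration = 15)
  rec <- simulate_recording(compliant$params, compliant$geometry, drv)
  rc <- recording_compliance(rec)
  expect_gt(rc$n_pulses, 10)
  expect_equal(rc$sd_dc, 0)
  # matches the closed-form single-pulse value from the forward model
  cur <- pressure_diameter_curve(compliant$params, compliant$geometry,
                                 c(80, 120))
  dc1 <- dynamic_compliance(cur$outer_diameter_um[2],
                            cur$outer_diameter_um[1], 120, 80)
  expect_equal(rc$mean_dc, dc1, tolerance = 0.01)
})

test_that("compliant preset has higher dynamic compliance than stiff", {
  drv <- physio_drive(duration = 15)
  rc <- recording_compliance(
    simulate_recording(compliant$params, compliant$geometry, drv))
  rs <- recording_compliance(
    simulate_recording(stiff$params, stiff$geometry, drv))
  expect_gt(rc$mean_dc, rs$mean_dc)
  expect_gt(rc$pulses$mean_delta, rs$pulses$mean_delta)
})

test_that("burst pressure returns the last sustained level", {
  sp <- step_spec(0, 64.37, 5, 450, 10)
  lt <- pressure_diameter_curve(compliant$params, compliant$geometry,
                                0:7 * 64.37)$lambda_theta
  sig <- circ_stress(compliant$params, lt, 1)
  rec <- simulate_burst_experiment(compliant$params, compliant$geometry,
                                   sp, mean(sig[7:8]))
  bp <- burst_pressure(rec)
  expect_true(bp$burst)
  expect_equal(bp$burst_pressure_mmhg, 7 * 64.37)
  # no rupture: completed protocol reported, not labeled a burst
  full <- simulate_burst_experiment(compliant$params, compliant$geometry,
                                    sp, Inf)
  bf <- burst_pressure(full)
  expect_false(bf$burst)
  expect_equal(bf$max_pressure_mmhg, 450.59)
})

test_that("pressure sensor noise barely moves the burst estimate", {
  sp <- step_spec(0, 64.37, 5, 450, 10)
  lt <- pressure_diameter_curve(compliant$params, compliant$geometry,
                                0:7 * 64.37)$lambda_theta
  sig <- circ_stress(compliant$params, lt, 1)
  errs <- vapply(1:10, function(s) {
    rec <- simulate_burst_experiment(compliant$params, compliant$geometry,
                                     sp, mean(sig[7:8]), pressure_sd = 2,
                                     seed = s)
    burst_pressure(rec)$burst_pressure_mmhg - 7 * 64.37
  }, numeric(1))
  expect_lt(max(abs(errs)), 3 * 2)
})

test_that("plateau pressure matches the closed-form saturating curve", {
  P <- seq(0, 400, by = 1)
  expect_equal(plateau_pressure(P, 100 * (1 - exp(-P / 50)), 0.1),
               115, tolerance = 3)      # analytic -50 log(0.1) = 115.13
  # straight line never plateaus
  expect_true(is.na(plateau_pressure(P, 3 * P, 0.1)))
  # invariant to a uniform diameter offset
  expect_equal(plateau_pressure(P, 100 * (1 - exp(-P / 50)) + 250, 0.1),
               plateau_pressure(P, 100 * (1 - exp(-P / 50)), 0.1))
  expect_error(plateau_pressure(c(0, 1, 2), c(1, 2, 3)), "4")
})

test_that("preset pressure-diameter curves plateau in the calibrated order", {
  ps <- seq(0, 300, by = 2)
  cc <- pressure_diameter_curve(compliant$params, compliant$geometry, ps)
  cs <- pressure_diameter_curve(stiff$params, stiff$geometry, ps)
  plat_c <- plateau_pressure(cc$pressure_mmhg, cc$outer_diameter_um)
  plat_s <- plateau_pressure(cs$pressure_mmhg, cs$outer_diameter_um)
  expect_lt(plat_s, plat_c)
  expect_equal(plat_c, 200, tolerance = 0.15)
  expect_equal(plat_s, 125, tolerance = 0.15)
})

test_that("vasoreactivity normalization reproduces the worked examples", {
  # min-max arithmetic: range 100, so (400, 380, 320, 300) maps to
  # (0, 20, 80, 100) percent constriction
  expect_equal(percent_constriction(c(400, 380, 320, 300)),
               c(0, 20, 80, 100))
  expect_equal(percent_relaxation(c(300, 320, 360, 400)), c(0, 20, 60, 100))
  expect_equal(percent_relaxation(c(300, 400)), c(0, 100))
  # shift invariance and order preservation
  expect_equal(percent_constriction(c(400, 380, 320, 300) + 57),
               c(0, 20, 80, 100))
  expect_equal(percent_relaxation(c(300, 320, 360, 400) - 12),
               c(0, 20, 60, 100))
  mono <- percent_constriction(seq(500, 400, by = -10))
  expect_true(all(diff(mono) > 0))
  expect_error(percent_constriction(c(300, 300)), "equal")
  expect_error(percent_relaxation(c(300, 300)), "dilation")
})

test_that("dose-response objects are type-checked by the normalizers", {
  dr <- simulate_dose_response(400, 0.4, 1e-6, 1, 10^seq(-8, -4), "constrictor")
  pc <- percent_constriction(dr)
  expect_equal(max(pc), 100)
  expect_equal(pc[which.max(dr$diameter_um)], 0)
  expect_error(percent_relaxation(dr), "dilator")
})
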