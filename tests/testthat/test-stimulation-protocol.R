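test_that("spherical-cap strain-volume map matches closed-form geometry", {
  p <- membrane_params(22)
  a <- 11
  expect_equal(cap_strain_from_volume(0, p)$radial_strain, 0)
  expect_equal(cap_strain_from_volume(0, p)$cap_height_mm, 0)
  expect_error(cap_strain_from_volume(-1, p), ">= 0")

  # hemisphere: dV = (2/3) pi a^3 -> strain (pi - 2) / 2
  hemi <- cap_strain_from_volume((2 / 3) * pi * a^3, p)
  expect_equal(hemi$radial_strain, (pi - 2) / 2, tolerance = 1e-9)
  expect_equal(hemi$cap_height_mm, a, tolerance = 1e-9)

  # strict monotonicity over the inflation range
  grid <- seq(0, (2 / 3) * pi * a^3, length.out = 200)
  st <- cap_strain_from_volume(grid, p)$radial_strain
  expect_true(all(diff(st) > 0))

  # small-deflection limit: strain ~ (2/3) (h/a)^2 for h << a
  h <- c(0.01, 0.03, 0.05) * a
  v <- pi * h * (3 * a^2 + h^2) / 6
  st <- cap_strain_from_volume(v, p)$radial_strain
  expect_true(all(abs(st - (2 / 3) * (h / a)^2) / st < 0.01))
})

test_that("strain inversion round-trips and matches a bisection oracle", {
  p <- membrane_params(24)
  for (target in c(5, 10)) {
    v <- volume_for_strain(target, p)
    expect_lt(abs(cap_strain_from_volume(v, p)$radial_strain_percent - target) / 100,
              1e-8)
  }
  expect_equal(volume_for_strain(0, p), 0)
  expect_error(volume_for_strain(60, p), "target strain")

  # independent oracle: bisection on volume through the forward map
  bisect_volume <- function(target_pct, params) {
    a <- params$membrane_diameter_mm / 2
    lo <- 0; hi <- (2 / 3) * pi * a^3
    for (i in 1:80) {
      mid <- (lo + hi) / 2
      if (cap_strain_from_volume(mid, params)$radial_strain_percent <
          target_pct) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  for (target in seq(1, 39, by = 2)) {
    expect_equal(volume_for_strain(target, p), bisect_volume(target, p),
                 tolerance = 1e-7)
  }
})

test_that("compiled waveforms conserve the protocol spec", {
  # conditioning day: 0 -> 10% ramp over 7 h, then 17 h rest
  wf <- compile_protocol(protocol_spec(phase_ramp(0, 10, 7 * 3600),
                                       phase_rest(17 * 3600)))
  expect_equal(max(wf$strain_percent), 10)
  expect_equal(wf$time_s[which.max(wf$strain_percent)], 7 * 3600)
  rest <- wf$time_s > 7 * 3600
  expect_true(all(wf$strain_percent[rest] == 0))
  expect_equal(length(wf$time_s), 86401L)
  # volumes are attached, zero iff strain zero, increasing with strain
  expect_true(all((wf$delta_volume_uL == 0) == (wf$strain_percent == 0)))
  vpk <- volume_for_strain(10)
  expect_equal(max(wf$delta_volume_uL), vpk, tolerance = 1e-6)

  # training day: 3 cycles x 10 stretches at 5%
  tr <- compile_protocol(protocol_spec(
    phase_cyclic(5, 10, 600, cycles_per_day = 3, days = 1)))
  expect_equal(nrow(tr$event_log), 30L)
  expect_equal(max(tr$strain_percent), 5)
  expect_true(all(tr$event_log$peak_strain_percent == 5))
  # stretches 60 s apart within a cycle, cycles 8 h apart
  cyc1 <- tr$event_log$time_s[tr$event_log$cycle == 1]
  expect_equal(diff(cyc1), rep(60, 9))
  starts <- tapply(tr$event_log$time_s, tr$event_log$cycle, min)
  expect_equal(as.numeric(diff(starts)), rep(28800, 2))

  # empty protocol
  empty <- compile_protocol(protocol_spec())
  expect_length(empty$time_s, 0)
  expect_equal(nrow(empty$event_log), 0L)

  expect_error(phase_cyclic(5, 10, 600, cycles_per_day = 200), "fit in a day")
})

test_that("waveform volumes agree with the exact inversion", {
  wf <- compile_protocol(protocol_spec(phase_ramp(0, 25, 600)), dt_s = 10)
  pos <- wf$strain_percent > 0
  exact <- volume_for_strain(wf$strain_percent[pos])
  expect_lt(max(abs(wf$delta_volume_uL[pos] - exact) / exact), 1e-6)
})

test_that("capability checks flag out-of-range protocols", {
  ok <- capability_check(standard_protocol(ramp_days = 1, training_days = 1))
  expect_true(ok$pass)

  too_strong <- protocol_spec(phase_ramp(0, 35, 3600))
  rep1 <- capability_check(too_strong)
  expect_false(rep1$pass)
  expect_false(all(rep1$phases$strain_ok))
  expect_true(all(rep1$phases$frequency_ok))

  too_fast <- protocol_spec(phase_cyclic(5, 20, 60, stretch_duration_s = 2))
  rep2 <- capability_check(too_fast)
  expect_false(rep2$pass)
  expect_false(all(rep2$phases$frequency_ok))
  expect_true(all(rep2$phases$strain_ok))
})
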