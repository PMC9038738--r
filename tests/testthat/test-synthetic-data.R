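test_that("spec validation rejects invalid parameters", {
  expect_error(fiber_field_spec(wavelength_px = 2), "Nyquist")
  expect_error(fiber_field_spec(orientation_kappa = -1), "kappa")
  expect_error(nuclei_field_spec(axis_ratio = 0.5), "axis_ratio")
  expect_error(make_calcium_trace(baseline = 0, amplitude = 1), "positive")
})

test_that("gratings have the stated geometry and are deterministic", {
  img <- make_grating(fiber_field_spec(stripe_angle_deg = 0, noise_sd = 0))
  # stripe axis 0 deg: intensity constant along x, varying along y
  expect_equal(apply(img$values, 1, stats::sd), rep(0, nrow(img$values)))
  expect_gt(stats::sd(img$values[, 1]), 0)
  expect_true(all(img$values >= 0 & img$values <= 1))

  spec <- fiber_field_spec(stripe_angle_deg = 30, noise_sd = 0.1, seed = 42)
  expect_identical(make_grating(spec)$values, make_grating(spec)$values)
  # a different seed changes the noise
  spec2 <- fiber_field_spec(stripe_angle_deg = 30, noise_sd = 0.1, seed = 43)
  expect_false(identical(make_grating(spec)$values, make_grating(spec2)$values))
})

test_that("grating orientation is recovered downstream to 1 degree", {
  img <- small_grating(30, n = 128, wavelength = 16)
  o <- orientation_coherency(structure_tensor(compute_gradients(img)))
  expect_lt(ax_dist(o$theta_deg, 30), 1)
  # brute-force angle sweep agrees on the same image
  bf <- dominant_direction_bruteforce(img, angle_step_deg = 0.5)
  expect_lt(ax_dist(bf$theta_deg, 30), 1)
})

test_that("fiber fields sample the requested axial distribution", {
  ff <- make_fiber_field(fiber_field_spec(orientation_kappa = 0,
                                          n_fibers = 2000, seed = 7))
  expect_gt(ax_stats(ff$angles_deg)$circ_var, 0.9)  # isotropic: circ var ~ 1

  ff2 <- make_fiber_field(fiber_field_spec(orientation_kappa = 50,
                                           orientation_mu_deg = 20,
                                           n_fibers = 500, seed = 7))
  expect_lt(ax_dist(ax_stats(ff2$angles_deg)$mean_deg, 20), 2)

  # ordering: higher kappa -> lower circular variance (fixed seed and n)
  cv <- vapply(c(0, 2, 10, 50), function(k)
    ax_stats(make_fiber_field(fiber_field_spec(orientation_kappa = k,
                                               n_fibers = 500,
                                               seed = 3))$angles_deg)$circ_var,
    numeric(1))
  expect_true(all(diff(cv) < 0))
})

test_that("fiber fields handle the empty case and are reproducible", {
  ff <- make_fiber_field(fiber_field_spec(n_fibers = 0))
  expect_identical(ff$angles_deg, numeric(0))
  expect_true(all(ff$image$values == 0))

  spec <- fiber_field_spec(orientation_kappa = 5, n_fibers = 30, seed = 99)
  a <- make_fiber_field(spec); b <- make_fiber_field(spec)
  expect_identical(a$image$values, b$image$values)
  expect_identical(a$angles_deg, b$angles_deg)
})

test_that("radial patterns encode the radial reference as ground truth", {
  expect_error(make_radial_pattern(64, 64, center = c(100, 5)), "inside")
  rp <- make_radial_pattern(128, 128, center = c(64, 64), n_spokes = 24,
                            seed = 3)
  ref <- rp$reference
  c0 <- rp$center
  # due east / north of center: 0 and 90 (axially -90) degrees
  expect_equal(ref$angle_field[c0[2] + 1, c0[1] + 1 + 20], 0)
  expect_equal(ax_dist(ref$angle_field[c0[2] + 1 + 20, c0[1] + 1], 90), 0)
  # pipeline self-consistency: recovered orientations track the reference
  omap <- orientation_map(rp$image, window_size_L = 24, stride = 12)
  expect_lt(angular_deviation(omap, ref)$mean_deg, 5)
})

test_that("nuclei images carry usable ground truth", {
  nn <- make_nuclei_image(nuclei_field_spec(axis_ratio = 1, n_nuclei = 20))
  expect_true(all(is.na(nn$angles_deg)))  # circular: orientation undefined
  spec <- nuclei_field_spec(orientation_kappa = 20, n_nuclei = 50, seed = 5)
  a <- make_nuclei_image(spec)
  expect_identical(a$image$values, make_nuclei_image(spec)$image$values)
  expect_length(a$angles_deg, 50)
  expect_true(all(a$image$values >= 0 & a$image$values <= 1))
})

test_that("calcium traces follow the stated transient model", {
  tr <- make_calcium_trace(baseline = 2, amplitude = 0, noise_sd = 0)
  expect_true(all(tr$F == 2))
  tr <- make_calcium_trace(baseline = 1, amplitude = 1, noise_sd = 0)
  expect_equal(max(tr$F), 2)  # peak dF/F0 = 1 at onset
  expect_true(all(tr$F[tr$time_s < tr$stimulus_time_s] == 1))
  # noisy peak stays within 3 noise-sd of amplitude/baseline
  trn <- make_calcium_trace(baseline = 1, amplitude = 0.8, noise_sd = 0.02,
                            seed = 4)
  q <- delta_f_over_f0(trn)
  expect_lt(abs(q$peak_dFF0 - 0.8), 3 * 0.02)
})
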