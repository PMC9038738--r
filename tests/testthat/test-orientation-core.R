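test_that("gradient estimates match analytic fields", {
  const <- image2d(matrix(5, 32, 32))
  g <- compute_gradients(const)
  expect_equal(max(abs(g$fx)), 0, tolerance = 1e-12)
  expect_equal(max(abs(g$fy)), 0, tolerance = 1e-12)

  ramp <- image2d(matrix(0:31, 32, 32, byrow = TRUE))  # f = x
  g <- compute_gradients(ramp, sigma = 1.5)
  interior <- 8:24
  expect_equal(g$fx[interior, interior],
               matrix(1, length(interior), length(interior)),
               tolerance = 1e-10)
  expect_equal(max(abs(g$fy[interior, interior])), 0, tolerance = 1e-10)

  # 45-degree ramp: f = (x + y)/sqrt(2), gradient (1, 1)/sqrt(2)
  x <- matrix(0:31, 32, 32, byrow = TRUE); y <- matrix(0:31, 32, 32)
  g <- compute_gradients(image2d((x + y) / sqrt(2)))
  expect_equal(g$fx[interior, interior][1, 1], 1 / sqrt(2), tolerance = 1e-10)
  expect_equal(g$fy[interior, interior][1, 1], 1 / sqrt(2), tolerance = 1e-10)

  expect_error(compute_gradients(image2d(matrix(0, 3, 3)), sigma = 5),
               "kernel support")
  expect_error(compute_gradients(ramp, sigma = 0), "positive")
})

test_that("structure tensor matches the double-loop summation oracle", {
  img <- withr::with_seed(11, matrix(stats::runif(48 * 40), 48, 40))
  g <- compute_gradients(image2d(img))
  for (win in list(c(20, 24, 16), c(5, 5, 12), c(39, 47, 30))) {
    J <- structure_tensor(g, weight_window(win[1:2], win[3]))
    o <- oracle_structure_tensor(g$fx, g$fy, win[1], win[2], win[3])
    expect_equal(J$jxx, o[["jxx"]], tolerance = 1e-10)
    expect_equal(J$jxy, o[["jxy"]], tolerance = 1e-10)
    expect_equal(J$jyy, o[["jyy"]], tolerance = 1e-10)
  }
  expect_error(structure_tensor(g, weight_window(c(500, 500), 10)),
               "intersect")
})

test_that("structure tensor reflects texture geometry", {
  g0 <- compute_gradients(image2d(matrix(1, 32, 32)))
  J0 <- structure_tensor(g0)
  expect_lt(abs(J0$jxx) + abs(J0$jxy) + abs(J0$jyy), 1e-20)

  # horizontal stripes (axis 0): intensity varies only along y
  g <- compute_gradients(small_grating(0, n = 96))
  J <- structure_tensor(g)
  expect_gt(J$jyy, 100 * J$jxx)
  expect_lt(abs(J$jxy), 1e-6 * J$jyy)
  # positive semi-definite
  expect_gte(J$jxx * J$jyy - J$jxy^2, -1e-10 * (J$jxx + J$jyy)^2)
})

test_that("orientation and coherency handle degenerate tensors", {
  iso <- structure(list(jxx = 3, jxy = 0, jyy = 3), class = "structure_tensor")
  o <- orientation_coherency(iso)
  expect_equal(o$coherency, 0)
  expect_true(is.na(o$theta_deg))

  zero <- structure(list(jxx = 0, jxy = 0, jyy = 0), class = "structure_tensor")
  o <- orientation_coherency(zero)
  expect_false(o$valid)
  expect_equal(o$coherency, 0)
})

test_that("tensor invariants hold on random seeded fields", {
  for (s in 1:8) {
    ff <- make_fiber_field(fiber_field_spec(height = 64, width = 64,
                                            orientation_kappa = s,
                                            n_fibers = 25, seed = s))
    J <- structure_tensor(compute_gradients(ff$image))
    o <- orientation_coherency(J)
    # trace conservation
    expect_equal(o$lambda_max + o$lambda_min, J$jxx + J$jyy,
                 tolerance = 1e-10)
    expect_gte(o$lambda_max, o$lambda_min)
    expect_gte(o$coherency, 0); expect_lte(o$coherency, 1)
    # intensity invariance: scaling by c scales energy by c^2 only
    J2 <- structure_tensor(compute_gradients(
      image2d(3.7 * ff$image$values)))
    o2 <- orientation_coherency(J2)
    expect_equal(o2$energy, 3.7^2 * o$energy, tolerance = 1e-10)
    expect_equal(o2$theta_deg, o$theta_deg, tolerance = 1e-8)
    expect_equal(o2$coherency, o$coherency, tolerance = 1e-10)
  }
})

test_that("brute-force arg-max agrees with the eigen route", {
  img <- small_grating(0, n = 96)
  bf <- dominant_direction_bruteforce(img, angle_step_deg = 0.5)
  # gradients are perpendicular to the stripes
  expect_equal(ax_dist(bf$gradient_axis_deg, 90), 0)

  g <- compute_gradients(img)
  J <- structure_tensor(g)
  o <- orientation_coherency(J)
  # Rayleigh-quotient identity at the exact eigen angle, by direct summation
  e_at_eigen <- oracle_direnergy(g$fx, g$fy, o$gradient_axis_deg)
  expect_equal(e_at_eigen, o$lambda_max, tolerance = 1e-8)

  for (s in 1:5) {
    ff <- make_fiber_field(fiber_field_spec(height = 64, width = 64,
                                            orientation_mu_deg = s * 31 - 90,
                                            orientation_kappa = 25,
                                            n_fibers = 25, seed = s))
    o <- orientation_coherency(structure_tensor(compute_gradients(ff$image)))
    bf <- dominant_direction_bruteforce(ff$image, angle_step_deg = 0.5)
    expect_lte(ax_dist(o$theta_deg, bf$theta_deg), 0.5)
  }
})

test_that("orientation maps tile correctly", {
  img <- small_grating(40, n = 128, wavelength = 16)
  omap <- orientation_map(img, window_size_L = 32, stride = 16)
  expect_true(all(omap$valid))
  # interior tiles (windows clear of the reflection-padded border) agree
  margin <- 16 + 5  # window half-size + gradient kernel radius
  inner <- omap$x0 >= margin & omap$x0 <= 127 - margin &
           omap$y0 >= margin & omap$y0 <= 127 - margin
  th <- omap$theta_deg[inner]
  expect_lt(max(ax_dist(th, 40)), 1)
  expect_lt(diff(range(th)), 1)
  # boundary tiles are still close, just reflection-biased
  expect_lt(max(ax_dist(omap$theta_deg, 40)), 3)

  blank <- image2d(matrix(0, 64, 64))
  expect_true(all(!orientation_map(blank, window_size_L = 16)$valid))

  expect_error(orientation_map(img, window_size_L = 4, sigma = 2), "sigma")
  expect_error(orientation_map(img, window_size_L = 16, stride = 1000),
               "stride")
})

test_that("orientation maps are equivariant under exact 90-degree rotation", {
  # odd image size so the tile grid maps onto itself under rotation
  ff <- make_fiber_field(fiber_field_spec(height = 97, width = 97,
                                          orientation_mu_deg = 20,
                                          orientation_kappa = 8,
                                          n_fibers = 60, seed = 3))
  v <- ff$image$values
  # exact 90-degree rotation of the square grid (lossless resampling);
  # axially, +90 and -90 are the same shift
  rot <- t(v)[, rev(seq_len(nrow(v)))]
  m1 <- orientation_map(image2d(v), window_size_L = 24, stride = 12)
  m2 <- orientation_map(image2d(rot), window_size_L = 24, stride = 12)
  a1 <- ax_stats(m1$theta_deg[m1$valid])
  a2 <- ax_stats(m2$theta_deg[m2$valid])
  expect_lt(ax_dist(a1$mean_deg + 90, a2$mean_deg), 2)
  expect_equal(mean(m1$coherency[m1$valid]), mean(m2$coherency[m2$valid]),
               tolerance = 1e-6)
})
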