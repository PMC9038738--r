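# Independent oracles and small helpers shared across the suite.
# These deliberately avoid the package's internal code paths.

# Axial wrap to [-90, 90) and axial (period-180) distance, in [0, 90].
wrap_ax <- function(deg) {
  out <- (deg + 90) %% 180 - 90
  out[out >= 90] <- out[out >= 90] - 180
  out
}
ax_dist <- function(a, b) {
  d <- abs(wrap_ax(a - b))
  pmin(d, 180 - d)
}

# Axial circular mean / variance via angle doubling, independent of the
# package implementation.
ax_stats <- function(deg) {
  z <- mean(exp(2i * deg * pi / 180))
  list(mean_deg = wrap_ax(Arg(z) * 90 / pi), circ_var = 1 - Mod(z))
}

# Brute-force double-loop structure tensor: explicit per-pixel summation of
# the weighted inner products over a box window centered at (x0, y0)
# (0-based), side L. Oracle for structure_tensor().
oracle_structure_tensor <- function(fx, fy, x0, y0, L) {
  jxx <- jxy <- jyy <- 0
  for (r in seq_len(nrow(fx))) {
    for (c in seq_len(ncol(fx))) {
      x <- c - 1; y <- r - 1
      if (abs(x - x0) <= L / 2 && abs(y - y0) <= L / 2) {
        jxx <- jxx + fx[r, c]^2
        jxy <- jxy + fx[r, c] * fy[r, c]
        jyy <- jyy + fy[r, c]^2
      }
    }
  }
  c(jxx = jxx, jxy = jxy, jyy = jyy)
}

# Directional-derivative energy by direct summation over the whole image:
# sum (u . grad f)^2 at probe axis theta (degrees). Rayleigh-quotient
# oracle evaluated at an arbitrary angle.
oracle_direnergy <- function(fx, fy, theta_deg) {
  th <- theta_deg * pi / 180
  sum((cos(th) * fx + sin(th) * fy)^2)
}

# Small standard fixtures.
small_grating <- function(angle, n = 96, wavelength = 12, noise = 0, seed = 1)
  make_grating(fiber_field_spec(height = n, width = n,
                                stripe_angle_deg = angle,
                                wavelength_px = wavelength,
                                noise_sd = noise, seed = seed))

# Exact-Gaussian histogram (the model is realizable, so a perfect fit
# exists): weights are a Gaussian evaluated at the bin centers.
gaussian_histogram <- function(mu = 0, sd = 10, n_bins = 90) {
  centers <- -90 + (seq_len(n_bins) - 0.5) * (180 / n_bins)
  w <- exp(-(wrap_ax(centers - mu))^2 / (2 * sd^2))
  orientation_histogram(rep(centers, times = 1), n_bins = n_bins) -> h
  h$weights <- w / sum(w)
  h
}
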