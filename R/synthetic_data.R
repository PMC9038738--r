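#' Specification for synthetic fiber-texture images
#'
#' A single spec type drives both the sinusoidal grating generator
#' ([make_grating()]) and the stroke-based fiber-field generator
#' ([make_fiber_field()]). Fiber axial angles are drawn from an axial
#' von Mises distribution: `kappa = 0` gives the isotropic control,
#' large `kappa` a strongly oriented field.
#'
#' @param height,width image size in pixels.
#' @param stripe_angle_deg stripe (fiber) axis of the grating, degrees in
#'   `[-90, 90)`, counter-clockwise from +x.
#' @param wavelength_px grating wavelength in pixels; must exceed 2 px
#'   (Nyquist).
#' @param orientation_mu_deg axial mean fiber angle, degrees.
#' @param orientation_kappa non-negative axial von Mises concentration.
#' @param n_fibers number of strokes for [make_fiber_field()].
#' @param noise_sd standard deviation of additive Gaussian intensity noise,
#'   applied after normalizing the clean image to `[0, 1]`.
#' @param seed integer RNG seed; identical spec (seed included) gives
#'   bit-identical output.
#' @return A validated `fiber_field_spec` list.
#' @export
fiber_field_spec <- function(height = 256L, width = 256L,
                             stripe_angle_deg = 30, wavelength_px = 16,
                             orientation_mu_deg = 0, orientation_kappa = 0,
                             n_fibers = 150L, noise_sd = 0, seed = 1L) {
  if (height < 3 || width < 3) stop("image must be at least 3 x 3")
  if (wavelength_px <= 2) stop("wavelength_px must exceed 2 px (Nyquist)")
  if (orientation_kappa < 0) stop("orientation_kappa must be >= 0")
  if (n_fibers < 0) stop("n_fibers must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(height = as.integer(height), width = as.integer(width),
                 stripe_angle_deg = wrap_axial(stripe_angle_deg),
                 wavelength_px = wavelength_px,
                 orientation_mu_deg = orientation_mu_deg,
                 orientation_kappa = orientation_kappa,
                 n_fibers = as.integer(n_fibers),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "fiber_field_spec")
}

#' Specification for synthetic nuclei images
#'
#' Elongated (elliptical) nuclei with major-axis angles drawn from an axial
#' von Mises distribution. Nuclei may overlap; overlaps are resolved by
#' taking the per-pixel maximum intensity.
#'
#' @param n_nuclei number of ellipses.
#' @param axis_ratio major/minor axis ratio, `>= 1`. A ratio of exactly 1
#'   makes the orientation ground truth undefined (circular nuclei): the
#'   returned angles are `NA`.
#' @param orientation_mu_deg,orientation_kappa axial von Mises parameters.
#' @param height,width image size in pixels.
#' @param minor_axis_px semi-minor axis length in pixels.
#' @param seed integer RNG seed.
#' @return A validated `nuclei_field_spec` list.
#' @export
nuclei_field_spec <- function(n_nuclei = 150L, axis_ratio = 3,
                              orientation_mu_deg = 0, orientation_kappa = 10,
                              height = 256L, width = 256L,
                              minor_axis_px = 3, seed = 1L) {
  if (axis_ratio < 1) stop("axis_ratio must be >= 1")
  if (orientation_kappa < 0) stop("orientation_kappa must be >= 0")
  if (n_nuclei < 0) stop("n_nuclei must be >= 0")
  if (minor_axis_px <= 0) stop("minor_axis_px must be positive")
  structure(list(n_nuclei = as.integer(n_nuclei), axis_ratio = axis_ratio,
                 orientation_mu_deg = orientation_mu_deg,
                 orientation_kappa = orientation_kappa,
                 height = as.integer(height), width = as.integer(width),
                 minor_axis_px = minor_axis_px, seed = as.integer(seed)),
            class = "nuclei_field_spec")
}

# von Mises sampler, Best & Fisher (1979) wrapped-Cauchy envelope rejection.
# mu in radians; returns angles in radians (unwrapped around mu).
rvonmises <- function(n, mu, kappa) {
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-10) return(stats::runif(n, mu - pi, mu + pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    z <- cos(pi * stats::runif(1))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- mu + sign(stats::runif(1) - 0.5) * acos(pmin(1, pmax(-1, f)))
    }
  }
  out
}

#' Sample axial angles from an axial von Mises distribution
#'
#' Uses the angle-doubling trick: `2*alpha` is drawn from von Mises
#' (`2*mu`, `kappa`), halved, and wrapped to the axial range `[-90, 90)`.
#' `kappa = 0` is the uniform (isotropic) case.
#'
#' @param n number of angles.
#' @param mu_deg axial mean, degrees.
#' @param kappa concentration, `>= 0`.
#' @return Numeric vector of angles in degrees, `[-90, 90)`.
#' @export
sample_axial_angles <- function(n, mu_deg, kappa) {
  if (kappa < 0) stop("kappa must be >= 0")
  doubled <- rvonmises(n, 2 * mu_deg * pi / 180, kappa)
  wrap_axial(doubled * 180 / pi / 2)
}

# Render an anti-aliased stroke (segment) onto canvas, max-compositing.
# Linear intensity falloff across the final half-pixel of the stroke edge.
render_stroke <- function(canvas, x0, y0, x1, y1, half_width) {
  h <- nrow(canvas); w <- ncol(canvas)
  pad <- ceiling(half_width + 1)
  cmin <- max(1L, floor(min(x0, x1)) - pad); cmax <- min(w, ceiling(max(x0, x1)) + pad)
  rmin <- max(1L, floor(min(y0, y1)) - pad); rmax <- min(h, ceiling(max(y0, y1)) + pad)
  if (cmin > cmax || rmin > rmax) return(canvas)
  xs <- (cmin:cmax) - 1; ys <- (rmin:rmax) - 1
  px <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  py <- matrix(ys, length(ys), length(xs))
  dx <- x1 - x0; dy <- y1 - y0
  len2 <- dx^2 + dy^2
  tt <- if (len2 == 0) matrix(0, nrow(px), ncol(px)) else
    pmin(1, pmax(0, ((px - x0) * dx + (py - y0) * dy) / len2))
  d <- sqrt((px - (x0 + tt * dx))^2 + (py - (y0 + tt * dy))^2)
  val <- pmin(1, pmax(0, half_width + 0.5 - d))
  sub <- canvas[rmin:rmax, cmin:cmax, drop = FALSE]
  canvas[rmin:rmax, cmin:cmax] <- pmax(sub, val)
  canvas
}

#' Generate a sinusoidal grating with a single stripe orientation
#'
#' Intensity varies sinusoidally perpendicular to the stripe axis, so the
#' fiber (stripe) axis at every pixel equals `spec$stripe_angle_deg`. The
#' clean image lies in `[0, 1]`; optional Gaussian noise is added afterwards
#' under the spec seed.
#'
#' @param spec a [fiber_field_spec()].
#' @return An [image2d()].
#' @examples
#' img <- make_grating(fiber_field_spec(stripe_angle_deg = 0, noise_sd = 0))
#' @export
make_grating <- function(spec) {
  stopifnot(inherits(spec, "fiber_field_spec"))
  a <- spec$stripe_angle_deg * pi / 180
  x <- matrix((seq_len(spec$width)) - 1, spec$height, spec$width, byrow = TRUE)
  y <- matrix((seq_len(spec$height)) - 1, spec$height, spec$width)
  # phase advances along the normal (-sin a, cos a) to the stripe axis
  phase <- (-sin(a) * x + cos(a) * y) / spec$wavelength_px
  img <- 0.5 + 0.5 * sin(2 * pi * phase)
  if (spec$noise_sd > 0) {
    img <- withr::with_seed(spec$seed,
      img + matrix(stats::rnorm(length(img), sd = spec$noise_sd),
                   nrow(img), ncol(img)))
  }
  image2d(img)
}

#' Generate a field of elongated fiber strokes with known axial angles
#'
#' Draws `n_fibers` anti-aliased strokes whose axial angles are sampled from
#' the axial von Mises distribution of the spec; `kappa = 0` yields the
#' isotropic control, large `kappa` an oriented control. The sampled angles
#' are returned so downstream recovery error is computable exactly.
#'
#' @param spec a [fiber_field_spec()].
#' @param stroke_width full stroke width in pixels (default 3; gradient
#'   estimation needs features at least ~2 px wide).
#' @return List with `image` ([image2d()]) and `angles_deg` (ground truth,
#'   length `n_fibers`).
#' @export
make_fiber_field <- function(spec, stroke_width = 3) {
  stopifnot(inherits(spec, "fiber_field_spec"))
  h <- spec$height; w <- spec$width
  canvas <- matrix(0, h, w)
  if (spec$n_fibers == 0L) {
    return(list(image = image2d(canvas), angles_deg = numeric(0)))
  }
  res <- withr::with_seed(spec$seed, {
    ang <- sample_axial_angles(spec$n_fibers, spec$orientation_mu_deg,
                               spec$orientation_kappa)
    cx <- stats::runif(spec$n_fibers, 0, w - 1)
    cy <- stats::runif(spec$n_fibers, 0, h - 1)
    len <- stats::runif(spec$n_fibers, 0.3, 0.6) * min(h, w)
    noise <- if (spec$noise_sd > 0)
      matrix(stats::rnorm(h * w, sd = spec$noise_sd), h, w) else NULL
    list(ang = ang, cx = cx, cy = cy, len = len, noise = noise)
  })
  for (i in seq_len(spec$n_fibers)) {
    th <- res$ang[i] * pi / 180
    hx <- cos(th) * res$len[i] / 2; hy <- sin(th) * res$len[i] / 2
    canvas <- render_stroke(canvas, res$cx[i] - hx, res$cy[i] - hy,
                            res$cx[i] + hx, res$cy[i] + hy, stroke_width / 2)
  }
  if (!is.null(res$noise)) canvas <- canvas + res$noise
  list(image = image2d(canvas), angles_deg = res$ang)
}

#' Generate a radial spoke pattern around a center
#'
#' Draws `n_spokes` strokes radiating from `center`; at every drawn pixel
#' the local fiber axis equals the radial direction from the center. Stands
#' in for a radially organized control image; the construction is a stated
#' choice, not a reproduction of any published control.
#'
#' @param height,width image size in pixels.
#' @param center length-2 numeric `(x0, y0)` in 0-based pixel coordinates;
#'   must lie inside the image.
#' @param n_spokes number of spokes (default 36).
#' @param seed RNG seed for the small angular jitter applied to spoke
#'   directions.
#' @param stroke_width full stroke width in pixels.
#' @return List with `image`, `center`, and `reference` (a
#'   [radial_reference()] giving the per-pixel radial axial angle).
#' @export
make_radial_pattern <- function(height = 256L, width = 256L,
                                center = c((width - 1) / 2, (height - 1) / 2),
                                n_spokes = 36L, seed = 1L, stroke_width = 3) {
  if (length(center) != 2 || center[1] < 0 || center[1] > width - 1 ||
      center[2] < 0 || center[2] > height - 1)
    stop("center must lie inside the image")
  canvas <- matrix(0, height, width)
  rmax <- 0.95 * min(center[1], width - 1 - center[1],
                     center[2], height - 1 - center[2])
  r0 <- max(4, 0.08 * rmax)
  jitter_span <- 0.2 * 180 / n_spokes
  phis <- withr::with_seed(seed, {
    seq(0, 360, length.out = n_spokes + 1)[-(n_spokes + 1)] +
      stats::runif(n_spokes, -jitter_span, jitter_span)
  })
  for (phi in phis * pi / 180) {
    canvas <- render_stroke(canvas,
                            center[1] + r0 * cos(phi), center[2] + r0 * sin(phi),
                            center[1] + rmax * cos(phi), center[2] + rmax * sin(phi),
                            stroke_width / 2)
  }
  list(image = image2d(canvas), center = center,
       reference = radial_reference(c(height, width), center))
}

#' Generate an image of elongated nuclei with known major-axis angles
#'
#' Filled, anti-aliased ellipses at uniform random positions; major-axis
#' angles sampled from the axial von Mises distribution of the spec. With
#' `axis_ratio = 1` the nuclei are circular and the orientation ground truth
#' is undefined: the returned angles are all `NA`.
#'
#' @param spec a [nuclei_field_spec()].
#' @return List with `image` ([image2d()]) and `angles_deg` (ground-truth
#'   major-axis angles, `NA` if `axis_ratio == 1`).
#' @export
make_nuclei_image <- function(spec) {
  stopifnot(inherits(spec, "nuclei_field_spec"))
  h <- spec$height; w <- spec$width
  canvas <- matrix(0, h, w)
  if (spec$n_nuclei == 0L)
    return(list(image = image2d(canvas), angles_deg = numeric(0)))
  res <- withr::with_seed(spec$seed, {
    list(ang = sample_axial_angles(spec$n_nuclei, spec$orientation_mu_deg,
                                   spec$orientation_kappa),
         cx = stats::runif(spec$n_nuclei, 0, w - 1),
         cy = stats::runif(spec$n_nuclei, 0, h - 1))
  })
  b <- spec$minor_axis_px
  a <- b * spec$axis_ratio
  for (i in seq_len(spec$n_nuclei)) {
    th <- res$ang[i] * pi / 180
    pad <- ceiling(a + 1)
    cmin <- max(1L, floor(res$cx[i]) - pad); cmax <- min(w, ceiling(res$cx[i]) + pad)
    rmin <- max(1L, floor(res$cy[i]) - pad); rmax <- min(h, ceiling(res$cy[i]) + pad)
    if (cmin > cmax || rmin > rmax) next
    xs <- (cmin:cmax) - 1 - res$cx[i]; ys <- (rmin:rmax) - 1 - res$cy[i]
    px <- matrix(xs, length(ys), length(xs), byrow = TRUE)
    py <- matrix(ys, length(ys), length(xs))
    u <- px * cos(th) + py * sin(th)
    v <- -px * sin(th) + py * cos(th)
    q <- sqrt((u / a)^2 + (v / b)^2)
    val <- pmin(1, pmax(0, (1 - q) * b + 0.5))
    sub <- canvas[rmin:rmax, cmin:cmax, drop = FALSE]
    canvas[rmin:rmax, cmin:cmax] <- pmax(sub, val)
  }
  ang <- if (spec$axis_ratio == 1) rep(NA_real_, spec$n_nuclei) else res$ang
  list(image = image2d(canvas), angles_deg = ang)
}

#' Generate a synthetic calcium-transient fluorescence trace
#'
#' Constant pre-stimulus baseline followed by an instantaneous-rise,
#' exponential-decay transient:
#' `F(t) = baseline` for `t < onset_time`, and
#' `baseline + amplitude * exp(-(t - onset_time) / decay_tau)` afterwards.
#' Optional additive Gaussian noise under the given seed.
#'
#' @param baseline pre-stimulus fluorescence, must be `> 0` (it becomes the
#'   denominator of dF/F0).
#' @param amplitude transient peak height above baseline.
#' @param onset_time_s stimulus time in seconds.
#' @param decay_tau_s exponential decay time constant, seconds.
#' @param noise_sd additive Gaussian noise SD.
#' @param seed RNG seed.
#' @param duration_s trace length in seconds.
#' @param sampling_rate_hz frames per second (default 16, typical of
#'   stereomicroscope video).
#' @return A `calcium_trace` list with `time_s`, `F`, `stimulus_time_s`.
#' @export
make_calcium_trace <- function(baseline, amplitude, onset_time_s = 10,
                               decay_tau_s = 2, noise_sd = 0, seed = 1L,
                               duration_s = 30, sampling_rate_hz = 16) {
  if (baseline <= 0) stop("baseline must be positive (F0 is a divisor)")
  if (decay_tau_s <= 0) stop("decay_tau_s must be positive")
  time_s <- seq(0, duration_s, by = 1 / sampling_rate_hz)
  f <- rep(baseline, length(time_s))
  post <- time_s >= onset_time_s
  f[post] <- baseline + amplitude * exp(-(time_s[post] - onset_time_s) / decay_tau_s)
  if (noise_sd > 0)
    f <- withr::with_seed(seed, f + stats::rnorm(length(f), sd = noise_sd))
  structure(list(time_s = time_s, F = f, stimulus_time_s = onset_time_s),
            class = "calcium_trace")
}
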