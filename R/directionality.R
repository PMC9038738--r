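#' Orientation-distribution histogram over the axial range
#'
#' Bins axial angles (wrapped to `[-90, 90)`) into equal-width bins.
#' Input is either a numeric vector of angles in degrees, or an
#' [orientation_map()] data.frame, in which case invalid tiles are dropped
#' and per-tile weighting can use the tensor energy or coherency-weighted
#' energy so that strongly textured tiles dominate.
#'
#' @param x numeric vector of axial angles (degrees) or an `orientation_map`.
#' @param n_bins number of bins, at least 8 (default 90, i.e. 2-degree bins).
#' @param weighting one of `"count"`, `"energy"`, `"coherency_energy"`;
#'   ignored for plain angle vectors.
#' @param normalize normalize weights to unit mass (default TRUE).
#' @return An `orientation_histogram` list with `bin_centers_deg`,
#'   `weights`, `bin_width_deg`, `normalized`.
#' @export
orientation_histogram <- function(x, n_bins = 90,
                                  weighting = c("count", "energy",
                                                "coherency_energy"),
                                  normalize = TRUE) {
  weighting <- match.arg(weighting)
  if (n_bins < 8) stop("n_bins must be at least 8")
  if (inherits(x, "orientation_map")) {
    keep <- x$valid & !is.na(x$theta_deg)
    angles <- x$theta_deg[keep]
    wts <- switch(weighting,
                  count = rep(1, sum(keep)),
                  energy = x$energy[keep],
                  coherency_energy = x$coherency[keep] * x$energy[keep])
  } else {
    angles <- as.numeric(x[!is.na(x)])
    wts <- rep(1, length(angles))
  }
  if (length(angles) == 0) stop("no orientations to bin")
  angles <- wrap_axial(angles)
  width <- 180 / n_bins
  idx <- pmin(n_bins, floor((angles + 90) / width) + 1)
  weights <- vapply(seq_len(n_bins), function(b) sum(wts[idx == b]), numeric(1))
  if (normalize) {
    total <- sum(weights)
    if (total <= 0) stop("histogram has zero total mass")
    weights <- weights / total
  }
  structure(list(bin_centers_deg = -90 + (seq_len(n_bins) - 0.5) * width,
                 weights = weights, bin_width_deg = width,
                 normalized = normalize),
            class = "orientation_histogram")
}

# Periodic (axial, period-180) distance from angles to mu, in [-90, 90).
periodic_delta <- function(deg, mu) wrap_axial(deg - mu)

# Sum of squared residuals of the periodic Gaussian-peak model.
peak_model <- function(par, centers) {
  d <- periodic_delta(centers, par[["mu"]])
  par[["baseline"]] + par[["amplitude"]] * exp(-d^2 / (2 * par[["sigma"]]^2))
}

#' Fit a Gaussian peak to an orientation histogram
#'
#' Nonlinear least squares of
#' `baseline + amplitude * exp(-delta(angle, mu)^2 / (2 sigma^2))`,
#' where `delta` is the periodic angular distance (period 180 degrees), so
#' peaks near +/-90 degrees are not split. Initialization from the modal
#' bin, with a second start on the strongest secondary mode; the fit with
#' the lower residual sum of squares wins. The goodness score is
#' `max(0, 1 - SS_res / SS_tot)`, clipped to `[0, 1]`: 1 for a perfectly
#' Gaussian-shaped histogram (good alignment), near 0 for a flat one (no
#' preferred orientation).
#'
#' @param hist an [orientation_histogram()] with at least 5 bins.
#' @return A `gaussian_peak_fit` list: `mu_deg`, `sigma_deg`, `amplitude`,
#'   `baseline`, `goodness`, `ss_res`, `ss_tot`.
#' @export
fit_gaussian_peak <- function(hist) {
  stopifnot(inherits(hist, "orientation_histogram"))
  centers <- hist$bin_centers_deg
  w <- hist$weights
  if (length(w) < 5) stop("need at least 5 bins to fit")
  if (all(w == 0)) stop("degenerate all-zero histogram")
  ss_tot <- sum((w - mean(w))^2)
  obj <- function(p) {
    if (p[3] <= 0) return(Inf)  # sigma
    r <- w - peak_model(c(mu = p[1], amplitude = p[2], sigma = p[3],
                          baseline = p[4]), centers)
    sum(r^2)
  }
  fit_from <- function(mu0) {
    p0 <- c(mu0, max(w) - min(w), 2 * hist$bin_width_deg + 5, min(w))
    o <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    stats::optim(o$par, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))
  }
  starts <- centers[which.max(w)]
  # second start: strongest bin at least 30 degrees (axially) from the mode
  far <- axial_distance(centers, starts[1]) >= 30
  if (any(far)) starts <- c(starts, centers[far][which.max(w[far])])
  fits <- lapply(starts, fit_from)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  ss_res <- best$value
  goodness <- if (ss_tot <= 0) 0 else min(1, max(0, 1 - ss_res / ss_tot))
  structure(list(mu_deg = wrap_axial(best$par[1]),
                 sigma_deg = abs(best$par[3]),
                 amplitude = best$par[2], baseline = best$par[4],
                 goodness = goodness, ss_res = ss_res, ss_tot = ss_tot),
            class = "gaussian_peak_fit")
}

#' @export
print.gaussian_peak_fit <- function(x, ...) {
  cat(sprintf(
    "<gaussian_peak_fit> mu %.2f deg, sigma %.2f deg, goodness %.4f\n",
    x$mu_deg, x$sigma_deg, x$goodness))
  invisible(x)
}

#' Alignment score of an image
#'
#' Composition of the tiled structure-tensor analysis
#' ([orientation_map()]), the orientation histogram, and the Gaussian peak
#' fit. The returned fit's `goodness` in `[0, 1]` is the alignment score:
#' high when the imaged structures (myotubes, nuclei, collagen fibers)
#' share one orientation, low for isotropic images.
#'
#' @param image an [image2d()] or matrix.
#' @param window_size_L,stride,sigma,energy_threshold_frac passed to
#'   [orientation_map()].
#' @param n_bins,weighting passed to [orientation_histogram()]; per-tile
#'   weighting defaults to coherency-weighted energy.
#' @return A `gaussian_peak_fit`; its `goodness` is the alignment score.
#' @export
alignment_score <- function(image, window_size_L = 24, stride = 12,
                            sigma = 1.5, energy_threshold_frac = 1e-3,
                            n_bins = 90, weighting = "coherency_energy") {
  omap <- orientation_map(image, window_size_L = window_size_L,
                          stride = stride, sigma = sigma,
                          energy_threshold_frac = energy_threshold_frac)
  if (!any(omap$valid)) stop("no valid tiles (blank image?)")
  fit_gaussian_peak(orientation_histogram(omap, n_bins = n_bins,
                                          weighting = weighting))
}
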