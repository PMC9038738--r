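#' @title Weighted structure-tensor orientation and coherency
#' @description Local texture orientation is estimated from the 2x2
#' structure tensor, the matrix of window-weighted inner products of the
#' image gradient components:
#' \deqn{J = \begin{pmatrix} \langle f_x, f_x\rangle_w & \langle f_x, f_y\rangle_w \\
#'  \langle f_x, f_y\rangle_w & \langle f_y, f_y\rangle_w \end{pmatrix}}
#' J is symmetric positive semi-definite; the eigenvector of its larger
#' eigenvalue is the axis maximizing the windowed directional-derivative
#' energy (the gradient-dominant axis), and the coherency
#' \eqn{C = (\lambda_{max}-\lambda_{min})/(\lambda_{max}+\lambda_{min})}
#' is 1 for a perfectly oriented texture and 0 for an isotropic one.
#' For a striped/fibrous texture gradients run perpendicular to the fibers,
#' so the reported fiber axis is the gradient-dominant axis rotated by 90
#' degrees; both axes are exposed.
#' @name orientation-core
NULL

# 1D Gaussian and Gaussian-derivative kernels over offsets -r..r.
# The derivative kernel is normalized so that a unit-slope ramp responds
# with exactly 1; the smoothing kernel sums to 1.
gaussian_kernels <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- -r:r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  d <- x * exp(-x^2 / (2 * sigma^2))
  d <- d / sum(d * x)
  list(g = g, d = d, radius = r)
}

# Reflect-pad then correlate a matrix with a 1D kernel along rows (dim = 1,
# i.e. the y axis) or columns (dim = 2, the x axis). Correlation form:
# out[i] = sum_k kern[k] * f[i + offset_k].
sep_filter <- function(m, kern, dim) {
  r <- (length(kern) - 1L) / 2L
  n <- if (dim == 1L) nrow(m) else ncol(m)
  if (n < r + 1L) stop("image smaller than kernel support")
  idx <- c(rev(seq_len(r) + 1L), seq_len(n), n - seq_len(r))  # reflect (no edge dup)
  padded <- if (dim == 1L) m[idx, , drop = FALSE] else m[, idx, drop = FALSE]
  out <- matrix(0, nrow(m), ncol(m))
  for (k in seq_along(kern)) {
    if (kern[k] == 0) next
    sl <- (k - 1L) + seq_len(n)
    out <- out + kern[k] *
      (if (dim == 1L) padded[sl, , drop = FALSE] else padded[, sl, drop = FALSE])
  }
  out
}

#' Gaussian-derivative gradient field of an image
#'
#' Estimates `fx = df/dx` and `fy = df/dy` by separable correlation with a
#' Gaussian-derivative kernel along the differentiated axis and a Gaussian
#' smoothing kernel along the other. Boundaries are handled by reflection.
#' Kernels are normalized so a unit-slope linear ramp yields a gradient of
#' exactly 1.
#'
#' @param image an [image2d()] (or plain matrix).
#' @param sigma Gaussian derivative scale in pixels (default 1.5).
#' @return A `gradient_field` list with matrices `fx`, `fy` and `sigma`.
#' @export
compute_gradients <- function(image, sigma = 1.5) {
  img <- as_image2d(image)
  if (sigma <= 0) stop("sigma must be positive")
  k <- gaussian_kernels(sigma)
  v <- img$values
  if (nrow(v) < k$radius + 1L || ncol(v) < k$radius + 1L)
    stop("image smaller than kernel support")
  fx <- sep_filter(sep_filter(v, k$d, 2L), k$g, 1L)
  fy <- sep_filter(sep_filter(v, k$d, 1L), k$g, 2L)
  structure(list(fx = fx, fy = fy, sigma = sigma), class = "gradient_field")
}

#' Weight window for the structure-tensor inner product
#'
#' The non-negative weight `w(x, y)` restricting the inner products to a
#' region of interest: a square box of side `size_L` centered at `center`
#' (the default), or an isotropic Gaussian of SD `size_L / 4` truncated to
#' the same box.
#'
#' @param center length-2 `(x0, y0)`, 0-based pixel coordinates.
#' @param size_L window side in pixels.
#' @param profile `"box"` or `"gaussian"`.
#' @return A `weight_window` list.
#' @export
weight_window <- function(center, size_L, profile = c("box", "gaussian")) {
  profile <- match.arg(profile)
  if (size_L < 1) stop("size_L must be >= 1 pixel")
  structure(list(center = as.numeric(center), size_L = size_L,
                 profile = profile), class = "weight_window")
}

# Evaluate the window weight on the full pixel grid of an h x w image.
window_weights <- function(window, h, w) {
  x <- matrix(0:(w - 1), h, w, byrow = TRUE)
  y <- matrix(0:(h - 1), h, w)
  half <- window$size_L / 2
  inside <- abs(x - window$center[1]) <= half & abs(y - window$center[2]) <= half
  if (!any(inside)) stop("window does not intersect the image")
  if (window$profile == "box") {
    wt <- inside * 1
  } else {
    s <- window$size_L / 4
    wt <- exp(-((x - window$center[1])^2 + (y - window$center[2])^2) / (2 * s^2))
    wt[!inside] <- 0
  }
  wt
}

#' Windowed structure tensor of a gradient field
#'
#' Computes the three weighted inner products `<fx,fx>_w`, `<fx,fy>_w`,
#' `<fy,fy>_w`, discretized as weighted sums over pixels.
#'
#' @param grad a `gradient_field` from [compute_gradients()].
#' @param window a [weight_window()]; defaults to a box covering the whole
#'   image.
#' @return A `structure_tensor` list with `jxx`, `jxy`, `jyy`.
#' @export
structure_tensor <- function(grad, window = NULL) {
  stopifnot(inherits(grad, "gradient_field"))
  h <- nrow(grad$fx); w <- ncol(grad$fx)
  if (is.null(window))
    window <- weight_window(c((w - 1) / 2, (h - 1) / 2), max(h, w) + 1)
  wt <- window_weights(window, h, w)
  structure(list(jxx = sum(wt * grad$fx * grad$fx),
                 jxy = sum(wt * grad$fx * grad$fy),
                 jyy = sum(wt * grad$fy * grad$fy)),
            class = "structure_tensor")
}

#' Orientation and coherency from a structure tensor
#'
#' Eigen-decomposes the tensor in closed form. The eigenvector of the larger
#' eigenvalue is the gradient-dominant axis (`gradient_axis_deg`); the
#' reported fiber axis `theta_deg` is that axis rotated by 90 degrees, which
#' for striped textures is the stripe/fiber direction. Coherency is
#' `(lmax - lmin) / (lmax + lmin)`, in `[0, 1]`. Tensors whose energy
#' (`jxx + jyy`) does not exceed `energy_threshold` are flagged invalid with
#' coherency 0 and undefined (NA) angles — no angle is fabricated for
#' isotropic or empty windows.
#'
#' @param J a [structure_tensor()].
#' @param energy_threshold minimum energy for a valid estimate (default 0:
#'   only exactly-zero tensors are invalid).
#' @return An `orientation_result` list: `theta_deg`, `gradient_axis_deg`,
#'   `coherency`, `energy`, `lambda_max`, `lambda_min`, `valid`.
#' @export
orientation_coherency <- function(J, energy_threshold = 0) {
  stopifnot(inherits(J, "structure_tensor"))
  energy <- J$jxx + J$jyy
  disc <- sqrt((J$jxx - J$jyy)^2 + 4 * J$jxy^2)
  lmax <- (energy + disc) / 2
  lmin <- (energy - disc) / 2
  if (energy <= energy_threshold || energy <= 0) {
    return(structure(list(theta_deg = NA_real_, gradient_axis_deg = NA_real_,
                          coherency = 0, energy = energy,
                          lambda_max = lmax, lambda_min = lmin,
                          valid = FALSE),
                     class = "orientation_result"))
  }
  coherency <- disc / energy
  if (disc == 0) {  # perfectly isotropic: axis undefined, still "valid" energy
    return(structure(list(theta_deg = NA_real_, gradient_axis_deg = NA_real_,
                          coherency = 0, energy = energy,
                          lambda_max = lmax, lambda_min = lmin,
                          valid = TRUE),
                     class = "orientation_result"))
  }
  grad_axis <- wrap_axial(0.5 * atan2(2 * J$jxy, J$jxx - J$jyy) * 180 / pi)
  structure(list(theta_deg = wrap_axial(grad_axis + 90),
                 gradient_axis_deg = grad_axis,
                 coherency = coherency, energy = energy,
                 lambda_max = lmax, lambda_min = lmin, valid = TRUE),
            class = "orientation_result")
}

#' @export
print.orientation_result <- function(x, ...) {
  cat(sprintf(
    "<orientation_result> fiber axis %s deg, coherency %.4f, energy %.4g%s\n",
    if (is.na(x$theta_deg)) "NA" else sprintf("%.2f", x$theta_deg),
    x$coherency, x$energy, if (x$valid) "" else " (invalid)"))
  invisible(x)
}

#' Brute-force dominant direction by angle sweep
#'
#' Independent oracle for the eigen-decomposition route: sweeps the probe
#' axis over `[0, 180)` degrees in steps of `angle_step_deg` and evaluates
#' the windowed directional-derivative energy
#' `||D_u f||_w^2 = sum_p w(p) (u . grad f(p))^2` by direct summation
#' (never forming the tensor). Returns the arg-max axis — the
#' gradient-dominant axis, perpendicular to the fiber axis on striped
#' textures — and the full energy curve.
#'
#' @param image an [image2d()] or matrix.
#' @param window a [weight_window()] or NULL for the whole image.
#' @param angle_step_deg sweep resolution in degrees (default 0.5).
#' @param sigma gradient scale passed to [compute_gradients()].
#' @return List: `gradient_axis_deg`, `theta_deg` (fiber axis = arg-max +
#'   90), `max_energy`, `angles_deg`, `energy`.
#' @export
dominant_direction_bruteforce <- function(image, window = NULL,
                                          angle_step_deg = 0.5, sigma = 1.5) {
  if (angle_step_deg <= 0) stop("angle_step_deg must be positive")
  grad <- compute_gradients(as_image2d(image), sigma)
  h <- nrow(grad$fx); w <- ncol(grad$fx)
  if (is.null(window))
    window <- weight_window(c((w - 1) / 2, (h - 1) / 2), max(h, w) + 1)
  wt <- window_weights(window, h, w)
  angles <- seq(0, 180 - angle_step_deg, by = angle_step_deg)
  energy <- vapply(angles, function(a) {
    th <- a * pi / 180
    du <- cos(th) * grad$fx + sin(th) * grad$fy
    sum(wt * du * du)
  }, numeric(1))
  best <- which.max(energy)
  list(gradient_axis_deg = wrap_axial(angles[best]),
       theta_deg = wrap_axial(angles[best] + 90),
       max_energy = energy[best],
       angles_deg = angles, energy = energy)
}

#' Tiled orientation map of an image
#'
#' Slides a square window of side `window_size_L` across the image with the
#' given stride and computes one orientation/coherency estimate per tile.
#' Gradients are computed once on the full image. Tiles whose energy is at
#' or below `energy_threshold_frac` times the maximum tile energy are
#' flagged invalid (blank regions carry no orientation information).
#'
#' @param image an [image2d()] or matrix.
#' @param window_size_L tile side in pixels; must be at least `4 * sigma`.
#' @param stride tile spacing in pixels (default `window_size_L`,
#'   non-overlapping).
#' @param sigma gradient scale in pixels.
#' @param energy_threshold_frac fraction of the maximum tile energy below
#'   which a tile is invalid (default 1e-3).
#' @param profile window profile, `"box"` or `"gaussian"`.
#' @return An `orientation_map` data.frame with columns `x0`, `y0` (tile
#'   center, 0-based), `theta_deg`, `gradient_axis_deg`, `coherency`,
#'   `energy`, `valid`; attributes record the parameters.
#' @export
orientation_map <- function(image, window_size_L = 32, stride = window_size_L,
                            sigma = 1.5, energy_threshold_frac = 1e-3,
                            profile = "box") {
  img <- as_image2d(image)
  h <- nrow(img$values); w <- ncol(img$values)
  if (window_size_L < 4 * sigma)
    stop("window_size_L must be at least 4 * sigma")
  if (stride > h || stride > w) stop("stride exceeds image size")
  grad <- compute_gradients(img, sigma)
  half <- window_size_L / 2
  cx <- seq(half, w - 1 - half, by = stride)
  cy <- seq(half, h - 1 - half, by = stride)
  if (length(cx) == 0 || length(cy) == 0)
    stop("window_size_L exceeds image size")
  rows <- vector("list", length(cx) * length(cy))
  i <- 0L
  for (y0 in cy) for (x0 in cx) {
    i <- i + 1L
    J <- structure_tensor(grad, weight_window(c(x0, y0), window_size_L, profile))
    o <- orientation_coherency(J)
    rows[[i]] <- data.frame(x0 = x0, y0 = y0, theta_deg = o$theta_deg,
                            gradient_axis_deg = o$gradient_axis_deg,
                            coherency = o$coherency, energy = o$energy,
                            valid = o$valid)
  }
  out <- do.call(rbind, rows)
  thr <- energy_threshold_frac * max(out$energy)
  low <- out$energy <= thr
  out$valid <- out$valid & !low
  out$coherency[low] <- 0
  out$theta_deg[low] <- NA_real_
  out$gradient_axis_deg[low] <- NA_real_
  structure(out, class = c("orientation_map", "data.frame"),
            window_size_L = window_size_L, stride = stride, sigma = sigma,
            energy_threshold_frac = energy_threshold_frac)
}
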