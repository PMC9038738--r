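#' 2D intensity image
#'
#' Light container for a single-channel 2D image. The pixel grid is stored as
#' a numeric matrix whose first index is the y (row) coordinate and whose
#' second index is the x (column) coordinate. The package works in a "y-up"
#' frame: row index increases with y, so angles are measured
#' counter-clockwise from the +x axis. [read_image()] performs the row flip
#' needed to map file formats (which store the top row first) into this
#' convention.
#'
#' @param values numeric matrix of finite intensities, at least 3 x 3.
#' @param pixel_size physical length per pixel (arbitrary units, default 1).
#' @return An object of class `image2d`.
#' @examples
#' img <- image2d(matrix(runif(64), 8, 8))
#' dim(img$values)
#' @export
image2d <- function(values, pixel_size = 1) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (any(!is.finite(values)))
    stop("image intensities must be finite")
  if (nrow(values) < 3L || ncol(values) < 3L)
    stop("image must be at least 3 x 3")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a positive scalar")
  structure(list(values = values, pixel_size = pixel_size),
            class = "image2d")
}

#' @export
print.image2d <- function(x, ...) {
  v <- x$values
  cat(sprintf("<image2d> %d x %d px, intensity range [%.4g, %.4g], pixel size %g\n",
              nrow(v), ncol(v), min(v), max(v), x$pixel_size))
  invisible(x)
}

#' @export
dim.image2d <- function(x) dim(x$values)

as_image2d <- function(x) {
  if (inherits(x, "image2d")) return(x)
  if (is.matrix(x)) return(image2d(x))
  stop("cannot interpret input as an image2d")
}

# Wrap angles (degrees) to the axial range [-90, 90).
wrap_axial <- function(deg) {
  out <- (deg + 90) %% 180 - 90
  # guard against -90 + eps rounding to 90 under %% for values like 90 - 1e-15
  out[out >= 90] <- out[out >= 90] - 180
  out
}

# Smallest axial (period-180) separation between two angle sets, in [0, 90].
axial_distance <- function(a, b) {
  d <- abs(wrap_axial(a - b))
  pmin(d, 180 - d)
}

# Axial mean via the angle-doubling trick; returns degrees in [-90, 90).
# R = mean resultant length of the doubled angles; axial circular variance
# is 1 - R.
axial_mean <- function(deg) {
  z <- exp(2i * deg * pi / 180)
  m <- mean(z)
  list(mean_deg = wrap_axial(Arg(m) * 180 / pi / 2),
       resultant = Mod(m),
       circ_var = 1 - Mod(m))
}
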