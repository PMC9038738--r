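#' Radial reference orientation field
#'
#' For every pixel, the axial angle of the vector from `center` to that
#' pixel — the orientation a perfectly radially organized fiber field would
#' show. The position equal to the center itself has no radial direction
#' and is `NA`.
#'
#' @param shape length-2 `(height, width)` in pixels.
#' @param center length-2 `(x0, y0)`, 0-based pixel coordinates, inside the
#'   image.
#' @return A `radial_reference` list with `center` and `angle_field` (an
#'   `height x width` matrix of axial angles in degrees, `[-90, 90)`).
#' @export
radial_reference <- function(shape, center) {
  h <- shape[1]; w <- shape[2]
  if (center[1] < 0 || center[1] > w - 1 || center[2] < 0 || center[2] > h - 1)
    stop("center must lie inside the image")
  x <- matrix(0:(w - 1), h, w, byrow = TRUE) - center[1]
  y <- matrix(0:(h - 1), h, w) - center[2]
  ang <- wrap_axial(atan2(y, x) * 180 / pi)
  ang[x == 0 & y == 0] <- NA_real_
  structure(list(center = as.numeric(center), angle_field = ang),
            class = "radial_reference")
}

# Radial axial angle at continuous (x, y) positions.
radial_angle_at <- function(x, y, center) {
  dx <- x - center[1]; dy <- y - center[2]
  out <- wrap_axial(atan2(dy, dx) * 180 / pi)
  out[dx == 0 & dy == 0] <- NA_real_
  out
}

#' Angular deviation of an orientation map from a radial reference
#'
#' Per-tile axial deviation `d = min(|theta - theta_ref|, 180 - |theta -
#' theta_ref|)`, bounded in `[0, 90]` degrees, evaluated at each tile
#' center; summarized by the energy-weighted mean and the unweighted
#' mean/median over valid tiles. A uniformly random axial field has
#' expected deviation 45 degrees; a perfectly radial one, 0.
#'
#' @param omap an [orientation_map()].
#' @param ref a [radial_reference()] (its `center` is used; tile centers
#'   need not coincide with pixel centers).
#' @return List: `deviation_deg` (per valid tile), `mean_deg` (energy
#'   weighted), `mean_unweighted_deg`, `median_deg`, `n_tiles`.
#' @export
angular_deviation <- function(omap, ref) {
  stopifnot(inherits(omap, "orientation_map"), inherits(ref, "radial_reference"))
  keep <- omap$valid & !is.na(omap$theta_deg)
  if (!any(keep)) stop("no valid tiles")
  theta <- omap$theta_deg[keep]
  theta_ref <- radial_angle_at(omap$x0[keep], omap$y0[keep], ref$center)
  ok <- !is.na(theta_ref)
  d <- axial_distance(theta[ok], theta_ref[ok])
  en <- omap$energy[keep][ok]
  list(deviation_deg = d,
       mean_deg = sum(d * en) / sum(en),
       mean_unweighted_deg = mean(d),
       median_deg = stats::median(d),
       n_tiles = sum(ok))
}

#' Compare a sample orientation map to radial and isotropic controls
#'
#' Similarity is judged on two independent axes: (a) the Kolmogorov-Smirnov
#' distance between the tile-coherency distributions of sample and control,
#' and (b) the absolute difference in mean radial deviation. The verdict is
#' `"radial-like"` only if both axes place the sample closer to the radial
#' control, `"isotropic-like"` if both place it closer to the isotropic
#' control, otherwise `"indeterminate"`. Similarities are reported as
#' `1 - (KS + |delta mean deviation| / 90) / 2`, so a self-comparison
#' scores 1.
#'
#' @param sample_map,radial_map,isotropic_map [orientation_map()]s sharing
#'   the same tiling (identical tile centers).
#' @param center `(x0, y0)` radial center; default the centroid of the tile
#'   grid.
#' @return A `comparison_report` list: `mean_radial_deviation_deg`,
#'   `control_deviation_deg` (radial/isotropic), `coherency_summary`,
#'   `ks_to_radial`, `ks_to_isotropic`, `similarity_to_radial`,
#'   `similarity_to_isotropic`, `verdict`.
#' @export
compare_to_controls <- function(sample_map, radial_map, isotropic_map,
                                center = NULL) {
  maps <- list(sample = sample_map, radial = radial_map,
               isotropic = isotropic_map)
  tiling <- lapply(maps, function(m) cbind(m$x0, m$y0))
  if (!isTRUE(all.equal(tiling$sample, tiling$radial)) ||
      !isTRUE(all.equal(tiling$sample, tiling$isotropic)))
    stop("maps must share the same tiling")
  if (is.null(center))
    center <- c(mean(sample_map$x0), mean(sample_map$y0))
  ref <- structure(list(center = as.numeric(center), angle_field = NULL),
                   class = "radial_reference")
  dev <- lapply(maps, function(m) angular_deviation(m, ref)$mean_deg)
  coh <- lapply(maps, function(m) m$coherency[m$valid])
  ks <- function(a, b) {
    if (length(a) == 0 || length(b) == 0) return(1)
    suppressWarnings(stats::ks.test(a, b)$statistic[[1]])
  }
  ks_r <- ks(coh$sample, coh$radial)
  ks_i <- ks(coh$sample, coh$isotropic)
  ddev_r <- abs(dev$sample - dev$radial)
  ddev_i <- abs(dev$sample - dev$isotropic)
  verdict <- if (ks_r <= ks_i && ddev_r <= ddev_i &&
                 (ks_r < ks_i || ddev_r < ddev_i)) "radial-like"
    else if (ks_i <= ks_r && ddev_i <= ddev_r &&
             (ks_i < ks_r || ddev_i < ddev_r)) "isotropic-like"
    else if (ks_r == ks_i && ddev_r == ddev_i) "indeterminate"
    else "indeterminate"
  structure(list(
    mean_radial_deviation_deg = dev$sample,
    control_deviation_deg = c(radial = dev$radial, isotropic = dev$isotropic),
    coherency_summary = vapply(coh, function(v)
      c(mean = mean(v), median = stats::median(v), sd = stats::sd(v)),
      numeric(3)),
    ks_to_radial = ks_r, ks_to_isotropic = ks_i,
    similarity_to_radial = 1 - (ks_r + ddev_r / 90) / 2,
    similarity_to_isotropic = 1 - (ks_i + ddev_i / 90) / 2,
    verdict = verdict), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf(
    paste0("<comparison_report> verdict: %s\n",
           "  mean radial deviation: %.1f deg (radial control %.1f, ",
           "isotropic control %.1f)\n",
           "  similarity to radial %.3f, to isotropic %.3f\n"),
    x$verdict, x$mean_radial_deviation_deg,
    x$control_deviation_deg[["radial"]],
    x$control_deviation_deg[["isotropic"]],
    x$similarity_to_radial, x$similarity_to_isotropic))
  invisible(x)
}
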