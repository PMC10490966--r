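#' Normalized difference vegetation index
#'
#' Computes NDVI = (NIR - R) / (NIR + R) from the scene's red and
#' near-infrared bands. Pixels where NIR + R = 0 (and nodata pixels) are
#' undefined (NA). Round-off excursions beyond [-1, 1] smaller than 1e-12
#' are clamped; anything larger is a genuine error and is left to surface.
#'
#' @param scene a [spectral_scene()] with `red` and `nir` band roles set.
#' @return An object of class `ndvi_grid`: list with `values` (matrix in
#'   [-1, 1] or NA), `pixel_size_m`, `epoch_label` and the five
#'   vegetation-density `bins`.
#' @examples
#' b <- array(c(0.1, 0.3), c(1, 1, 2))
#' g <- compute_ndvi(spectral_scene(b, c(red = 1, nir = 2)))
#' g$values  # (0.3 - 0.1)/(0.3 + 0.1) = 0.5
#' @export
compute_ndvi <- function(scene) {
  stopifnot(inherits(scene, "spectral_scene"))
  d <- dim(scene$bands)
  r <- matrix(scene$bands[, , scene$band_roles[["red"]]], d[1], d[2])
  n <- matrix(scene$bands[, , scene$band_roles[["nir"]]], d[1], d[2])
  v <- (n - r) / (n + r)
  v[n + r == 0] <- NA_real_
  v[scene$nodata_mask] <- NA_real_
  over <- !is.na(v) & abs(v) > 1
  v[over & abs(v) <= 1 + 1e-12] <- sign(v[over & abs(v) <= 1 + 1e-12])
  structure(list(values = v, pixel_size_m = scene$pixel_size_m,
                 epoch_label = scene$epoch_label, bins = ndvi_bins()),
            class = "ndvi_grid")
}

#' @export
print.ndvi_grid <- function(x, ...) {
  cat("NDVI grid ", nrow(x$values), " x ", ncol(x$values),
      "; defined range [", signif(min(x$values, na.rm = TRUE), 3), ", ",
      signif(max(x$values, na.rm = TRUE), 3), "]\n", sep = "")
  invisible(x)
}

# The five vegetation-density intervals. Printed interval lists for these
# classes share endpoints (0.15 appears as both an upper and a lower bound),
# resolved here as half-open lower-inclusive intervals with the top bin
# closed at 1, so the bins partition [-1, 1] with no gaps or overlaps.
ndvi_bins <- function() {
  data.frame(class_code = 1:5,
             class_name = ndvi_legend()$class_name,
             lower = c(-1, -0.03, 0.15, 0.25, 0.35),
             upper = c(-0.03, 0.15, 0.25, 0.35, 1))
}

#' Bin an NDVI grid into vegetation-density classes
#'
#' Maps NDVI values to the five density classes: non-vegetation/water
#' [-1, -0.03), very low [-0.03, 0.15), low [0.15, 0.25), moderate
#' ("grassland") [0.25, 0.35), and dense [0.35, 1]. Undefined pixels
#' propagate to nodata.
#'
#' @param grid an `ndvi_grid` from [compute_ndvi()].
#' @return A [class_map()] with the five-class [ndvi_legend()].
#' @export
bin_ndvi <- function(grid) {
  stopifnot(inherits(grid, "ndvi_grid"))
  v <- grid$values
  cls <- matrix(0L, nrow(v), ncol(v))
  ok <- !is.na(v)
  cls[ok] <- findInterval(v[ok], c(-0.03, 0.15, 0.25, 0.35)) + 1L
  class_map(cls, ndvi_legend(), grid$pixel_size_m, grid$epoch_label)
}
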