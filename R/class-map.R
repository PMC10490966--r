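#' Categorical land-cover map
#'
#' The unit all change-detection and valuation operations consume: an integer
#' grid of class codes (0 = nodata) together with its legend, pixel size and
#' epoch label.
#'
#' @param classes integer matrix of class codes; 0 marks nodata.
#' @param legend a [lulc_legend()] whose codes cover every nonzero cell.
#' @param pixel_size_m pixel edge length in metres (> 0).
#' @param epoch_label year or other label for the epoch.
#' @return An object of class `class_map`.
#' @examples
#' m <- class_map(matrix(c(1, 1, 2, 0), 2), lulc_legend(), 30, 1984)
#' summary(m)
#' @export
class_map <- function(classes, legend, pixel_size_m = 30,
                      epoch_label = NA) {
  classes <- as.matrix(classes)
  storage.mode(classes) <- "integer"
  codes <- unique(classes[classes != 0L])
  if (!all(codes %in% legend$class_code))
    stop("map contains class codes absent from the legend: ",
         paste(setdiff(codes, legend$class_code), collapse = ", "))
  if (pixel_size_m <= 0) stop("pixel_size_m must be positive")
  structure(list(classes = classes, legend = legend,
                 pixel_size_m = pixel_size_m, epoch_label = epoch_label),
            class = "class_map")
}

#' @export
print.class_map <- function(x, ...) {
  cat("Land-cover map", if (!is.na(x$epoch_label))
    paste0("(epoch ", x$epoch_label, ")"), "\n")
  cat("  ", nrow(x$classes), " x ", ncol(x$classes), " pixels at ",
      x$pixel_size_m, " m; ", sum(x$classes == 0L), " nodata\n", sep = "")
  invisible(x)
}

#' @export
summary.class_map <- function(object, ...) {
  tab <- class_areas(object)
  cat("Land-cover map", if (!is.na(object$epoch_label))
    paste0("(epoch ", object$epoch_label, ")"), "\n")
  print(tab, row.names = FALSE)
  invisible(tab)
}

#' Multi-band reflectance scene
#'
#' Holds one epoch's reflectance bands as a rows x cols x B array, the band
#' roles (which band is red, which is near-infrared), the nodata mask, the
#' pixel size and the epoch label.
#'
#' @param bands numeric rows x cols x B array of reflectances (finite and
#'   nonnegative outside the nodata mask).
#' @param band_roles named integer vector with at least `red` and `nir`,
#'   giving distinct in-range band indices.
#' @param nodata_mask logical rows x cols matrix; TRUE marks nodata.
#' @param pixel_size_m pixel edge length in metres.
#' @param epoch_label year or other label.
#' @return An object of class `spectral_scene`.
#' @export
spectral_scene <- function(bands, band_roles, nodata_mask = NULL,
                           pixel_size_m = 30, epoch_label = NA) {
  bands <- as.array(bands)
  if (length(dim(bands)) != 3) stop("bands must be a rows x cols x B array")
  B <- dim(bands)[3]
  roles <- vapply(band_roles, as.integer, integer(1))
  if (!all(c("red", "nir") %in% names(roles)))
    stop("band_roles must name 'red' and 'nir'")
  if (roles["red"] == roles["nir"] || any(roles < 1L) || any(roles > B))
    stop("red and nir must be distinct in-range band indices")
  if (is.null(nodata_mask))
    nodata_mask <- matrix(FALSE, dim(bands)[1], dim(bands)[2])
  valid <- !as.vector(nodata_mask)
  flat <- matrix(bands, ncol = B)
  if (any(!is.finite(flat[valid, ])) || any(flat[valid, ] < 0))
    stop("reflectances must be finite and nonnegative outside nodata")
  structure(list(bands = bands, band_roles = roles,
                 nodata_mask = nodata_mask, pixel_size_m = pixel_size_m,
                 epoch_label = epoch_label),
            class = "spectral_scene")
}

#' @export
print.spectral_scene <- function(x, ...) {
  d <- dim(x$bands)
  cat("Spectral scene", if (!is.na(x$epoch_label))
    paste0("(epoch ", x$epoch_label, ")"), "\n")
  cat("  ", d[1], " x ", d[2], " pixels, ", d[3], " bands at ",
      x$pixel_size_m, " m; ", sum(x$nodata_mask), " nodata\n", sep = "")
  invisible(x)
}

#' Labelled reference points
#'
#' Ground-truth sample: pixel coordinates with their reference class code,
#' used to train signatures and to assess accuracy.
#'
#' @param points data frame with columns `row`, `col`, `class_code`.
#' @param epoch_label year or other label.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(points, epoch_label = NA) {
  stopifnot(all(c("row", "col", "class_code") %in% names(points)))
  structure(list(points = as.data.frame(points), epoch_label = epoch_label),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth: ", nrow(x$points), " points",
      if (!is.na(x$epoch_label)) paste0(" (epoch ", x$epoch_label, ")"),
      "\n", sep = "")
  print(table(class_code = x$points$class_code))
  invisible(x)
}
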