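#' Specification of a synthetic multi-epoch scene
#'
#' Bundles everything needed to simulate a multi-temporal land-cover scene:
#' grid size, pixel size, epoch labels, the initial class proportions, the
#' per-step Markov transition matrix, the per-class spectral band model
#' (multivariate-Gaussian mean and covariance per class), a nodata fraction
#' and a master seed. Pixels evolve independently between epochs; there is no
#' spatial autocorrelation, matching the per-pixel bookkeeping that a
#' cross-tabulated transition matrix assumes.
#'
#' The default band model has four bands (blue, green, red, NIR) whose class
#' means are chosen so that the NDVI of each class mean falls inside the NDVI
#' interval conventionally associated with that cover type (water below
#' -0.03; built-up and barren in (-0.03, 0.15); cultivated in (0.15, 0.25);
#' grassland in (0.25, 0.35); forest above 0.35), making NDVI binning and
#' maximum-likelihood classification mutually consistent on simulated data.
#'
#' @param grid_rows,grid_cols pixel counts of the simulated grid.
#' @param pixel_size_m pixel edge length in metres (default 30, Landsat-like).
#' @param epochs ordered vector of epoch (year) labels.
#' @param legend a [lulc_legend()].
#' @param initial_class_proportions numeric vector over legend classes,
#'   summing to 1 within 1e-9.
#' @param transition_probabilities row-stochastic K x K matrix applied at
#'   each epoch step (rows sum to 1 within 1e-9).
#' @param band_means K x B matrix of per-class mean reflectances.
#' @param band_covs list of K symmetric positive semi-definite B x B
#'   covariance matrices (a single matrix is recycled to all classes).
#' @param band_roles named integer vector mapping at least `red` and `nir`
#'   to band indices.
#' @param nodata_fraction fraction of pixels masked as nodata, in [0, 1).
#'   The mask is drawn once and held fixed across epochs so cross-tabulation
#'   is defined on a constant support.
#' @param seed master integer seed; all sub-streams derive from it.
#' @return An object of class `scene_spec`.
#' @examples
#' sp <- scene_spec(grid_rows = 50, grid_cols = 50, seed = 1)
#' sp$epochs
#' @export
scene_spec <- function(grid_rows = 200, grid_cols = 200, pixel_size_m = 30,
                       epochs = c(1984, 1991, 2001, 2021),
                       legend = lulc_legend(),
                       initial_class_proportions =
                         c(0.108, 0.330, 0.265, 0.120, 0.108, 0.069),
                       transition_probabilities = default_transitions(),
                       band_means = default_band_means(),
                       band_covs = diag(0.005^2, 4),
                       band_roles = c(blue = 1L, green = 2L,
                                      red = 3L, nir = 4L),
                       nodata_fraction = 0.02,
                       seed = 1L) {
  k <- nrow(legend)
  if (length(epochs) < 1) stop("at least one epoch label required")
  if (length(initial_class_proportions) != k)
    stop("initial_class_proportions must have one entry per legend class")
  if (abs(sum(initial_class_proportions) - 1) > 1e-9)
    stop("initial class proportions must sum to 1")
  P <- as.matrix(transition_probabilities)
  if (!all(dim(P) == k)) stop("transition matrix must be K x K")
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-9))
    stop("each transition-probability row must be nonnegative and sum to 1")
  M <- as.matrix(band_means)
  if (nrow(M) != k) stop("band_means must have one row per class")
  B <- ncol(M)
  if (is.matrix(band_covs)) band_covs <- rep(list(band_covs), k)
  if (length(band_covs) != k)
    stop("band_covs must be one covariance per class (or a single matrix)")
  for (S in band_covs) {
    S <- as.matrix(S)
    if (!all(dim(S) == B)) stop("each band covariance must be B x B")
    if (max(abs(S - t(S))) > 1e-12) stop("band covariances must be symmetric")
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
      stop("band covariances must be positive semi-definite")
  }
  roles <- vapply(band_roles, as.integer, integer(1))
  if (!all(c("red", "nir") %in% names(roles)))
    stop("band_roles must name at least 'red' and 'nir'")
  if (roles["red"] == roles["nir"] || any(roles < 1L) || any(roles > B))
    stop("red and nir roles must be distinct in-range band indices")
  if (nodata_fraction < 0 || nodata_fraction >= 1)
    stop("nodata_fraction must lie in [0, 1)")
  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 pixel_size_m = pixel_size_m,
                 epochs = epochs,
                 legend = legend,
                 initial_class_proportions = initial_class_proportions,
                 transition_probabilities = P,
                 band_means = M,
                 band_covs = lapply(band_covs, as.matrix),
                 band_roles = roles,
                 nodata_fraction = nodata_fraction,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat("Synthetic scene specification\n")
  cat("  grid: ", x$grid_rows, " x ", x$grid_cols, " pixels at ",
      x$pixel_size_m, " m\n", sep = "")
  cat("  epochs:", paste(x$epochs, collapse = ", "), "\n")
  cat("  classes:", paste(x$legend$class_name, collapse = ", "), "\n")
  cat("  bands: ", ncol(x$band_means), " (roles: ",
      paste(names(x$band_roles), x$band_roles, sep = "=", collapse = ", "),
      ")\n", sep = "")
  cat("  nodata fraction:", x$nodata_fraction, " seed:", x$seed, "\n")
  invisible(x)
}

#' Default synthetic-scene parameters
#'
#' `default_transitions()` returns the per-step class-transition matrix used
#' by [scene_spec()]: persistence on the diagonal with conversion pressure
#' toward cultivated and built-up land, emulating the agricultural-expansion
#' / natural-cover-decline regime of East African highland landscapes.
#' `default_band_means()` returns the class mean reflectances over
#' (blue, green, red, NIR); each row's NDVI sits inside the
#' vegetation-density interval of its cover type.
#'
#' @return A 6 x 6 row-stochastic matrix, or a 6 x 4 matrix of mean
#'   reflectances, with class names on the rows.
#' @export
default_transitions <- function() {
  P <- matrix(c(
    0.85, 0.08, 0.05, 0.02, 0.00, 0.00,
    0.00, 0.92, 0.00, 0.06, 0.02, 0.00,
    0.00, 0.12, 0.82, 0.04, 0.02, 0.00,
    0.00, 0.00, 0.00, 0.97, 0.03, 0.00,
    0.00, 0.06, 0.00, 0.04, 0.90, 0.00,
    0.00, 0.13, 0.06, 0.03, 0.03, 0.75), 6, 6, byrow = TRUE)
  dimnames(P) <- list(lulc_legend()$class_name, lulc_legend()$class_name)
  P
}

#' @rdname default_transitions
#' @export
default_band_means <- function() {
  m <- matrix(c(
    0.03, 0.05, 0.04, 0.120,   # forestland, NDVI 0.50
    0.06, 0.09, 0.12, 0.180,   # cultivated, NDVI 0.20
    0.05, 0.08, 0.09, 0.160,   # grassland,  NDVI 0.28
    0.20, 0.21, 0.22, 0.240,   # built-up,   NDVI 0.043
    0.28, 0.29, 0.30, 0.340,   # barren,     NDVI 0.063
    0.08, 0.07, 0.06, 0.020),  # water,      NDVI -0.50
    6, 4, byrow = TRUE)
  dimnames(m) <- list(lulc_legend()$class_name,
                      c("blue", "green", "red", "nir"))
  m
}
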