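#' Simulate a multi-epoch land-cover class series
#'
#' Draws the first epoch i.i.d. from the spec's initial class proportions and
#' evolves each pixel independently through the spec's row-stochastic
#' transition matrix at every epoch step. The nodata mask is drawn once (at
#' epoch 1) and held fixed across epochs, so cross-tabulations between epochs
#' are defined on a constant support. Fully reproducible from the spec's
#' master seed; per-epoch sub-streams are derived deterministically, so adding
#' later epochs never changes earlier maps.
#'
#' @param spec a [scene_spec()].
#' @return A list of [class_map()] objects, one per epoch, in epoch order.
#' @examples
#' maps <- generate_class_series(scene_spec(grid_rows = 40, grid_cols = 40,
#'                                          seed = 7))
#' length(maps)
#' @export
generate_class_series <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  n <- spec$grid_rows * spec$grid_cols
  codes <- spec$legend$class_code
  k <- length(codes)
  mask <- with_substream(spec$seed, "nodata", {
    matrix(stats::runif(n) < spec$nodata_fraction,
           spec$grid_rows, spec$grid_cols)
  })
  cur <- with_substream(spec$seed, "epoch_1", {
    sample(codes, n, replace = TRUE, prob = spec$initial_class_proportions)
  })
  maps <- vector("list", length(spec$epochs))
  for (e in seq_along(spec$epochs)) {
    if (e > 1) {
      cur <- with_substream(spec$seed, paste0("epoch_", e), {
        nxt <- cur
        for (i in seq_len(k)) {
          idx <- which(cur == codes[i])
          if (length(idx))
            nxt[idx] <- sample(codes, length(idx), replace = TRUE,
                               prob = spec$transition_probabilities[i, ])
        }
        nxt
      })
    }
    grid <- matrix(cur, spec$grid_rows, spec$grid_cols)
    grid[mask] <- 0L
    maps[[e]] <- class_map(grid, spec$legend, spec$pixel_size_m,
                           spec$epochs[e])
  }
  maps
}

#' Render per-class Gaussian reflectances for a class map
#'
#' Each non-nodata pixel's band vector is drawn from the multivariate
#' Gaussian of its class in the spec's band model; a zero covariance yields
#' the class mean exactly. Negative draws are floored at zero (reflectance
#' is physically nonnegative; with the default means and standard deviations
#' this affects a negligible fraction of pixels). Nodata pixels carry NA.
#'
#' @param map a [class_map()].
#' @param spec a [scene_spec()] providing band means/covariances per class;
#'   every class present in the map must have a band model.
#' @return A [spectral_scene()].
#' @export
render_spectra <- function(map, spec) {
  stopifnot(inherits(map, "class_map"), inherits(spec, "scene_spec"))
  codes <- spec$legend$class_code
  present <- unique(map$classes[map$classes != 0L])
  if (!all(present %in% codes))
    stop("no band model for class(es): ",
         paste(setdiff(present, codes), collapse = ", "))
  B <- ncol(spec$band_means)
  n <- length(map$classes)
  flat <- matrix(NA_real_, n, B)
  with_substream(spec$seed, paste0("spectra_", map$epoch_label), {
    for (i in seq_along(codes)) {
      idx <- which(as.vector(map$classes) == codes[i])
      if (!length(idx)) next
      S <- spec$band_covs[[i]]
      if (all(S == 0)) {
        flat[idx, ] <- matrix(spec$band_means[i, ], length(idx), B,
                              byrow = TRUE)
      } else {
        flat[idx, ] <- MASS::mvrnorm(length(idx), spec$band_means[i, ], S)
      }
    }
  })
  flat[flat < 0] <- 0
  bands <- array(flat, c(nrow(map$classes), ncol(map$classes), B))
  spectral_scene(bands, spec$band_roles,
                 nodata_mask = map$classes == 0L,
                 pixel_size_m = map$pixel_size_m,
                 epoch_label = map$epoch_label)
}

#' Sample labelled ground-truth points from a class map
#'
#' Samples a fixed number of pixels per class without replacement, off the
#' nodata mask, labelling each point with the map's class at that pixel —
#' the synthetic analogue of collecting GPS-referenced training/validation
#' points per cover type.
#'
#' @param map a [class_map()].
#' @param n_per_class points to draw per class (every class present in the
#'   map must have at least this many pixels).
#' @param seed integer seed.
#' @param classes class codes to sample (default: all classes present).
#' @return A [ground_truth()] with `n_per_class` points per class.
#' @export
sample_ground_truth <- function(map, n_per_class = 50, seed = 1,
                                classes = NULL) {
  stopifnot(inherits(map, "class_map"))
  if (is.null(classes))
    classes <- sort(unique(map$classes[map$classes != 0L]))
  pts <- with_substream(seed, "ground_truth", {
    do.call(rbind, lapply(classes, function(cc) {
      idx <- which(map$classes == cc)
      if (length(idx) < n_per_class)
        stop("class ", cc, " has only ", length(idx),
             " pixels; cannot sample ", n_per_class)
      pick <- sample(idx, n_per_class)
      data.frame(row = ((pick - 1L) %% nrow(map$classes)) + 1L,
                 col = ((pick - 1L) %/% nrow(map$classes)) + 1L,
                 class_code = cc)
    }))
  })
  ground_truth(pts, map$epoch_label)
}
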