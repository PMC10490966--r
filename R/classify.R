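#' Fit Gaussian class signatures from training points
#'
#' Estimates, for every class in the training set, the empirical mean vector
#' and empirical covariance (denominator n - 1) of the pixel band vectors at
#' the training locations — the "spectral signature" of the class. When a
#' covariance is numerically singular (smallest eigenvalue below 1e-10 times
#' the largest), a ridge epsilon * I is added with
#' epsilon = 1e-6 * mean(diag(cov)), floored at 1e-6 when the diagonal is
#' entirely zero, so that the maximum-likelihood discriminant is always
#' defined.
#'
#' @param scene a [spectral_scene()].
#' @param truth a [ground_truth()] with at least 2 points per class, all
#'   off the nodata mask.
#' @return An object of class `mlc` (a fitted maximum-likelihood classifier):
#'   a list of per-class signatures, each with `class_code`, `mean`,
#'   `cov` (regularized), `n_samples` and `regularized` flag. Use
#'   [predict.mlc()] / [classify_max_likelihood()] to classify scenes.
#' @examples
#' sp <- scene_spec(grid_rows = 30, grid_cols = 30, seed = 2)
#' maps <- generate_class_series(sp)
#' scn <- render_spectra(maps[[1]], sp)
#' gt <- sample_ground_truth(maps[[1]], n_per_class = 10, seed = 3)
#' fit <- fit_signatures(scn, gt)
#' fit
#' @export
fit_signatures <- function(scene, truth) {
  stopifnot(inherits(scene, "spectral_scene"), inherits(truth, "ground_truth"))
  pts <- truth$points
  d <- dim(scene$bands)
  if (any(pts$row < 1 | pts$row > d[1] | pts$col < 1 | pts$col > d[2]))
    stop("training points fall outside the grid")
  if (any(scene$nodata_mask[cbind(pts$row, pts$col)]))
    stop("training points fall on nodata pixels")
  B <- d[3]
  flat <- matrix(scene$bands, ncol = B)
  idx <- (pts$col - 1L) * d[1] + pts$row
  sigs <- lapply(sort(unique(pts$class_code)), function(cc) {
    x <- flat[idx[pts$class_code == cc], , drop = FALSE]
    if (nrow(x) < 2)
      stop("class ", cc, " has fewer than 2 training points")
    S <- stats::cov(x)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    reg <- FALSE
    if (min(ev) < 1e-10 * max(ev, 0) || max(ev) == 0) {
      eps <- 1e-6 * mean(diag(S))
      if (eps == 0) eps <- 1e-6
      S <- S + diag(eps, B)
      reg <- TRUE
    }
    list(class_code = cc, mean = colMeans(x), cov = S,
         n_samples = nrow(x), regularized = reg)
  })
  structure(list(signatures = sigs, n_bands = B), class = "mlc")
}

#' @export
print.mlc <- function(x, ...) {
  cat("Gaussian maximum-likelihood classifier:",
      length(x$signatures), "class signatures over",
      x$n_bands, "bands\n")
  for (s in x$signatures)
    cat(sprintf("  class %d: n = %d, mean = [%s]%s\n", s$class_code,
                s$n_samples, paste(signif(s$mean, 3), collapse = ", "),
                if (s$regularized) " (covariance ridge-regularized)" else ""))
  invisible(x)
}

#' Maximum-likelihood classification of a scene
#'
#' Assigns each non-nodata pixel the class maximising the Gaussian
#' log-density
#' \deqn{-\tfrac12\,[\,\ln\det\Sigma_k + (x-\mu_k)^\top\Sigma_k^{-1}(x-\mu_k)\,]}
#' with equal class priors (plain maximum likelihood, no prior weighting).
#' Ties are broken toward the lowest class code; nodata pixels stay 0.
#'
#' @param scene a [spectral_scene()] with the same band count as the fit.
#' @param fit an `mlc` object from [fit_signatures()], or a list of
#'   signature lists with `class_code`, `mean`, `cov`.
#' @param legend legend for the output map; defaults to a bare legend built
#'   from the signature codes.
#' @return A [class_map()].
#' @export
classify_max_likelihood <- function(scene, fit, legend = NULL) {
  stopifnot(inherits(scene, "spectral_scene"))
  sigs <- if (inherits(fit, "mlc")) fit$signatures else fit
  if (!length(sigs)) stop("at least one class signature required")
  B <- dim(scene$bands)[3]
  if (any(vapply(sigs, function(s) length(s$mean), 0L) != B))
    stop("band-count mismatch between scene and signatures")
  codes <- vapply(sigs, function(s) as.integer(s$class_code), 0L)
  ord <- order(codes)          # low codes first so ties resolve downward
  sigs <- sigs[ord]; codes <- codes[ord]
  flat <- matrix(scene$bands, ncol = B)
  valid <- which(!as.vector(scene$nodata_mask))
  x <- flat[valid, , drop = FALSE]
  scores <- matrix(-Inf, length(valid), length(sigs))
  for (j in seq_along(sigs)) {
    R <- chol(sigs[[j]]$cov)
    centred <- sweep(x, 2, sigs[[j]]$mean)
    z <- backsolve(R, t(centred), transpose = TRUE)
    scores[, j] <- -sum(log(diag(R))) - 0.5 * colSums(z^2)
  }
  pick <- max.col(scores, ties.method = "first")
  out <- matrix(0L, nrow(scene$nodata_mask), ncol(scene$nodata_mask))
  out[valid] <- codes[pick]
  if (is.null(legend))
    legend <- lulc_legend(codes = codes,
                          names = paste0("class_", codes),
                          descriptions = "")
  class_map(out, legend, scene$pixel_size_m, scene$epoch_label)
}

#' @rdname classify_max_likelihood
#' @param object,newdata standard predict-method arguments (`newdata` is the
#'   scene to classify).
#' @param ... unused.
#' @export
predict.mlc <- function(object, newdata, legend = NULL, ...) {
  classify_max_likelihood(newdata, object, legend = legend)
}
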