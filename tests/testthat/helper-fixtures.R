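# Shared fixtures built in code.

two_class_legend <- function() {
  lulc_legend(1:2, c("a", "b"), c("", ""))
}

# A tiny spec with well-separated classes for fast deterministic runs.
small_spec <- function(rows = 40, cols = 40, seed = 11, ...) {
  scene_spec(grid_rows = rows, grid_cols = cols, seed = seed, ...)
}

# Brute-force Gaussian log-density argmax, written independently of the
# vectorized classifier: per pixel, loop over classes using solve() and
# det() directly.
brute_force_classify <- function(scene, sigs) {
  d <- dim(scene$bands)
  flat <- matrix(scene$bands, ncol = d[3])
  out <- matrix(0L, d[1], d[2])
  codes <- vapply(sigs, function(s) s$class_code, 0L)
  inv <- lapply(sigs, function(s) solve(s$cov))
  ld <- vapply(sigs, function(s) determinant(s$cov)$modulus[1], 0)
  for (p in which(!as.vector(scene$nodata_mask))) {
    best <- -Inf; pick <- NA_integer_
    for (j in seq_along(sigs)) {
      r <- flat[p, ] - sigs[[j]]$mean
      s <- -0.5 * (ld[j] + drop(r %*% inv[[j]] %*% r))
      if (s > best + 1e-12) { best <- s; pick <- codes[j] }
      else if (abs(s - best) <= 1e-12) pick <- min(pick, codes[j])
    }
    out[p] <- pick
  }
  out
}

# Published per-class areas (ha) for the four epochs of the study, used as
# direct inputs to the valuation module.
study_areas <- function() {
  list(
    "1984" = area_table(c(forestland = 10706.4, grassland = 26319.6,
                          water = 6806.7), epoch_label = 1984),
    "1991" = area_table(c(forestland = 9631.84, grassland = 24451.17),
                        epoch_label = 1991),
    "2001" = area_table(c(forestland = 5583.04, grassland = 18985.62),
                        epoch_label = 2001),
    "2021" = area_table(c(forestland = 5005.31, grassland = 15051.85,
                          water = 914.89), epoch_label = 2021))
}
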