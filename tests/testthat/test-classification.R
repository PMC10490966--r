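test_that("signature fitting recovers empirical and true moments", {
  # n - 1 denominator on a hand-checkable (full-rank) sample
  b <- array(c(1, 1, 3, 2, 5, 4), c(3, 1, 2))
  scn <- spectral_scene(b, c(red = 1, nir = 2))
  gt <- ground_truth(data.frame(row = 1:3, col = 1, class_code = 1L))
  fit <- fit_signatures(scn, gt)
  s <- fit$signatures[[1]]
  expect_equal(s$mean, colMeans(matrix(c(1, 1, 3, 2, 5, 4), 3)),
               ignore_attr = TRUE)
  expect_false(s$regularized)
  expect_equal(s$cov, cov(matrix(c(1, 1, 3, 2, 5, 4), 3)),
               ignore_attr = TRUE)

  # two identical pixels: singular covariance regularized to epsilon * I
  b2 <- array(rep(c(0.2, 0.4), each = 2), c(2, 1, 2))
  scn2 <- spectral_scene(b2, c(red = 1, nir = 2))
  gt2 <- ground_truth(data.frame(row = 1:2, col = 1, class_code = 1L))
  s2 <- fit_signatures(scn2, gt2)$signatures[[1]]
  expect_true(s2$regularized)
  expect_equal(s2$cov, diag(1e-6, 2), ignore_attr = TRUE)
  expect_equal(s2$mean, c(0.2, 0.4), ignore_attr = TRUE)

  # zero-covariance render: fitted means equal the spec means exactly
  sp0 <- small_spec(rows = 12, cols = 12, band_covs = diag(0, 4),
                    nodata_fraction = 0)
  m0 <- generate_class_series(sp0)[[1]]
  f0 <- fit_signatures(render_spectra(m0, sp0),
                       sample_ground_truth(m0, 5, seed = 2))
  for (s in f0$signatures)
    expect_equal(s$mean, sp0$band_means[s$class_code, ],
                 ignore_attr = TRUE)

  # large-sample recovery: fitted mean within 3 SE of the generating truth
  sp <- small_spec(rows = 80, cols = 80, nodata_fraction = 0, seed = 31)
  m <- generate_class_series(sp)[[1]]
  fit <- fit_signatures(render_spectra(m, sp),
                        sample_ground_truth(m, 500, seed = 3,
                                            classes = 2L))
  s <- fit$signatures[[1]]
  expect_true(all(abs(s$mean - sp$band_means[2, ]) <
                    3 * 0.005 / sqrt(500)))

  expect_error(
    fit_signatures(scn, ground_truth(data.frame(row = 1, col = 1,
                                                class_code = 1L))),
    "fewer than 2")
})

test_that("maximum-likelihood classification matches a brute-force argmax", {
  sp <- scene_spec(grid_rows = 100, grid_cols = 100, seed = 17,
                   band_covs = diag(0.01^2, 4), nodata_fraction = 0.05)
  m <- generate_class_series(sp)[[1]]
  scn <- render_spectra(m, sp)
  fit <- fit_signatures(scn, sample_ground_truth(m, 40, seed = 9))
  cm <- classify_max_likelihood(scn, fit, legend = sp$legend)
  expect_identical(cm$classes, brute_force_classify(scn, fit$signatures))
})

test_that("classifier edge cases: single signature, ties, band mismatch", {
  b <- array(runif(8), c(2, 2, 2))
  scn <- spectral_scene(b, c(red = 1, nir = 2))
  one <- list(list(class_code = 3L, mean = c(0.5, 0.5), cov = diag(2)))
  cm <- classify_max_likelihood(scn, one)
  expect_true(all(cm$classes == 3L))

  # pixel exactly equidistant between class codes 2 and 5 -> lower code
  btie <- array(c(0.5, 0.5), c(1, 1, 2))
  stie <- spectral_scene(btie, c(red = 1, nir = 2))
  sigs <- list(list(class_code = 5L, mean = c(0.4, 0.5), cov = diag(2)),
               list(class_code = 2L, mean = c(0.6, 0.5), cov = diag(2)))
  expect_equal(classify_max_likelihood(stie, sigs)$classes[1, 1], 2L)

  bad <- list(list(class_code = 1L, mean = c(0.5, 0.5, 0.5), cov = diag(3)))
  expect_error(classify_max_likelihood(scn, bad), "mismatch")
})

test_that("shared covariance reduces ML to nearest-mean in Mahalanobis", {
  set.seed(42)
  S <- crossprod(matrix(rnorm(16), 4)) + diag(0.5, 4)
  mu <- matrix(rnorm(24), 6, 4)
  sigs <- lapply(1:6, function(k)
    list(class_code = k, mean = mu[k, ], cov = S))
  x <- array(rnorm(40 * 40 * 4), c(40, 40, 4))
  scn <- spectral_scene(abs(x), c(red = 1, nir = 2))
  cm <- classify_max_likelihood(scn, sigs)
  flat <- matrix(scn$bands, ncol = 4)
  Sinv <- solve(S)
  d2 <- sapply(1:6, function(k) {
    r <- sweep(flat, 2, mu[k, ])
    rowSums((r %*% Sinv) * r)
  })
  nearest <- max.col(-d2, ties.method = "first")
  expect_equal(as.vector(cm$classes), nearest)
})

test_that("well-separated classes are recovered almost perfectly", {
  sp <- small_spec(rows = 100, cols = 100, seed = 23)
  m <- generate_class_series(sp)[[1]]
  scn <- render_spectra(m, sp)
  fit <- fit_signatures(scn, sample_ground_truth(m, 50, seed = 4))
  cm <- classify_max_likelihood(scn, fit, legend = sp$legend)
  ok <- m$classes != 0L
  expect_gte(mean(cm$classes[ok] == m$classes[ok]), 0.99)
})
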