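test_that("confusion matrix is built correctly from map and points", {
  l <- two_class_legend()
  m <- class_map(matrix(c(1, 1, 2, 2), 2), l)
  gt <- ground_truth(data.frame(row = c(1, 2, 1, 2),
                                col = c(1, 1, 2, 2),
                                class_code = c(1, 1, 2, 1)))
  cm <- build_confusion(m, gt)
  expect_equal(cm$counts, matrix(c(2L, 0L, 1L, 1L), 2,
                                 dimnames = list(reference = 1:2,
                                                 mapped = 1:2)))
  # identical labels -> diagonal
  gtd <- ground_truth(data.frame(row = c(1, 2, 1, 2), col = c(1, 1, 2, 2),
                                 class_code = c(1, 1, 2, 2)))
  cmd <- build_confusion(m, gtd)
  expect_true(all(cmd$counts[upper.tri(cmd$counts) |
                               lower.tri(cmd$counts)] == 0))
  # single off-diagonal observation
  g1 <- ground_truth(data.frame(row = 1, col = 1, class_code = 3L))
  c1 <- build_confusion(class_map(matrix(1L, 1, 1), lulc_legend()), g1)
  expect_equal(dim(c1$counts), c(2L, 2L))  # classes absent both sides drop
  expect_equal(c1$counts[rownames(c1$counts) == "3",
                         colnames(c1$counts) == "1"][[1]], 1L)
  expect_error(build_confusion(m, ground_truth(gt$points[0, ])), "empty")
  nod <- class_map(matrix(0L, 1, 1), l)
  expect_error(build_confusion(nod, g1), "nodata")
})

test_that("confusion cell totals match an independent linear-scan tally", {
  set.seed(77)
  l <- lulc_legend()
  m <- class_map(matrix(sample(1:6, 400, TRUE), 20), l)
  pts <- data.frame(row = sample(20, 100, TRUE),
                    col = sample(20, 100, TRUE),
                    class_code = sample(1:6, 100, TRUE))
  cm <- build_confusion(m, ground_truth(pts))
  tally <- matrix(0L, 6, 6)
  for (i in seq_len(nrow(pts)))          # brute-force recount
    tally[pts$class_code[i], m$classes[pts$row[i], pts$col[i]]] <-
      tally[pts$class_code[i], m$classes[pts$row[i], pts$col[i]]] + 1L
  expect_equal(unname(unclass(cm$counts)), tally)
  expect_equal(cm$M, 100L)
  expect_equal(unname(cm$n_i), rowSums(tally), ignore_attr = TRUE)
  expect_equal(unname(cm$n_j), colSums(tally), ignore_attr = TRUE)
})

test_that("accuracy statistics reproduce hand-computed values", {
  cm <- confusion_matrix(matrix(c(40, 5, 10, 45), 2), 1:2)
  expect_equal(overall_accuracy(cm), 0.85)
  pu <- producers_users_accuracy(cm)
  expect_equal(pu$producers, c(0.8, 0.9))
  expect_equal(pu$users, c(40 / 45, 45 / 55))
  expect_equal(kappa_coefficient(cm)$kappa, 0.70)
  expect_equal(kappa_coefficient(cm)$agreement, "moderate")

  # a 3x3 case, kappa by direct formula
  x <- matrix(c(30, 2, 1, 3, 25, 4, 2, 3, 30), 3)
  cm3 <- confusion_matrix(x, 1:3)
  M <- sum(x); chance <- sum(rowSums(x) * colSums(x))
  expect_equal(kappa_coefficient(cm3)$kappa,
               (M * sum(diag(x)) - chance) / (M^2 - chance))
  expect_equal(overall_accuracy(cm3), sum(diag(x)) / M)

  perfect <- confusion_matrix(diag(50, 2), 1:2)
  expect_equal(overall_accuracy(perfect), 1)
  expect_equal(kappa_coefficient(perfect)$kappa, 1)
  expect_equal(kappa_coefficient(perfect)$agreement, "strong")

  allbad <- confusion_matrix(matrix(c(0, 5, 5, 0), 2), 1:2)
  expect_equal(overall_accuracy(allbad), 0)

  chance2 <- confusion_matrix(matrix(1, 2, 2), 1:2)
  expect_equal(kappa_coefficient(chance2)$kappa, 0)

  empty_row <- confusion_matrix(matrix(c(0, 5, 0, 7), 2), 1:2)
  expect_true(is.na(producers_users_accuracy(empty_row)$producers[1]))

  degenerate <- confusion_matrix(matrix(c(7, 0, 0, 0), 2), 1:2)
  k <- kappa_coefficient(degenerate)
  expect_true(is.na(k$kappa))
  expect_equal(k$agreement, "undefined")
})

test_that("kappa = 1 iff off-diagonals vanish; kappa always in [-1, 1]", {
  set.seed(5)
  for (i in 1:50) {
    r <- sample(2:5, 1)
    x <- matrix(rpois(r * r, 4), r)
    if (sum(x) == 0 || sum(rowSums(x) * colSums(x)) == sum(x)^2) next
    k <- kappa_coefficient(confusion_matrix(x))$kappa
    expect_true(k >= -1 && k <= 1)
    expect_equal(isTRUE(all.equal(k, 1)),
                 all(x[row(x) != col(x)] == 0) && sum(diag(x)) > 0)
  }
})

test_that("class-order permutation permutes PA/UA, fixes OA and kappa", {
  x <- matrix(c(40, 5, 2, 10, 45, 3, 1, 2, 30), 3)
  cm <- confusion_matrix(x, 1:3)
  p <- c(3, 1, 2)
  cmp <- confusion_matrix(x[p, p], (1:3)[p])
  expect_equal(overall_accuracy(cm), overall_accuracy(cmp))
  expect_equal(kappa_coefficient(cm)$kappa, kappa_coefficient(cmp)$kappa)
  pu <- producers_users_accuracy(cm)
  pup <- producers_users_accuracy(cmp)
  expect_equal(pup$producers, pu$producers[p])
  expect_equal(pup$users, pu$users[p])
})

test_that("on synthetic truth, OA equals one minus the mislabelled share", {
  sp <- small_spec(rows = 50, cols = 50, seed = 6)
  m <- generate_class_series(sp)[[1]]
  gt <- sample_ground_truth(m, 30, seed = 2)
  flip <- gt
  swap <- 1:40                           # mislabel a known subset
  flip$points$class_code[swap] <-
    (flip$points$class_code[swap] %% 6L) + 1L
  acc <- assess_accuracy(m, flip)
  expect_equal(acc$overall_accuracy, 1 - 40 / 180)
})
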