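#' Confusion matrix between a classified map and reference points
#'
#' Cross-tabulates reference labels (rows) against mapped labels (columns).
#' Classes absent from both sides are dropped, keeping the kappa denominator
#' meaningful; the retained class order follows the map legend (codes absent
#' from the legend, e.g. reference-only codes, are appended in code order).
#'
#' @param map a [class_map()].
#' @param truth a [ground_truth()]; points must be on-grid and off nodata.
#' @return An object of class `confusion_matrix`: list with integer `counts`
#'   (reference x mapped), `class_codes`, total `M`, row sums `n_i` and
#'   column sums `n_j`.
#' @examples
#' m <- class_map(matrix(c(1, 1, 2, 2), 2), lulc_legend())
#' gt <- ground_truth(data.frame(row = c(1, 2, 1, 2), col = c(1, 1, 2, 2),
#'                               class_code = c(1, 1, 2, 1)))
#' build_confusion(m, gt)
#' @export
build_confusion <- function(map, truth) {
  stopifnot(inherits(map, "class_map"), inherits(truth, "ground_truth"))
  pts <- truth$points
  if (!nrow(pts)) stop("empty ground-truth set")
  d <- dim(map$classes)
  if (any(pts$row < 1 | pts$row > d[1] | pts$col < 1 | pts$col > d[2]))
    stop("reference points fall outside the grid")
  mapped <- map$classes[cbind(pts$row, pts$col)]
  if (any(mapped == 0L)) stop("reference points fall on nodata pixels")
  codes <- union(map$legend$class_code,
                 sort(unique(c(pts$class_code, mapped))))
  codes <- codes[codes %in% c(pts$class_code, mapped)]  # drop empty classes
  f <- function(x) factor(x, levels = codes)
  counts <- unclass(table(reference = f(pts$class_code), mapped = f(mapped)))
  confusion_matrix(counts, codes)
}

#' @rdname build_confusion
#' @param counts nonnegative integer matrix, reference classes in rows and
#'   mapped classes in columns.
#' @param class_codes codes labelling the rows/columns (defaults to existing
#'   dimnames or 1..r).
#' @export
confusion_matrix <- function(counts, class_codes = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("confusion matrix must be square")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion-matrix cells must be nonnegative integers")
  storage.mode(counts) <- "integer"
  if (is.null(class_codes))
    class_codes <- if (!is.null(rownames(counts)))
      as.integer(rownames(counts)) else seq_len(nrow(counts))
  dimnames(counts) <- list(reference = class_codes, mapped = class_codes)
  structure(list(counts = counts, class_codes = as.integer(class_codes),
                 M = sum(counts), n_i = rowSums(counts),
                 n_j = colSums(counts)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = reference, cols = mapped), M =", x$M, "\n")
  print(x$counts)
  cat(sprintf("Overall accuracy %.3f, kappa %s\n", overall_accuracy(x),
              format(signif(kappa_coefficient(x)$kappa, 3))))
  invisible(x)
}

#' Overall accuracy
#'
#' Proportion of reference observations whose mapped class agrees with the
#' reference class: the sum of the confusion-matrix diagonal over the total
#' number of observations.
#'
#' @param cm a `confusion_matrix`.
#' @return Proportion in [0, 1].
#' @export
overall_accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$M == 0) stop("empty confusion matrix")
  sum(diag(cm$counts)) / cm$M
}

#' Producer's and user's accuracy per class
#'
#' Producer's accuracy (recall) is the diagonal over the reference row sum;
#' user's accuracy (precision) is the diagonal over the mapped column sum.
#' Classes with a zero denominator get NA.
#'
#' @param cm a `confusion_matrix`.
#' @return Data frame with columns `class_code`, `producers`, `users`.
#' @export
producers_users_accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$M == 0) stop("empty confusion matrix")
  d <- diag(cm$counts)
  data.frame(class_code = cm$class_codes,
             producers = ifelse(cm$n_i > 0, d / cm$n_i, NA_real_),
             users = ifelse(cm$n_j > 0, d / cm$n_j, NA_real_))
}

#' Cohen's kappa coefficient
#'
#' Chance-corrected agreement
#' \deqn{K = \frac{M \sum_i X_{ii} - \sum_i n_i n_j}{M^2 - \sum_i n_i n_j}}
#' where M is the total count, X_ii the diagonal, and n_i / n_j the row and
#' column sums. Returns the agreement band alongside: above 0.80 strong,
#' 0.40 to 0.80 moderate, below 0.40 poor. When the denominator is zero
#' (a single nonempty class), kappa is undefined and NA is returned.
#'
#' @param cm a `confusion_matrix`.
#' @return List with `kappa` (in [-1, 1], or NA) and `agreement` band
#'   ("strong", "moderate", "poor" or "undefined").
#' @export
kappa_coefficient <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$M == 0) stop("empty confusion matrix")
  M <- as.numeric(cm$M)
  chance <- sum(as.numeric(cm$n_i) * as.numeric(cm$n_j))
  if (M^2 == chance)
    return(list(kappa = NA_real_, agreement = "undefined"))
  k <- (M * sum(diag(cm$counts)) - chance) / (M^2 - chance)
  band <- if (k > 0.80) "strong" else if (k >= 0.40) "moderate" else "poor"
  list(kappa = k, agreement = band)
}

#' One-call accuracy report
#'
#' Convenience wrapper bundling the confusion matrix, overall accuracy,
#' per-class producer's/user's accuracy and kappa for one epoch.
#'
#' @param map a [class_map()].
#' @param truth a [ground_truth()].
#' @return List with `confusion`, `overall_accuracy`, `per_class`, `kappa`,
#'   `agreement`.
#' @export
assess_accuracy <- function(map, truth) {
  cm <- build_confusion(map, truth)
  kp <- kappa_coefficient(cm)
  list(confusion = cm, overall_accuracy = overall_accuracy(cm),
       per_class = producers_users_accuracy(cm),
       kappa = kp$kappa, agreement = kp$agreement)
}
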