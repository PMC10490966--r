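#' Load a value-coefficient table
#'
#' Reads a class x service-function table of benefit-value-transfer
#' coefficients (US$ per hectare per year). The CSV layout has one row per
#' service function (17 functions grouped into provisioning, regulatory,
#' supporting, and recreation-and-culture categories) plus a trailing TOTAL
#' row, and one column per land-cover class; blank cells are read as 0.
#' Per-class sums are validated against the TOTAL row to within 0.01 and a
#' mismatch is an error naming the class. The packaged default is the
#' modified conservative coefficient set for tropical Afromontane
#' landscapes (forest 986.69, cultivated 225.56, grassland 293.25, water
#' 8103.5, built-up and barren 0 US$/ha/yr class totals).
#'
#' @param source path to a coefficient CSV; default is the packaged table.
#' @param legend a [lulc_legend()] naming the class columns.
#' @return An object of class `esv_coefficients`: list with `vc`
#'   (K x F matrix, classes x functions), `functions` (code + category),
#'   `class_totals`, and the legend.
#' @examples
#' vc <- load_coefficients()
#' vc$class_totals
#' @export
load_coefficients <- function(source = system.file("extdata",
                                "value_coefficients.csv",
                                package = "lulcesv"),
                              legend = lulc_legend()) {
  raw <- utils::read.csv(source, stringsAsFactors = FALSE,
                         check.names = FALSE)
  need <- c("function_code", "category", legend$class_name)
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("coefficient table lacks column(s): ",
                         paste(miss, collapse = ", "))
  tot_row <- raw$function_code == "TOTAL"
  fun <- raw[!tot_row, , drop = FALSE]
  vals <- as.matrix(fun[, legend$class_name, drop = FALSE])
  vals[is.na(vals)] <- 0        # blanks mean "no value attributed"
  storage.mode(vals) <- "double"
  if (any(vals < 0)) stop("value coefficients must be nonnegative")
  vc <- t(vals)                 # classes x functions
  dimnames(vc) <- list(legend$class_name, fun$function_code)
  totals <- rowSums(vc)
  if (any(tot_row)) {
    declared <- as.numeric(raw[tot_row, legend$class_name][1, ])
    declared[is.na(declared)] <- 0
    off <- abs(totals - declared) > 0.01
    if (any(off))
      stop("per-class coefficient sums disagree with declared totals for: ",
           paste(legend$class_name[off], collapse = ", "))
  }
  if (all(totals == 0))
    warning("all value coefficients are zero")
  structure(list(vc = vc,
                 functions = data.frame(function_code = fun$function_code,
                                        category = fun$category),
                 class_totals = totals, legend = legend),
            class = "esv_coefficients")
}

#' @export
print.esv_coefficients <- function(x, ...) {
  cat("Value-coefficient table:", nrow(x$vc), "classes x", ncol(x$vc),
      "service functions (US$/ha/yr)\n")
  cat("Per-class totals:\n")
  print(round(x$class_totals, 2))
  invisible(x)
}

# Align an area_table's hectares with a coefficient table's class rows.
aligned_areas <- function(areas, coeffs) {
  stopifnot(inherits(areas, "area_table"),
            inherits(coeffs, "esv_coefficients"))
  bad <- setdiff(areas$class_name[areas$area_ha > 0],
                 rownames(coeffs$vc))
  if (length(bad)) stop("no value coefficients for class(es): ",
                        paste(bad, collapse = ", "))
  a <- stats::setNames(numeric(nrow(coeffs$vc)), rownames(coeffs$vc))
  i <- match(areas$class_name, names(a))
  a[i[!is.na(i)]] <- areas$area_ha[!is.na(i)]
  a
}

#' Per-class ecosystem service value
#'
#' ESV_k = A_k * sum_f VC_kf: each class's area in hectares times its
#' total value coefficient, in US$ per year.
#'
#' @param areas an `area_table` ([class_areas()] or [area_table()]).
#' @param coeffs an `esv_coefficients` table.
#' @param extra_esv optional named vector (class name -> US$) of per-class
#'   values entering directly, for classes whose ESV is known but whose
#'   area is not; added to the area-based value of that class.
#' @return Named numeric vector of US$ per year, one entry per class.
#' @examples
#' a <- area_table(c(forestland = 10706.4), epoch_label = 1984)
#' esv_by_class(a, load_coefficients())["forestland"] / 1e6  # 10.56 M US$
#' @export
esv_by_class <- function(areas, coeffs, extra_esv = NULL) {
  a <- aligned_areas(areas, coeffs)
  v <- a * coeffs$class_totals
  if (!is.null(extra_esv)) {
    bad <- setdiff(names(extra_esv), names(v))
    if (length(bad)) stop("unknown class name(s) in extra_esv: ",
                          paste(bad, collapse = ", "))
    v[names(extra_esv)] <- v[names(extra_esv)] + extra_esv
  }
  v
}

#' Per-function ecosystem service value
#'
#' ESV_f = sum_k A_k * VC_kf: for each of the 17 service functions, the
#' area-weighted sum of that function's coefficients over all classes,
#' in US$ per year. Classes entering through `extra_esv` (value known,
#' area unknown) are apportioned over functions in proportion to the
#' class's coefficient row.
#'
#' @inheritParams esv_by_class
#' @return Named numeric vector of US$ per year, one entry per function.
#' @export
esv_by_function <- function(areas, coeffs, extra_esv = NULL) {
  a <- aligned_areas(areas, coeffs)
  v <- as.vector(a %*% coeffs$vc)
  names(v) <- colnames(coeffs$vc)
  if (!is.null(extra_esv)) {
    for (cl in names(extra_esv)) {
      tot <- coeffs$class_totals[cl]
      if (tot > 0)
        v <- v + extra_esv[[cl]] * coeffs$vc[cl, ] / tot
    }
  }
  v
}

#' Total ecosystem service value
#'
#' ESV = sum_k sum_f A_k * VC_kf; by construction it equals both the sum of
#' the per-class values and the sum of the per-function values.
#'
#' @inheritParams esv_by_class
#' @return Total US$ per year.
#' @export
esv_total <- function(areas, coeffs, extra_esv = NULL) {
  sum(esv_by_class(areas, coeffs, extra_esv))
}

#' Percent change between two ecosystem service values
#'
#' (end - start) / start * 100. In `"paper"` mode both values are first
#' rounded half-away-from-zero to 0.1 million US$, matching how published
#' change percentages are computed from tabulated values at one decimal in
#' millions; `"raw"` mode uses the values as given.
#'
#' @param esv_start,esv_end values in US$ (start must be nonzero).
#' @param mode `"paper"` (round inputs to 0.1 M US$ first) or `"raw"`.
#' @return Percent change.
#' @examples
#' esv_percent_change(55.1e6, 7.4e6)  # -86.6
#' @export
esv_percent_change <- function(esv_start, esv_end,
                               mode = c("paper", "raw")) {
  mode <- match.arg(mode)
  if (mode == "paper") {
    esv_start <- round_half_away(esv_start / 1e6, 1) * 1e6
    esv_end <- round_half_away(esv_end / 1e6, 1) * 1e6
  }
  if (esv_start == 0) stop("starting ESV is zero; percent change undefined")
  (esv_end - esv_start) / esv_start * 100
}

#' Coefficient of sensitivity (elasticity) of the total ESV
#'
#' Scales one class's value coefficients by (1 + perturbation), recomputes
#' the total ESV, and forms the elasticity
#' \deqn{CS = \frac{(ESV_j - ESV_i)/ESV_i}{(VC_{jk} - VC_{ik})/VC_{ik}}}
#' of the total with respect to that class's coefficient. Because the
#' perturbation is proportional to the whole coefficient row, CS reduces to
#' the class's share of the total value and is identical for the + and -
#' perturbation of the same magnitude. A class with all-zero coefficients
#' has CS = 0 by definition. The estimate is called elastic when CS > 1 and
#' inelastic otherwise.
#'
#' @inheritParams esv_by_class
#' @param class_name class whose coefficients are perturbed.
#' @param perturbation proportional adjustment (default 0.5, i.e. +/-50%).
#' @return One-row data frame with baseline `esv_i`, adjusted `esv_j`,
#'   `cs` and the `elasticity` verdict.
#' @export
coefficient_sensitivity <- function(areas, coeffs, class_name,
                                    perturbation = 0.5, extra_esv = NULL) {
  if (!class_name %in% rownames(coeffs$vc))
    stop("unknown class: ", class_name)
  by_class <- esv_by_class(areas, coeffs, extra_esv)
  esv_i <- sum(by_class)
  if (esv_i <= 0) stop("baseline total ESV must be positive")
  has_extra <- !is.null(extra_esv) && class_name %in% names(extra_esv)
  if (coeffs$class_totals[class_name] == 0 && !has_extra) {
    cs <- 0                     # zero-coefficient class: no effect at all
    esv_j <- esv_i
  } else {
    esv_j <- esv_i + perturbation * by_class[[class_name]]
    cs <- ((esv_j - esv_i) / esv_i) / perturbation
  }
  data.frame(class_name = class_name, perturbation = perturbation,
             esv_i = esv_i, esv_j = esv_j, cs = cs,
             elasticity = if (cs > 1) "elastic" else "inelastic")
}

#' Multi-epoch ESV report
#'
#' Bundles per-class and per-function ESVs and the total for every epoch,
#' plus absolute and percent changes for each requested epoch pair.
#'
#' @param areas_by_epoch named list of `area_table`s (names = epoch labels).
#' @param coeffs an `esv_coefficients` table.
#' @param epoch_pairs list of length-2 vectors of epoch labels; default is
#'   consecutive pairs plus first-to-last.
#' @param mode percent-change mode, see [esv_percent_change()].
#' @param extra_esv_by_epoch optional named list (epoch -> named vector)
#'   of direct per-class values, see [esv_by_class()].
#' @return An object of class `esv_report`: list with `by_class`,
#'   `by_function` (classes/functions x epochs matrices, US$), `totals`,
#'   and `changes` (data frame per pair and scope).
#' @export
esv_report <- function(areas_by_epoch, coeffs, epoch_pairs = NULL,
                       mode = c("paper", "raw"),
                       extra_esv_by_epoch = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(areas_by_epoch) >= 1, !is.null(names(areas_by_epoch)))
  epochs <- names(areas_by_epoch)
  xtra <- function(ep) extra_esv_by_epoch[[ep]]
  k <- vapply(epochs, function(ep)
    esv_by_class(areas_by_epoch[[ep]], coeffs, xtra(ep)),
    numeric(nrow(coeffs$vc)))
  f <- vapply(epochs, function(ep)
    esv_by_function(areas_by_epoch[[ep]], coeffs, xtra(ep)),
    numeric(ncol(coeffs$vc)))
  totals <- colSums(k)
  if (is.null(epoch_pairs) && length(epochs) > 1) {
    epoch_pairs <- lapply(seq_len(length(epochs) - 1),
                          function(i) epochs[c(i, i + 1)])
    if (length(epochs) > 2)
      epoch_pairs <- c(epoch_pairs, list(epochs[c(1, length(epochs))]))
  }
  changes <- NULL
  for (pr in epoch_pairs) {
    a <- as.character(pr[1]); b <- as.character(pr[2])
    if (!all(c(a, b) %in% epochs))
      stop("epoch pair ", a, ":", b, " references undeclared epochs")
    pc <- function(x0, x1)   # NA when the (possibly rounded) start is zero
      tryCatch(esv_percent_change(x0, x1, mode), error = function(e) NA_real_)
    rows <- rbind(
      data.frame(scope = "class", name = rownames(k),
                 start = k[, a], end = k[, b]),
      data.frame(scope = "function", name = rownames(f),
                 start = f[, a], end = f[, b]),
      data.frame(scope = "total", name = "total",
                 start = totals[[a]], end = totals[[b]]))
    rows$epoch_a <- a; rows$epoch_b <- b
    rows$change_usd <- rows$end - rows$start
    rows$change_pct <- mapply(pc, rows$start, rows$end)
    changes <- rbind(changes, rows)
  }
  if (!is.null(changes)) rownames(changes) <- NULL
  structure(list(by_class = k, by_function = f, totals = totals,
                 changes = changes, mode = mode, unit = "USD"),
            class = "esv_report")
}

#' @export
print.esv_report <- function(x, ...) {
  cat("Ecosystem service values (million US$ per year):\n")
  cat("\nPer class:\n")
  print(round(x$by_class / 1e6, 1))
  cat("\nTotals:\n")
  print(round(x$totals / 1e6, 1))
  if (!is.null(x$changes)) {
    tot <- x$changes[x$changes$scope == "total", ]
    cat("\nTotal-change summary (", x$mode, " rounding mode):\n", sep = "")
    print(data.frame(pair = paste(tot$epoch_a, tot$epoch_b, sep = "-"),
                     change_musd = round(tot$change_usd / 1e6, 1),
                     change_pct = round(tot$change_pct, 1)),
          row.names = FALSE)
  }
  invisible(x)
}

#' Sensitivity table over classes and epochs
#'
#' Runs [coefficient_sensitivity()] for every class with nonzero
#' coefficients (zero-coefficient classes are reported with CS = 0) in
#' every epoch.
#'
#' @inheritParams esv_report
#' @param perturbation proportional coefficient adjustment (default 0.5).
#' @return Data frame with one row per epoch x class.
#' @export
sensitivity_table <- function(areas_by_epoch, coeffs, perturbation = 0.5,
                              extra_esv_by_epoch = NULL) {
  out <- NULL
  for (ep in names(areas_by_epoch)) {
    for (cl in rownames(coeffs$vc)) {
      row <- coefficient_sensitivity(areas_by_epoch[[ep]], coeffs, cl,
                                     perturbation,
                                     extra_esv_by_epoch[[ep]])
      row <- cbind(epoch = ep, row)
      out <- rbind(out, row)
    }
  }
  rownames(out) <- NULL
  out
}
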