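#' Per-class areas of a land-cover map
#'
#' Counts pixels per legend class (nodata excluded) and converts to hectares
#' via area_ha = pixel_count * pixel_size_m^2 / 10000.
#'
#' @param map a [class_map()].
#' @return An object of class `area_table`: data frame with `class_code`,
#'   `class_name`, `pixels`, `area_ha` (one row per legend class, zero
#'   rows included) plus attributes `total_area_ha`, `pixel_size_m`,
#'   `epoch_label`.
#' @examples
#' m <- class_map(matrix(1L, 10, 10), lulc_legend(), 30)
#' class_areas(m)  # 100 pixels at 30 m -> 9 ha
#' @export
class_areas <- function(map) {
  stopifnot(inherits(map, "class_map"))
  ha_per_px <- map$pixel_size_m^2 / 1e4
  counts <- vapply(map$legend$class_code,
                   function(cc) sum(map$classes == cc), 0L)
  out <- data.frame(class_code = map$legend$class_code,
                    class_name = map$legend$class_name,
                    pixels = counts,
                    area_ha = counts * ha_per_px)
  attr(out, "total_area_ha") <- sum(out$area_ha)
  attr(out, "pixel_size_m") <- map$pixel_size_m
  attr(out, "epoch_label") <- map$epoch_label
  class(out) <- c("area_table", "data.frame")
  out
}

#' Build an area table from known hectare values
#'
#' Constructs the same container [class_areas()] returns, but from areas
#' given directly (e.g. published per-class areas), so the valuation module
#' can run without rasters.
#'
#' @param area_ha named numeric vector (names = class names) or numeric
#'   vector ordered as `legend`; classes omitted from a named vector get 0.
#' @param legend a [lulc_legend()].
#' @param epoch_label year or other label.
#' @return An `area_table`.
#' @examples
#' area_table(c(forestland = 10706.4, grassland = 26319.6, water = 6806.7),
#'            epoch_label = 1984)
#' @export
area_table <- function(area_ha, legend = lulc_legend(), epoch_label = NA) {
  if (!is.null(names(area_ha))) {
    bad <- setdiff(names(area_ha), legend$class_name)
    if (length(bad)) stop("unknown class name(s): ",
                          paste(bad, collapse = ", "))
    v <- stats::setNames(numeric(nrow(legend)), legend$class_name)
    v[names(area_ha)] <- area_ha
  } else {
    if (length(area_ha) != nrow(legend))
      stop("unnamed area vector must have one entry per legend class")
    v <- stats::setNames(as.numeric(area_ha), legend$class_name)
  }
  if (any(v < 0)) stop("areas must be nonnegative")
  out <- data.frame(class_code = legend$class_code,
                    class_name = legend$class_name,
                    pixels = NA_integer_, area_ha = unname(v))
  attr(out, "total_area_ha") <- sum(v)
  attr(out, "pixel_size_m") <- NA_real_
  attr(out, "epoch_label") <- epoch_label
  class(out) <- c("area_table", "data.frame")
  out
}

#' Annualized land-cover change rate
#'
#' The degree of change of one cover type over an estimation period of t
#' years, expressed as a yearly percentage of the starting area:
#' \deqn{rate = \frac{A_{end} - A_{start}}{A_{start}} \cdot \frac{1}{t}
#'   \cdot 100}
#' Positive values indicate expansion, negative values contraction. The
#' companion absolute rate is (A_end - A_start)/t in ha per year.
#'
#' @param start_area_ha,end_area_ha class area in hectares at the two dates
#'   (start must be positive).
#' @param start_year,end_year epoch years (end > start).
#' @param class_code optional class code carried through to the result.
#' @return An object of class `change_summary` (one-row data frame) with
#'   `annual_rate_pct` and `annual_area_change_ha`.
#' @examples
#' change_rate(10706.4, 5005.31, 1984, 2021)  # -1.44 %/yr, -154.1 ha/yr
#' @export
change_rate <- function(start_area_ha, end_area_ha, start_year, end_year,
                        class_code = NA) {
  if (start_area_ha <= 0) stop("start area must be positive")
  t <- end_year - start_year
  if (t <= 0) stop("end_year must exceed start_year")
  out <- data.frame(class_code = class_code,
                    start_year = start_year, end_year = end_year,
                    start_area_ha = start_area_ha,
                    end_area_ha = end_area_ha, t = t,
                    annual_rate_pct =
                      (end_area_ha - start_area_ha) / start_area_ha / t * 100,
                    annual_area_change_ha = (end_area_ha - start_area_ha) / t)
  class(out) <- c("change_summary", "data.frame")
  out
}

#' Cross-tabulated transition matrix between two epochs
#'
#' Post-classification comparison: cell (i, j) holds the hectares of pixels
#' classed i in the first epoch and j in the second, restricted to pixels
#' that are non-nodata in both maps. Per class, the derived columns follow
#' the usual bookkeeping: persistence is the diagonal, loss the off-diagonal
#' row remainder, gain the off-diagonal column remainder, net change
#' Nc = gain - loss, and the net-change-to-persistence ratio Np = Nc
#' divided by the class's unchanged area (NA when nothing persisted).
#'
#' @param map_a,map_b two [class_map()]s on the same grid, pixel size and
#'   legend.
#' @return An object of class `transition_matrix`: list with `hectares`
#'   (K x K), `summary` data frame (persistence, loss, gain, net_change,
#'   net_to_persistence per class), epoch labels and pixel size.
#' @examples
#' l <- lulc_legend(1:2, c("a", "b"), "")
#' a <- class_map(matrix(c(1, 1, 2, 2), 2), l, 30)
#' b <- class_map(matrix(c(1, 2, 2, 2), 2), l, 30)
#' cross_tabulate(a, b)$hectares
#' @export
cross_tabulate <- function(map_a, map_b) {
  stopifnot(inherits(map_a, "class_map"), inherits(map_b, "class_map"))
  if (!all(dim(map_a$classes) == dim(map_b$classes)))
    stop("maps must share the same grid")
  if (map_a$pixel_size_m != map_b$pixel_size_m)
    stop("maps must share the same pixel size")
  if (!identical(map_a$legend$class_code, map_b$legend$class_code))
    stop("maps must share the same legend")
  codes <- map_a$legend$class_code
  ok <- map_a$classes != 0L & map_b$classes != 0L
  f <- function(x) factor(x, levels = codes)
  ha_per_px <- map_a$pixel_size_m^2 / 1e4
  H <- unclass(table(from = f(map_a$classes[ok]),
                     to = f(map_b$classes[ok]))) * ha_per_px
  dimnames(H) <- list(from = map_a$legend$class_name,
                      to = map_a$legend$class_name)
  transition_matrix(H, map_a$legend,
                    epoch_a = map_a$epoch_label, epoch_b = map_b$epoch_label,
                    pixel_size_m = map_a$pixel_size_m)
}

#' @rdname cross_tabulate
#' @param hectares K x K matrix of transition areas (from-class rows,
#'   to-class columns).
#' @param legend the shared [lulc_legend()].
#' @param epoch_a,epoch_b epoch labels.
#' @param pixel_size_m pixel size carried through for provenance.
#' @export
transition_matrix <- function(hectares, legend, epoch_a = NA, epoch_b = NA,
                              pixel_size_m = NA) {
  H <- as.matrix(hectares)
  k <- nrow(legend)
  if (!all(dim(H) == k)) stop("hectares must be K x K for the legend")
  if (any(H < 0)) stop("transition areas must be nonnegative")
  persistence <- diag(H)
  loss <- rowSums(H) - persistence
  gain <- colSums(H) - persistence
  nc <- gain - loss
  s <- data.frame(class_code = legend$class_code,
                  class_name = legend$class_name,
                  area_a_ha = rowSums(H), area_b_ha = colSums(H),
                  persistence_ha = persistence, loss_ha = loss,
                  gain_ha = gain, net_change_ha = nc,
                  net_to_persistence =
                    ifelse(persistence > 0, nc / persistence, NA_real_))
  rownames(s) <- NULL
  structure(list(hectares = H, summary = s, legend = legend,
                 epoch_a = epoch_a, epoch_b = epoch_b,
                 pixel_size_m = pixel_size_m),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("Transition matrix", if (!is.na(x$epoch_a))
    paste0(x$epoch_a, " -> ", x$epoch_b), "(ha)\n")
  print(round(x$hectares, 2))
  cat("\nPer-class summary:\n")
  print(cbind(x$summary[, c("class_name", "persistence_ha", "loss_ha",
                            "gain_ha", "net_change_ha")],
              net_to_persistence = round(x$summary$net_to_persistence, 2)),
        row.names = FALSE)
  invisible(x)
}
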