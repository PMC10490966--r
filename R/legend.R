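#' Land-cover legends
#'
#' A legend maps small positive integer class codes to class names; code 0 is
#' reserved for nodata everywhere in the package. [lulc_legend()] returns the
#' default six-class land-use/land-cover legend (dry Afromontane forestland,
#' cultivated land, grassland, built-up area, barren land, water bodies);
#' [ndvi_legend()] returns the five vegetation-density classes used when
#' binning NDVI.
#'
#' @param codes integer class codes, unique and strictly positive.
#' @param names character class names, one per code.
#' @param descriptions optional character descriptions, recycled to length.
#' @return An object of class `lulc_legend`: a data frame with columns
#'   `class_code`, `class_name`, `description`.
#' @examples
#' lulc_legend()
#' ndvi_legend()
#' @export
lulc_legend <- function(codes = 1:6,
                        names = c("forestland", "cultivated", "grassland",
                                  "built_up", "barren", "water"),
                        descriptions = c(
                          "Dry evergreen Afromontane forest and plantations",
                          "Rain-fed and irrigated crop fields",
                          "Open grass and rangeland",
                          "Settlements, roads and other built surfaces",
                          "Exposed soil and rock with little vegetation",
                          "Lakes, rivers and reservoirs")) {
  codes <- as.integer(codes)
  if (anyDuplicated(codes) || any(codes <= 0L))
    stop("class codes must be unique and strictly positive (0 is nodata)")
  if (length(names) != length(codes))
    stop("one class name per class code required")
  out <- data.frame(class_code = codes,
                    class_name = as.character(names),
                    description = rep_len(as.character(descriptions),
                                          length(codes)),
                    stringsAsFactors = FALSE)
  class(out) <- c("lulc_legend", "data.frame")
  out
}

#' @rdname lulc_legend
#' @export
ndvi_legend <- function() {
  lulc_legend(
    codes = 1:5,
    names = c("non_vegetation", "very_low_vegetation", "low_vegetation",
              "moderate_vegetation", "dense_vegetation"),
    descriptions = c(
      "Non-vegetation areas or water bodies (NDVI in [-1, -0.03))",
      "Very low vegetation (NDVI in [-0.03, 0.15))",
      "Low vegetation (NDVI in [0.15, 0.25))",
      "Moderate vegetation, alias grassland (NDVI in [0.25, 0.35))",
      "Thriving, very dense vegetation (NDVI in [0.35, 1])"))
}

#' @export
print.lulc_legend <- function(x, ...) {
  cat("Land-cover legend (", nrow(x), " classes; 0 = nodata)\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

legend_names <- function(legend, codes) {
  legend$class_name[match(codes, legend$class_code)]
}
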