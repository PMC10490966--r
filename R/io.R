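#' Raster and table input/output
#'
#' Rasters are exchanged as ESRI ASCII grids (`.asc`): a six-line header
#' (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by
#' rows of whitespace-separated values, top row first. Multi-band scenes are
#' written one grid per band with a YAML sidecar recording band order, band
#' roles and the epoch label. Class maps use integer codes with NODATA 0;
#' NDVI grids use NODATA -9999.
#'
#' @param values numeric or integer matrix to write.
#' @param path output path.
#' @param cellsize pixel size in metres.
#' @param nodata value standing for nodata in the file; NA cells are
#'   written as this value.
#' @param xll,yll lower-left corner coordinates carried in the header.
#' @return `write_ascii_grid()` returns `path` invisibly;
#'   `read_ascii_grid()` returns a list with `values` (matrix, nodata as
#'   NA), `cellsize`, `nodata`, `xll`, `yll`.
#' @name ascii_grid
NULL

#' @rdname ascii_grid
#' @export
write_ascii_grid <- function(values, path, cellsize = 30, nodata = -9999,
                             xll = 0, yll = 0) {
  values <- as.matrix(values)
  values[is.na(values)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(values)),
               paste("nrows", nrow(values)),
               paste("xllcorner", xll),
               paste("yllcorner", yll),
               paste("cellsize", cellsize),
               paste("NODATA_value", nodata)), con)
  utils::write.table(values, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname ascii_grid
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  m <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(m) <- NULL
  if (nrow(m) != h["nrows"] || ncol(m) != h["ncols"])
    stop("grid dimensions disagree with header in ", path)
  m[m == h["nodata_value"]] <- NA
  list(values = m, cellsize = h[["cellsize"]],
       nodata = h[["nodata_value"]],
       xll = h[["xllcorner"]], yll = h[["yllcorner"]])
}

#' Write / read a class map
#'
#' Single ASCII grid with integer codes and NODATA 0, plus a YAML sidecar
#' (`<path>.yml`) holding the legend and epoch label.
#'
#' @param map a [class_map()].
#' @param path `.asc` output path.
#' @return `write_class_map()` returns `path` invisibly; `read_class_map()`
#'   the reconstructed [class_map()].
#' @export
write_class_map <- function(map, path) {
  stopifnot(inherits(map, "class_map"))
  write_ascii_grid(map$classes, path, cellsize = map$pixel_size_m,
                   nodata = 0)
  yaml::write_yaml(list(epoch_label = map$epoch_label,
                        legend = lapply(seq_len(nrow(map$legend)), function(i)
                          as.list(map$legend[i, ]))),
                   paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_class_map
#' @export
read_class_map <- function(path) {
  g <- read_ascii_grid(path)
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  leg <- do.call(rbind, lapply(meta$legend, as.data.frame))
  v <- g$values
  v[is.na(v)] <- 0
  class_map(v, lulc_legend(leg$class_code, leg$class_name, leg$description),
            g$cellsize, meta$epoch_label %||% NA)
}

#' Write / read a multi-band scene
#'
#' One ASCII grid per band (`<stem>_band<i>.asc`, NODATA -9999) plus a YAML
#' sidecar `<stem>.yml` with band roles, band files and epoch label.
#'
#' @param scene a [spectral_scene()].
#' @param stem path stem (no extension).
#' @return `write_scene()` returns `stem` invisibly; `read_scene()` the
#'   reconstructed [spectral_scene()].
#' @export
write_scene <- function(scene, stem) {
  stopifnot(inherits(scene, "spectral_scene"))
  B <- dim(scene$bands)[3]
  files <- character(B)
  for (b in seq_len(B)) {
    v <- scene$bands[, , b]
    v[scene$nodata_mask] <- NA
    files[b] <- paste0(stem, "_band", b, ".asc")
    write_ascii_grid(v, files[b], cellsize = scene$pixel_size_m)
  }
  yaml::write_yaml(list(epoch_label = scene$epoch_label,
                        band_files = basename(files),
                        band_roles = as.list(scene$band_roles)),
                   paste0(stem, ".yml"))
  invisible(stem)
}

#' @rdname write_scene
#' @export
read_scene <- function(stem) {
  meta <- yaml::read_yaml(paste0(stem, ".yml"))
  grids <- lapply(file.path(dirname(stem), meta$band_files), read_ascii_grid)
  bands <- array(unlist(lapply(grids, `[[`, "values")),
                 c(dim(grids[[1]]$values), length(grids)))
  mask <- is.na(grids[[1]]$values)
  bands[is.na(bands)] <- 0     # values under the mask are never read
  spectral_scene(bands, unlist(meta$band_roles), nodata_mask = mask,
                 pixel_size_m = grids[[1]]$cellsize,
                 epoch_label = meta$epoch_label %||% NA)
}

#' Write / read ground-truth points as CSV
#'
#' Columns `row`, `col`, `class_code`.
#'
#' @param truth a [ground_truth()].
#' @param path CSV path.
#' @param epoch_label label attached on read.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  utils::write.csv(truth$points, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path, epoch_label = NA) {
  ground_truth(utils::read.csv(path), epoch_label)
}

#' Serialize fitted class signatures to CSV
#'
#' One row per class: `class_code`, `n_samples`, band means
#' (`mean_1..mean_B`) and the flattened covariance (`cov_i_j`, row-major).
#'
#' @param fit an `mlc` object from [fit_signatures()].
#' @param path CSV path.
#' @export
write_signatures <- function(fit, path) {
  stopifnot(inherits(fit, "mlc"))
  B <- fit$n_bands
  rows <- lapply(fit$signatures, function(s) {
    v <- c(s$class_code, s$n_samples, s$mean, as.vector(t(s$cov)))
    stats::setNames(as.data.frame(t(v)),
                    c("class_code", "n_samples", paste0("mean_", seq_len(B)),
                      paste0("cov_", rep(seq_len(B), each = B), "_",
                             rep(seq_len(B), B))))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signatures
#' @export
read_signatures <- function(path) {
  df <- utils::read.csv(path)
  B <- sum(grepl("^mean_", names(df)))
  sigs <- lapply(seq_len(nrow(df)), function(i) {
    list(class_code = as.integer(df$class_code[i]),
         mean = as.numeric(df[i, paste0("mean_", seq_len(B))]),
         cov = matrix(as.numeric(df[i, grepl("^cov_", names(df))]),
                      B, B, byrow = TRUE),
         n_samples = as.integer(df$n_samples[i]), regularized = NA)
  })
  structure(list(signatures = sigs, n_bands = B), class = "mlc")
}

#' Write a transition matrix (with its per-class summary) as CSV
#'
#' The matrix block has a header row naming the to-classes; the summary
#' block follows after a blank line.
#'
#' @param tm a `transition_matrix`.
#' @param path CSV path.
#' @export
write_transition_matrix <- function(tm, path) {
  stopifnot(inherits(tm, "transition_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# transition ", tm$epoch_a, " -> ", tm$epoch_b,
                    " (ha)"), con)
  utils::write.csv(as.data.frame(tm$hectares), con)
  writeLines("", con)
  utils::write.csv(tm$summary, con, row.names = FALSE)
  invisible(path)
}
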