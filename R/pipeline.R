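#' Pipeline run configuration
#'
#' Collects everything one end-to-end run needs: a [scene_spec()] for
#' simulation (or pre-existing class maps), ground-truth sampling size,
#' epoch pairs for change analysis, the value-coefficient source, the
#' percent-change rounding mode, the sensitivity perturbation, the master
#' seed and the output directory.
#'
#' @param spec a [scene_spec()] used to simulate scenes; alternatively
#'   supply `maps`, a named list of [class_map()]s keyed by epoch label.
#' @param maps optional pre-classified maps; when given, the simulate and
#'   classify stages are skipped and the maps are analysed as-is.
#' @param n_truth_per_class reference points sampled per class and epoch.
#' @param epoch_pairs list of length-2 epoch-label vectors; default is
#'   consecutive pairs plus first-to-last.
#' @param coefficients path to a coefficient CSV (default: packaged table).
#' @param rounding percent-change mode, `"paper"` or `"raw"`.
#' @param perturbation sensitivity perturbation in (0, 1).
#' @param seed master seed; overrides `spec$seed` when given.
#' @param out_dir output directory for report artifacts.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = NULL, maps = NULL, n_truth_per_class = 50,
                            epoch_pairs = NULL,
                            coefficients = NULL,
                            rounding = c("paper", "raw"),
                            perturbation = 0.5, seed = NULL,
                            out_dir = tempfile("lulcesv_run_")) {
  rounding <- match.arg(rounding)
  if (is.null(spec) && is.null(maps))
    stop("either a scene spec or pre-classified maps must be supplied")
  if (perturbation <= 0 || perturbation >= 1)
    stop("perturbation must lie in (0, 1)")
  if (!is.null(seed) && !is.null(spec)) spec$seed <- as.integer(seed)
  epochs <- if (!is.null(spec)) as.character(spec$epochs) else names(maps)
  for (pr in epoch_pairs)
    if (!all(as.character(pr) %in% epochs))
      stop("epoch pair ", paste(pr, collapse = ":"),
           " references undeclared epochs")
  structure(list(spec = spec, maps = maps,
                 n_truth_per_class = n_truth_per_class,
                 epoch_pairs = epoch_pairs, coefficients = coefficients,
                 rounding = rounding, perturbation = perturbation,
                 seed = seed %||% (if (!is.null(spec)) spec$seed else 1L),
                 out_dir = out_dir),
            class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Simulate (or take) multi-epoch class maps, render reflectances, sample
#' ground truth, fit signatures and classify, compute NDVI and its density
#' classes, assess accuracy, detect change (areas, rates, transition
#' matrices), value ecosystem services and run the sensitivity analysis.
#' All artifacts are written under the configured output directory and a
#' manifest JSON lists every file with its MD5 checksum; runs are
#' deterministic given the seed.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, the report bundle: list with `maps` (classified),
#'   `accuracy`, `areas`, `rates`, `transitions`, `esv`, `sensitivity`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  coeffs <- run_stage("coefficients",
    if (is.null(config$coefficients)) load_coefficients()
    else load_coefficients(config$coefficients))

  simulated <- is.null(config$maps)
  truth <- list(); classified <- list(); accuracy <- list(); ndvi <- list()
  if (simulated) {
    spec <- config$spec
    true_maps <- run_stage("simulate", generate_class_series(spec))
    names(true_maps) <- as.character(spec$epochs)
    for (ep in names(true_maps)) {
      scn <- run_stage("render", render_spectra(true_maps[[ep]], spec))
      gt <- run_stage("ground_truth",
        sample_ground_truth(true_maps[[ep]], config$n_truth_per_class,
                            seed = substream_seed(spec$seed,
                                                  paste0("truth_", ep))))
      fit <- run_stage("signatures", fit_signatures(scn, gt))
      classified[[ep]] <- run_stage("classify",
        classify_max_likelihood(scn, fit, legend = spec$legend))
      accuracy[[ep]] <- run_stage("accuracy",
        assess_accuracy(classified[[ep]], gt))
      ndvi[[ep]] <- run_stage("ndvi", bin_ndvi(compute_ndvi(scn)))
      truth[[ep]] <- gt
      write_class_map(classified[[ep]],
                      file.path(config$out_dir,
                                paste0("classified_", ep, ".asc")))
      write_class_map(ndvi[[ep]],
                      file.path(config$out_dir, paste0("ndvi_", ep, ".asc")))
      write_ground_truth(gt, file.path(config$out_dir,
                                       paste0("truth_", ep, ".csv")))
    }
  } else {
    classified <- config$maps
    for (ep in names(classified))
      write_class_map(classified[[ep]],
                      file.path(config$out_dir,
                                paste0("classified_", ep, ".asc")))
  }
  epochs <- names(classified)

  areas <- run_stage("areas", lapply(classified, class_areas))
  pairs <- config$epoch_pairs
  if (is.null(pairs) && length(epochs) > 1) {
    pairs <- lapply(seq_len(length(epochs) - 1),
                    function(i) epochs[c(i, i + 1)])
    if (length(epochs) > 2) pairs <- c(pairs, list(epochs[c(1,
                                                            length(epochs))]))
  }
  transitions <- list(); rates <- NULL
  for (pr in pairs) {
    a <- as.character(pr[1]); b <- as.character(pr[2])
    key <- paste(a, b, sep = "_")
    transitions[[key]] <- run_stage("change",
      cross_tabulate(classified[[a]], classified[[b]]))
    write_transition_matrix(transitions[[key]],
      file.path(config$out_dir, paste0("transition_", key, ".csv")))
    ya <- suppressWarnings(as.numeric(a)); yb <- suppressWarnings(as.numeric(b))
    if (!is.na(ya) && !is.na(yb)) {
      for (i in seq_len(nrow(areas[[a]]))) {
        if (areas[[a]]$area_ha[i] > 0) {
          r <- change_rate(areas[[a]]$area_ha[i], areas[[b]]$area_ha[i],
                           ya, yb, class_code = areas[[a]]$class_code[i])
          r$class_name <- areas[[a]]$class_name[i]
          rates <- rbind(rates, r)
        }
      }
    }
  }

  valuation <- run_stage("esv",
    run_valuation_only(areas, coeffs, epoch_pairs = pairs,
                       rounding = config$rounding,
                       perturbation = config$perturbation))

  for (ep in epochs)
    utils::write.csv(areas[[ep]],
                     file.path(config$out_dir, paste0("areas_", ep, ".csv")),
                     row.names = FALSE)
  if (!is.null(rates))
    utils::write.csv(rates, file.path(config$out_dir, "change_rates.csv"),
                     row.names = FALSE)
  utils::write.csv(round(valuation$esv$by_class, 2),
                   file.path(config$out_dir, "esv_by_class.csv"))
  utils::write.csv(round(valuation$esv$by_function, 2),
                   file.path(config$out_dir, "esv_by_function.csv"))
  if (!is.null(valuation$esv$changes))
    utils::write.csv(valuation$esv$changes,
                     file.path(config$out_dir, "esv_changes.csv"),
                     row.names = FALSE)
  utils::write.csv(valuation$sensitivity,
                   file.path(config$out_dir, "sensitivity.csv"),
                   row.names = FALSE)
  if (length(accuracy)) {
    acc <- lapply(accuracy, function(a)
      list(overall_accuracy = a$overall_accuracy, kappa = a$kappa,
           agreement = a$agreement,
           per_class = a$per_class))
    jsonlite::write_json(acc, file.path(config$out_dir, "accuracy.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }

  files <- sort(setdiff(list.files(config$out_dir, full.names = TRUE),
                        file.path(config$out_dir, "manifest.json")))
  manifest <- list(
    seed = config$seed,
    coefficient_table_md5 = unname(tools::md5sum(
      config$coefficients %||% system.file("extdata",
        "value_coefficients.csv", package = "lulcesv"))),
    artifacts = data.frame(file = basename(files),
                           md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  invisible(list(maps = classified, truth = truth, accuracy = accuracy,
                 ndvi = ndvi, areas = areas, rates = rates,
                 transitions = transitions, esv = valuation$esv,
                 sensitivity = valuation$sensitivity, manifest = manifest,
                 out_dir = config$out_dir))
}

#' Valuation and sensitivity from area tables alone
#'
#' Runs the valuation sub-pipeline (per-class, per-function and total ESVs,
#' changes between epoch pairs, and the coefficient-of-sensitivity table)
#' directly from per-epoch area tables, with no rasters involved. Given the
#' same areas it produces numbers identical to the full pipeline.
#'
#' @param areas_by_epoch named list of `area_table`s (names = epoch labels).
#' @param coeffs an `esv_coefficients` table (default: packaged).
#' @param epoch_pairs list of length-2 epoch-label vectors.
#' @param rounding percent-change mode, `"paper"` or `"raw"`.
#' @param perturbation sensitivity perturbation in (0, 1).
#' @param extra_esv_by_epoch optional named list (epoch -> named vector) of
#'   direct per-class values for classes without area figures.
#' @return List with `esv` (an [esv_report()]) and `sensitivity` (data
#'   frame); if every area table is all-zero the ESVs are zero and the
#'   sensitivity table carries an explicit `undefined` flag.
#' @export
run_valuation_only <- function(areas_by_epoch, coeffs = load_coefficients(),
                               epoch_pairs = NULL,
                               rounding = c("paper", "raw"),
                               perturbation = 0.5,
                               extra_esv_by_epoch = NULL) {
  rounding <- match.arg(rounding)
  rep <- esv_report(areas_by_epoch, coeffs, epoch_pairs, mode = rounding,
                    extra_esv_by_epoch = extra_esv_by_epoch)
  sens <- NULL
  for (ep in names(areas_by_epoch)) {
    if (rep$totals[[ep]] > 0) {
      s <- sensitivity_table(areas_by_epoch[ep], coeffs, perturbation,
                             extra_esv_by_epoch[ep])
      s$undefined <- FALSE
    } else {
      s <- data.frame(epoch = ep, class_name = rownames(coeffs$vc),
                      perturbation = perturbation, esv_i = 0, esv_j = 0,
                      cs = NA_real_, elasticity = NA_character_,
                      undefined = TRUE)
    }
    sens <- rbind(sens, s)
  }
  list(esv = rep, sensitivity = sens)
}
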