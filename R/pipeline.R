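#' Pipeline configuration
#'
#' Bundles every tunable of the simulate - segment - measure - classify -
#' spatial - report chain, with the analysis defaults. The `seed`, when
#' given, overrides the phantom seed so one integer reproduces a full run.
#'
#' @param phantom a [phantom_config()].
#' @param segmentation a [segmentation_params()] (defaults to the phantom's
#'   dialect).
#' @param composition a [composition_params()].
#' @param k neighbours for the k-NN statistics.
#' @param af_threshold AF cut-off for the tissue mask.
#' @param tissue_closing_um closing radius for tissue mask / lumens.
#' @param region_axis explicit organ axis for regional assignment (the
#'   phantom's tissue box has no anatomical axis of its own); `NULL`
#'   disables regions.
#' @param seed integer master seed.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(phantom = phantom_config(),
                            segmentation = NULL,
                            composition = composition_params(),
                            k = 5,
                            af_threshold = 10,
                            tissue_closing_um = 50,
                            region_axis = c(1, 0, 0),
                            seed = NULL) {
  segmentation <- segmentation %||% segmentation_params(dialect = phantom$dialect)
  if (!is.null(seed)) phantom$seed <- as.integer(seed)
  structure(list(phantom = phantom, segmentation = segmentation,
                 composition = composition, k = k,
                 af_threshold = af_threshold,
                 tissue_closing_um = tissue_closing_um,
                 region_axis = region_axis,
                 seed = phantom$seed),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on a synthetic disc
#'
#' Chains phantom simulation, two-pass insulin segmentation, single-pass
#' glucagon segmentation, tissue-mask exclusion, islet-border merging,
#' morphometry, composition classification and size filters, thirds
#' partitioning, k-NN statistics, optional regional assignment, per-disc
#' density, and report building. Fixed seeds make the run (and the written
#' bundle) fully deterministic.
#'
#' @param config a [pipeline_config()].
#' @param out_dir if non-`NULL`, [write_report()] is called on the result.
#' @param keep_volumes retain the rendered grid and label volumes in the
#'   returned list (memory-heavy; default `FALSE`).
#' @return a list: `report` (an `islet_report`), `islets` (tibble),
#'   `truth` (the planted catalog), plus volumes if requested.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         keep_volumes = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- sample_islet_catalog(config$phantom)
  grid <- render_volume(truth, config$phantom)

  ins <- two_pass_segment(grid, "INS", config$segmentation)
  gcg_grid <- preprocess_channel(grid, "GCG", config$segmentation)
  gcg <- threshold_objects(gcg_grid, "GCG", config$segmentation$primary_threshold,
                           config$segmentation)
  rm(gcg_grid)
  ins <- exclude_outside_tissue(ins, grid, config$af_threshold,
                                config$tissue_closing_um)
  gcg <- exclude_outside_tissue(gcg, grid, config$af_threshold,
                                config$tissue_closing_um)

  border <- islet_border_objects(ins, gcg, config$composition)
  islets <- measure_objects(border$labels)
  islets <- dplyr::left_join(
    islets,
    dplyr::select(border$volumes, "id", "ins_volume_um3", "gcg_volume_um3"),
    by = "id")
  islets <- classify_islets(islets, config$composition)
  islets <- apply_size_filters(islets, config$composition)
  ledger <- attr(islets, "filter_ledger")

  if (nrow(islets) >= 3) islets <- partition_thirds(islets)
  knn <- if (nrow(islets) > config$k) {
    suppressWarnings(knn_distances(islets, k = config$k,
                                   by = if ("size_category" %in% names(islets))
                                     "size_category" else NULL))
  } else NULL
  if (!is.null(knn)) {
    all_knn <- dplyr::filter(knn, .data$to_category == "All")
    islets <- dplyr::left_join(
      islets, dplyr::select(all_knn, "id", mean_knn_um = "mean_knn_um"),
      by = "id")
  }

  mask <- tissue_mask(grid, config$af_threshold, config$tissue_closing_um)
  if (!is.null(config$region_axis) && nrow(islets) > 0) {
    islets <- assign_regions(islets, mask, grid$voxel_size,
                             region_scheme(axis = config$region_axis))
  }
  rm(mask)

  disc <- disc_density(grid, ins, config$af_threshold, config$tissue_closing_um)
  bins <- bin_histograms(islets, disc$tissue_volume_um3)
  spectrum <- composition_spectrum(islets, config$composition)

  cfg_json <- rapply(unclass(config), unclass, how = "replace")
  report <- build_report(disc, islets, config = c(cfg_json, list(filter_ledger = ledger)),
                         knn = knn, spectrum = spectrum, bins = bins)
  if (!is.null(out_dir)) write_report(report, out_dir)
  out <- list(report = report, islets = islets, truth = truth)
  if (keep_volumes) out <- c(out, list(grid = grid, ins = ins, gcg = gcg,
                                       border = border))
  invisible(out)
}
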