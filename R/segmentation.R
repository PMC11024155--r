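#' Segmentation parameters
#'
#' Tunables of the 3D surfacing pipeline: Gaussian smoothing, background
#' subtraction as a white top-hat (structures larger than
#' `background_structure_um` are treated as background; the scale parameter
#' is the ball diameter), strict intensity thresholds for the two-pass
#' method, the overlap-exclusion filter, and the small-object noise filter.
#'
#' Thresholds are explicit configuration rather than interactive tuning:
#' the primary threshold (default 5) segments high-intensity objects, the
#' secondary threshold (default half the primary) adds low-intensity objects
#' missed entirely by the first pass.
#'
#' @param dialect `"OPT"` or `"LSFM"`; sets scale defaults (background
#'   structure 158 vs 10 um; minimum object volume one voxel vs 3e3 um^3).
#' @param gaussian_sigma_um smoothing sigma in physical units (0 disables).
#' @param background_structure_um top-hat ball diameter in um; `Inf`
#'   degenerates to subtracting the global minimum.
#' @param primary_threshold,secondary_threshold strict (`>`) intensity
#'   cut-offs; secondary must be below primary.
#' @param overlap_exclusion_min_um3 minimum voxelised intersection volume at
#'   which a second-pass object is discarded as a duplicate of a first-pass
#'   object (default 10 um^3: sub-voxel at the OPT scale, so there any
#'   non-empty intersection triggers exclusion).
#' @param min_object_volume_um3 components smaller than this are removed.
#' @param connectivity 6, 18 or 26 (default 26, merging diagonal contact).
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(dialect = c("OPT", "LSFM"),
                                gaussian_sigma_um = NULL,
                                background_structure_um = NULL,
                                primary_threshold = 5,
                                secondary_threshold = NULL,
                                overlap_exclusion_min_um3 = 10,
                                min_object_volume_um3 = NULL,
                                connectivity = 26) {
  dialect <- match.arg(dialect)
  gaussian_sigma_um <- gaussian_sigma_um %||% (if (dialect == "OPT") 21 else 2)
  background_structure_um <- background_structure_um %||% (if (dialect == "OPT") 158 else 10)
  min_object_volume_um3 <- min_object_volume_um3 %||% (if (dialect == "OPT") 0 else 3e3)
  secondary_threshold <- secondary_threshold %||% (0.5 * primary_threshold)
  if (secondary_threshold >= primary_threshold)
    abort("`secondary_threshold` must be below `primary_threshold`")
  if (gaussian_sigma_um < 0 || background_structure_um <= 0 ||
      overlap_exclusion_min_um3 <= 0 || min_object_volume_um3 < 0)
    abort("physical parameters must be positive")
  if (!connectivity %in% c(6L, 18L, 26L))
    abort("`connectivity` must be 6, 18 or 26")
  structure(list(
    dialect = dialect,
    gaussian_sigma_um = gaussian_sigma_um,
    background_structure_um = background_structure_um,
    primary_threshold = primary_threshold,
    secondary_threshold = secondary_threshold,
    overlap_exclusion_min_um3 = overlap_exclusion_min_um3,
    min_object_volume_um3 = min_object_volume_um3,
    connectivity = as.integer(connectivity)
  ), class = "segmentation_params")
}

#' Smooth and background-subtract one channel
#'
#' Gaussian blur (sigma in physical units, converted per axis to voxels)
#' followed by background subtraction implemented as a white top-hat with a
#' ball structuring element of diameter `background_structure_um`. The
#' output is non-negative by construction.
#'
#' @param grid a [voxel_grid()].
#' @param channel channel name.
#' @param params a [segmentation_params()].
#' @return the grid with the channel replaced by its preprocessed version.
#' @export
preprocess_channel <- function(grid, channel, params) {
  img <- get_channel(grid, channel)
  storage.mode(img) <- "double"
  vox <- grid$voxel_size
  if (params$gaussian_sigma_um > 0)
    img <- cpp_gaussian3d(img, params$gaussian_sigma_um / vox)

  radius <- params$background_structure_um / 2
  if (is.infinite(radius) || all(floor(radius / vox) >= dim(img))) {
    # structuring element larger than the volume: nothing qualifies as
    # background, subtraction is the identity
  } else {
    ax <- c("z", "y", "x")[radius < vox]
    if (length(ax))
      abort(sprintf(
        "background structuring element smaller than one voxel along axis %s",
        paste(ax, collapse = ", ")))
    off <- ball_offsets(radius, vox)
    bg <- cpp_morph3d(cpp_morph3d(img, off, dilate = FALSE), off, dilate = TRUE)
    img <- img - bg
  }
  img[img < 0] <- 0
  dim(img) <- dim(grid$channels[[channel]])
  grid$channels[[channel]] <- img
  grid
}

#' Threshold a channel into labelled 3D objects
#'
#' Voxels strictly above the threshold form the foreground; connected
#' components under the configured connectivity become objects; components
#' below the minimum physical volume are removed and the rest relabelled
#' consecutively.
#'
#' @inheritParams preprocess_channel
#' @param threshold strict intensity cut-off.
#' @param provenance label provenance tag.
#' @return a [label_volume()].
#' @export
threshold_objects <- function(grid, channel, threshold, params,
                              provenance = "single_pass") {
  img <- get_channel(grid, channel)
  mask <- img > threshold
  storage.mode(mask) <- "integer"
  labels <- cpp_label3d(mask, params$connectivity)
  n <- attr(labels, "n_labels")
  if (n > 0 && params$min_object_volume_um3 > 0) {
    vv <- voxel_volume(grid$voxel_size)
    counts <- tabulate(labels[labels > 0L], nbins = n)
    keep <- counts * vv >= params$min_object_volume_um3
    labels <- relabel_keep(labels, keep)
  }
  label_volume(labels, grid$voxel_size, provenance = provenance)
}

#' Two-pass gradient-corrected segmentation
#'
#' Corrects for the staining intensity gradient across the imaged slab.
#' Pass 1 thresholds at the primary level and captures high-intensity
#' objects. Pass 2 thresholds at the secondary level; any pass-2 object
#' whose voxelised intersection with the pass-1 segmentation reaches
#' `overlap_exclusion_min_um3` is discarded as a duplicate. The result is
#' the union of the pass-1 mask and the surviving pass-2 objects,
#' relabelled. Dim objects missed entirely by pass 1 are thereby recovered;
#' the overlap filter prevents bright objects from being counted twice.
#'
#' @inheritParams preprocess_channel
#' @param preprocess apply [preprocess_channel()] first (default `TRUE`).
#' @return a [label_volume()] with provenance `"merged"`.
#' @export
two_pass_segment <- function(grid, channel, params, preprocess = TRUE) {
  if (preprocess) grid <- preprocess_channel(grid, channel, params)
  p1 <- threshold_objects(grid, channel, params$primary_threshold, params, "pass1")
  p2 <- threshold_objects(grid, channel, params$secondary_threshold, params, "pass2")
  vv <- voxel_volume(grid$voxel_size)
  keep2 <- logical(p2$n_labels)
  if (p2$n_labels > 0) {
    ov <- tabulate(p2$labels[p1$labels > 0L], nbins = p2$n_labels)
    keep2 <- ov * vv < params$overlap_exclusion_min_um3
  }
  surv2 <- relabel_keep(p2$labels, keep2)
  merged <- (p1$labels > 0L) | (surv2 > 0L)
  storage.mode(merged) <- "integer"
  labels <- cpp_label3d(merged, params$connectivity)
  label_volume(labels, grid$voxel_size, provenance = "merged")
}

#' Write / read a label volume as 32-bit TIFF
#'
#' Pages are z-planes; labels are stored as 32-bit floats (exact for label
#' counts below 2^24). Voxel size travels in a JSON sidecar next to the
#' TIFF.
#'
#' @param objects a [label_volume()].
#' @param path output `.tif` path; the sidecar is `<path>.json`.
#' @return `path` (`write_labels`), a [label_volume()] (`read_labels`).
#' @export
write_labels <- function(objects, path) {
  stopifnot(inherits(objects, "label_volume"))
  a <- objects$labels
  if (objects$n_labels >= 2^24) abort("too many labels for float32 storage")
  # power-of-two scaling into [0, 1]: exact in 32-bit floats
  pages <- lapply(seq_len(dim(a)[1]), function(z) {
    m <- a[z, , ]
    storage.mode(m) <- "double"
    m / 2^24
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(
    list(voxel_size_zyx_um = objects$voxel_size, n_labels = objects$n_labels,
         provenance = objects$provenance),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  a <- array(0L, dim = c(length(pages), dim(pages[[1]])))
  for (z in seq_along(pages)) a[z, , ] <- as.integer(round(pages[[z]] * 2^24))
  attr(a, "n_labels") <- as.integer(meta$n_labels)
  label_volume(a, meta$voxel_size_zyx_um, provenance = meta$provenance)
}

#' Tissue mask from the autofluorescence channel
#'
#' Largest connected component of `AF > af_threshold`, morphologically
#' closed so that vessel and duct lumens become internal to the mask.
#'
#' @param grid a [voxel_grid()] with an `AF` channel.
#' @param af_threshold strict intensity cut-off on the anatomy channel.
#' @param closing_um closing ball radius in um.
#' @return a logical 3D array.
#' @export
tissue_mask <- function(grid, af_threshold = 10, closing_um = 50) {
  af <- get_channel(grid, "AF")
  raw <- af > af_threshold
  storage.mode(raw) <- "integer"
  lab <- cpp_label3d(raw, 26L)
  n <- attr(lab, "n_labels")
  if (n == 0) abort("empty tissue mask: no AF voxels above threshold")
  counts <- tabulate(lab[lab > 0L], nbins = n)
  main <- array(lab == which.max(counts), dim = dim(af))
  binary_close(main, closing_um, grid$voxel_size)
}

#' Remove objects outside the tissue volume
#'
#' Objects whose centroid falls outside the (closed) tissue mask are
#' excluded; objects centred inside lumens are retained, since lumens are
#' internal to the mask after closing.
#'
#' @param objects a [label_volume()].
#' @param grid the originating [voxel_grid()] (for the `AF` channel).
#' @param af_threshold,closing_um see [tissue_mask()].
#' @return a [label_volume()] with the surviving objects relabelled.
#' @export
exclude_outside_tissue <- function(objects, grid, af_threshold = 10,
                                   closing_um = 50) {
  mask <- tissue_mask(grid, af_threshold, closing_um)
  n <- objects$n_labels
  if (n == 0) return(objects)
  st <- cpp_region_stats(objects$labels, n)
  iz <- pmin(pmax(round(st$sum_z / st$count), 0), dim(mask)[1] - 1) + 1
  iy <- pmin(pmax(round(st$sum_y / st$count), 0), dim(mask)[2] - 1) + 1
  ix <- pmin(pmax(round(st$sum_x / st$count), 0), dim(mask)[3] - 1) + 1
  keep <- mask[cbind(iz, iy, ix)]
  labels <- relabel_keep(objects$labels, keep)
  label_volume(labels, objects$voxel_size, provenance = objects$provenance)
}
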