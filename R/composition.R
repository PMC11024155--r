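#' Composition parameters
#'
#' Tunables of the endocrine composition analysis: the negativity rule
#' (a hormone is called negative when its share of the islet's
#' immunolabelled volume is below 1%), the noise and single-cell volume
#' filters (3e3 um^3 and 1.4e4 um^3, the latter a ~29 um sphere), the
#' islet-border closing scale, and the glucagon-fraction bin edges used for
#' the composition spectrum.
#'
#' @param negativity_threshold fraction below which a hormone is negative.
#' @param noise_min_volume_um3 objects below this are treated as noise.
#' @param single_cell_min_volume_um3 islets strictly below this are
#'   excluded as single cells.
#' @param border_smoothing_um closing ball radius used when merging INS and
#'   GCG masks into islet-border objects.
#' @param gcg_fraction_bins ordered bin edges on `[0, 1]`.
#' @return an object of class `composition_params`.
#' @export
composition_params <- function(negativity_threshold = 0.01,
                               noise_min_volume_um3 = 3e3,
                               single_cell_min_volume_um3 = 1.4e4,
                               border_smoothing_um = 3.78,
                               gcg_fraction_bins = c(0, 0.01, 0.10, 0.20, 0.30, 1)) {
  if (negativity_threshold <= 0 || negativity_threshold >= 1)
    abort("`negativity_threshold` must be in (0, 1)")
  if (any(diff(gcg_fraction_bins) <= 0) || gcg_fraction_bins[1] != 0 ||
      gcg_fraction_bins[length(gcg_fraction_bins)] != 1)
    abort("`gcg_fraction_bins` must be strictly increasing edges spanning [0, 1]")
  structure(list(
    negativity_threshold = negativity_threshold,
    noise_min_volume_um3 = noise_min_volume_um3,
    single_cell_min_volume_um3 = single_cell_min_volume_um3,
    border_smoothing_um = border_smoothing_um,
    gcg_fraction_bins = gcg_fraction_bins
  ), class = "composition_params")
}

#' Merge INS and GCG segmentations into islet-border objects
#'
#' An islet is a connected component of the union of the insulin-positive
#' and glucagon-positive masks after morphological closing at the
#' border-smoothing scale (the closing glues hormone domains separated by
#' less than that scale; it does not inflate the reported volumes, which
#' are counted on the original masks). Each islet carries its constituent
#' INS and GCG voxel volumes.
#'
#' @param ins,gcg [label_volume()]s sharing geometry.
#' @param params a [composition_params()].
#' @return a list of class `islet_border`: `labels` (a [label_volume()])
#'   and `volumes`, a tibble with `id`, `volume_um3` (union),
#'   `ins_volume_um3`, `gcg_volume_um3`.
#' @export
islet_border_objects <- function(ins, gcg, params = composition_params()) {
  if (!identical(dim(ins$labels), dim(gcg$labels)) ||
      !isTRUE(all.equal(ins$voxel_size, gcg$voxel_size)))
    abort("INS and GCG label volumes must share geometry")
  vox <- ins$voxel_size
  union <- ins$labels > 0L | gcg$labels > 0L
  closed <- binary_close(union, params$border_smoothing_um, vox)
  storage.mode(closed) <- "integer"
  labels <- cpp_label3d(closed, 26L)
  n <- attr(labels, "n_labels")
  vv <- voxel_volume(vox)
  ins_v <- tabulate(labels[ins$labels > 0L], nbins = n) * vv
  gcg_v <- tabulate(labels[gcg$labels > 0L], nbins = n) * vv
  uni_v <- tabulate(labels[union], nbins = n) * vv
  volumes <- tibble(id = seq_len(n),
                    volume_um3 = uni_v,
                    ins_volume_um3 = ins_v,
                    gcg_volume_um3 = gcg_v)
  list(labels = label_volume(labels, vox, provenance = "islet_border"),
       volumes = volumes) |>
    structure(class = "islet_border")
}

#' Classify islet hormonal composition
#'
#' Adds the glucagon volume fraction
#' `f_gcg = gcg_volume / (ins_volume + gcg_volume)` and the composition
#' class: `INS+GCG-` when `f_gcg` is below the negativity threshold,
#' `INS-GCG+` when the insulin fraction is, `INS+GCG+` otherwise.
#'
#' @param data a data frame with `ins_volume_um3` and `gcg_volume_um3`.
#' @param params a [composition_params()].
#' @return the data as a tibble with `f_gcg` and `comp_class` added.
#' @export
classify_islets <- function(data, params = composition_params()) {
  data <- as_tibble(data)
  tot <- data$ins_volume_um3 + data$gcg_volume_um3
  if (any(tot <= 0)) abort("islet with zero INS and GCG volume cannot be classified")
  f_gcg <- data$gcg_volume_um3 / tot
  thr <- params$negativity_threshold
  data$f_gcg <- f_gcg
  data$comp_class <- classify_from_fraction(f_gcg, thr)
  data
}

#' Apply the noise and single-cell volume filters
#'
#' Removes objects below the noise floor (normally already removed at
#' segmentation) and islets strictly below the single-cell volume (default
#' 1.4e4 um^3, a ~29 um sphere). A ledger of removals per filter is
#' attached as attribute `filter_ledger`.
#'
#' @param data a data frame with `volume_um3`.
#' @param params a [composition_params()].
#' @return the surviving rows, with attribute `filter_ledger`.
#' @export
apply_size_filters <- function(data, params = composition_params()) {
  data <- as_tibble(data)
  noise <- data$volume_um3 < params$noise_min_volume_um3
  single <- !noise & data$volume_um3 < params$single_cell_min_volume_um3
  out <- data[!(noise | single), , drop = FALSE]
  attr(out, "filter_ledger") <- tibble(
    filter = c("noise_min_volume", "single_cell_min_volume"),
    threshold_um3 = c(params$noise_min_volume_um3, params$single_cell_min_volume_um3),
    n_removed = c(sum(noise), sum(single))
  )
  out
}

#' Composition spectrum
#'
#' Summarises classified islets per glucagon-fraction bin and per size bin:
#' islet count fraction, volume fraction (normalised to total islet
#' volume), and the mean INS:GCG volume ratio (over islets with non-zero
#' GCG). Fractions sum to 1 over the bins of each type.
#'
#' @param data classified islets (needs `f_gcg`, `volume_um3`,
#'   `ins_volume_um3`, `gcg_volume_um3`).
#' @param params a [composition_params()].
#' @param size_bin_edges volume bin edges in um^3 (default
#'   [islet_size_bins()]).
#' @return a tibble of class `composition_spectrum` with columns
#'   `bin_type`, `bin`, `bin_lo`, `bin_hi`, `n`, `count_fraction`,
#'   `volume_fraction`, `mean_ins_gcg_ratio`.
#' @export
composition_spectrum <- function(data, params = composition_params(),
                                 size_bin_edges = islet_size_bins()) {
  data <- as_tibble(data)
  schema <- tibble(bin_type = character(), bin = character(),
                   bin_lo = numeric(), bin_hi = numeric(), n = integer(),
                   count_fraction = numeric(), volume_fraction = numeric(),
                   mean_ins_gcg_ratio = numeric())
  if (nrow(data) == 0)
    return(structure(schema, class = c("composition_spectrum", class(schema))))

  one_axis <- function(values, edges, type) {
    # right-open bins, except the last which is closed at 1 / Inf
    idx <- findInterval(values, edges, rightmost.closed = TRUE)
    idx[idx < 1] <- 1L
    idx[idx > length(edges) - 1] <- length(edges) - 1L
    purrr::map_dfr(seq_len(length(edges) - 1L), function(b) {
      in_bin <- idx == b
      ratio <- data$ins_volume_um3[in_bin] / data$gcg_volume_um3[in_bin]
      ratio <- ratio[is.finite(ratio)]
      tibble(
        bin_type = type,
        bin = sprintf("[%.3g, %.3g%s", edges[b], edges[b + 1],
                      if (b == length(edges) - 1L) "]" else ")"),
        bin_lo = edges[b], bin_hi = edges[b + 1],
        n = sum(in_bin),
        count_fraction = sum(in_bin) / nrow(data),
        volume_fraction = sum(data$volume_um3[in_bin]) / sum(data$volume_um3),
        mean_ins_gcg_ratio = if (length(ratio)) mean(ratio) else NA_real_
      )
    })
  }
  out <- dplyr::bind_rows(
    one_axis(data$f_gcg, params$gcg_fraction_bins, "gcg_fraction"),
    one_axis(data$volume_um3, size_bin_edges, "size")
  )
  structure(out, class = c("composition_spectrum", class(out)))
}
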