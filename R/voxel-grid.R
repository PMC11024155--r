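#' Multi-channel 3D intensity volume
#'
#' The unit of work for one imaged tissue disc or region of interest. Arrays
#' are indexed `[z, y, x]`; voxel sizes are physical edge lengths in
#' micrometres, ordered `(z, y, x)` so that both the isotropic optical
#' projection tomography dialect (~21 um) and the anisotropic light sheet
#' dialect (e.g. 5 x 1.9 x 1.9 um) are handled without resampling.
#'
#' @param channels named list of 3D numeric arrays with identical dimensions;
#'   conventional names are `"INS"` (insulin), `"GCG"` (glucagon) and `"AF"`
#'   (tissue autofluorescence / anatomy).
#' @param voxel_size numeric length-3, micrometres per voxel along `(z, y, x)`.
#' @param origin physical offset of the volume in micrometres, `(x, y, z)`.
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(channels, voxel_size, origin = c(0, 0, 0)) {
  if (!is.list(channels) || is.null(names(channels)) || any(names(channels) == ""))
    abort("`channels` must be a named list of 3D arrays")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    abort("every channel must be a 3D array")
  if (length(unique(lapply(dims, as.integer))) != 1L)
    abort("all channels must share the same dimensions")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    abort("`voxel_size` must be three strictly positive values (z, y, x)")
  for (ch in names(channels)) {
    if (min(channels[[ch]]) < 0)
      abort(sprintf("channel '%s' contains negative intensities", ch))
  }
  structure(
    list(channels = channels, voxel_size = voxel_size, origin = as.numeric(origin)),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf(
    "<voxel_grid> %d x %d x %d voxels (z,y,x), %.3g x %.3g x %.3g um, channels: %s\n",
    d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
    paste(names(x$channels), collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$channels[[1]])

get_channel <- function(grid, channel) {
  if (!channel %in% names(grid$channels))
    abort(sprintf("channel '%s' not present (have: %s)", channel,
                  paste(names(grid$channels), collapse = ", ")))
  grid$channels[[channel]]
}

#' Integer-labelled 3D segmentation
#'
#' @param labels 3D integer array, 0 = background, objects labelled with
#'   consecutive positive integers.
#' @param voxel_size micrometres per voxel `(z, y, x)`.
#' @param provenance which stage produced the labels: one of `"pass1"`,
#'   `"pass2"`, `"merged"`, `"islet_border"`, `"single_pass"`.
#' @return an object of class `label_volume`.
#' @export
label_volume <- function(labels, voxel_size,
                         provenance = c("single_pass", "pass1", "pass2",
                                        "merged", "islet_border")) {
  provenance <- match.arg(provenance)
  if (length(dim(labels)) != 3L) abort("`labels` must be a 3D array")
  storage.mode(labels) <- "integer"
  n <- attr(labels, "n_labels") %||% (if (length(labels)) max(labels) else 0L)
  structure(
    list(labels = labels, voxel_size = as.numeric(voxel_size),
         n_labels = as.integer(n), provenance = provenance),
    class = "label_volume"
  )
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume> %d object(s) in %d x %d x %d voxels (%s)\n",
              x$n_labels, d[1], d[2], d[3], x$provenance))
  invisible(x)
}

#' @export
dim.label_volume <- function(x) dim(x$labels)
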