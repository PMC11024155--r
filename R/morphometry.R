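#' Equivalent-sphere diameter
#'
#' Diameter of the sphere with the object's volume, `(6 V / pi)^(1/3)`.
#' This is the quantity that maps the volumetric size categories onto the
#' diameters reported by 2D stereological studies (e.g. 400e3 um^3 ~ 91 um,
#' 12,800e3 um^3 ~ 290 um).
#'
#' @param volume_um3 volume(s) in um^3, strictly positive.
#' @return diameter(s) in um.
#' @export
eq_sphere_diameter <- function(volume_um3) {
  if (any(!is.finite(volume_um3)) || any(volume_um3 <= 0))
    abort("`volume_um3` must be strictly positive")
  (6 * volume_um3 / pi)^(1 / 3)
}

#' Mean 3D diameter
#'
#' Arithmetic mean of the object's diameters along the X, Y and Z axes
#' (axis-aligned bounding extents, the export convention of commercial
#' surfacing software).
#'
#' @param extent_x_um,extent_y_um,extent_z_um axis extents in um.
#' @return mean diameter(s) in um.
#' @export
mean_3d_diameter <- function(extent_x_um, extent_y_um, extent_z_um) {
  if (any(c(extent_x_um, extent_y_um, extent_z_um) <= 0))
    abort("extents must be positive")
  (extent_x_um + extent_y_um + extent_z_um) / 3
}

#' Sphericity
#'
#' `Psi = pi^(1/3) (6 V)^(2/3) / A`; 1 for a perfect sphere. Surface areas
#' should come from a smoothed iso-surface mesh (see [measure_objects()]);
#' raw voxel face counting overestimates A by ~50% and would bias Psi.
#'
#' @param volume_um3 volume in um^3.
#' @param surface_area_um2 surface area in um^2.
#' @return dimensionless sphericity.
#' @export
sphericity <- function(volume_um3, surface_area_um2) {
  if (any(volume_um3 <= 0) || any(surface_area_um2 <= 0))
    abort("volume and surface area must be strictly positive")
  pi^(1 / 3) * (6 * volume_um3)^(2 / 3) / surface_area_um2
}

#' Tissue shrinkage correction
#'
#' Fixed-to-cleared tissue shrinkage (~5% in linear dimension) can be
#' compensated by scaling lengths by `(1 + s)` and volumes by `(1 + s)^3`
#' (65 um -> 68.25 um at s = 0.05). The correction is off by default
#' throughout the pipeline; measured values are reported uncorrected.
#'
#' @param x measurement(s) to correct.
#' @param s linear shrinkage fraction in `[0, 1)`, default 0.05.
#' @param dimension `"length"` or `"volume"`.
#' @return corrected value(s).
#' @export
shrinkage_correct <- function(x, s = 0.05, dimension = c("length", "volume")) {
  dimension <- match.arg(dimension)
  if (s < 0 || s >= 1) abort("`s` must be in [0, 1)")
  if (dimension == "length") x * (1 + s) else x * (1 + s)^3
}

# smoothed iso-surface mesh (area, enclosed volume) of one object; the
# label array is cropped to the object's bounding box plus a zero shell so
# the mesh is closed; if smoothing dissolves a tiny object below the iso
# level, the unsmoothed binary mesh is used instead
object_surface_mesh <- function(labels, lab, bbox, voxel_size, smooth_sigma_vox = 1) {
  pad <- 2L
  d <- dim(labels)
  z <- max(1L, bbox$z0 - pad):min(d[1], bbox$z1 + pad)
  y <- max(1L, bbox$y0 - pad):min(d[2], bbox$y1 + pad)
  x <- max(1L, bbox$x0 - pad):min(d[3], bbox$x1 + pad)
  sub <- labels[z, y, x, drop = FALSE] == lab
  full <- array(0, dim = dim(sub) + 2L * pad)
  full[pad + seq_len(dim(sub)[1]), pad + seq_len(dim(sub)[2]),
       pad + seq_len(dim(sub)[3])] <- sub
  if (smooth_sigma_vox > 0) {
    m <- cpp_mesh_area(cpp_gaussian3d(full, rep(smooth_sigma_vox, 3)), 0.5, voxel_size)
    if (m$area > 0) return(m)
  }
  cpp_mesh_area(full, 0.5, voxel_size)
}

#' Per-object morphometry
#'
#' Measures every labelled object: voxel-count volume, unweighted centre of
#' mass (um), axis-aligned extents, equivalent-sphere diameter, mean 3D
#' diameter, and (optionally) iso-surface area and sphericity from a
#' marching-tetrahedra mesh of the Gaussian-smoothed binary mask at the 0.5
#' level.
#'
#' @param objects a [label_volume()].
#' @param compute_surface compute surface area and sphericity (default
#'   `TRUE`; the mesh pass is the only expensive step).
#' @param smooth_sigma_vox smoothing applied to the binary mask before
#'   meshing, in voxels.
#' @return a tibble with one row per object: `id`, `n_voxels`,
#'   `volume_um3`, `x_um`, `y_um`, `z_um`, `extent_x_um`, `extent_y_um`,
#'   `extent_z_um`, `eq_diameter_um`, `mean_3d_diameter_um`, and if
#'   requested `surface_area_um2`, `sphericity`.
#' @export
measure_objects <- function(objects, compute_surface = TRUE,
                            smooth_sigma_vox = 1) {
  stopifnot(inherits(objects, "label_volume"))
  vox <- objects$voxel_size
  n <- objects$n_labels
  if (n == 0) {
    return(tibble(
      id = integer(), n_voxels = numeric(), volume_um3 = numeric(),
      x_um = numeric(), y_um = numeric(), z_um = numeric(),
      extent_x_um = numeric(), extent_y_um = numeric(), extent_z_um = numeric(),
      eq_diameter_um = numeric(), mean_3d_diameter_um = numeric(),
      surface_area_um2 = numeric(), sphericity = numeric()
    ))
  }
  st <- cpp_region_stats(objects$labels, n)
  empty <- st$count == 0
  if (any(empty)) inform(sprintf("skipping %d empty label(s)", sum(empty)))
  vv <- voxel_volume(vox)
  out <- tibble(
    id = seq_len(n),
    n_voxels = st$count,
    volume_um3 = st$count * vv,
    x_um = (st$sum_x / st$count + 0.5) * vox[3],
    y_um = (st$sum_y / st$count + 0.5) * vox[2],
    z_um = (st$sum_z / st$count + 0.5) * vox[1],
    extent_x_um = (st$x1 - st$x0 + 1) * vox[3],
    extent_y_um = (st$y1 - st$y0 + 1) * vox[2],
    extent_z_um = (st$z1 - st$z0 + 1) * vox[1]
  )
  out <- out[!empty, , drop = FALSE]
  out$eq_diameter_um <- eq_sphere_diameter(out$volume_um3)
  out$mean_3d_diameter_um <- mean_3d_diameter(out$extent_x_um, out$extent_y_um,
                                              out$extent_z_um)
  if (compute_surface) {
    mesh <- vapply(out$id, function(lab) {
      i <- lab
      m <- object_surface_mesh(
        objects$labels, lab,
        list(z0 = st$z0[i] + 1L, z1 = st$z1[i] + 1L,
             y0 = st$y0[i] + 1L, y1 = st$y1[i] + 1L,
             x0 = st$x0[i] + 1L, x1 = st$x1[i] + 1L),
        vox, smooth_sigma_vox)
      c(m$area, m$volume)
    }, numeric(2))
    if (any(mesh[1, ] <= 0) || any(mesh[2, ] <= 0))
      abort("degenerate iso-surface mesh for at least one object")
    out$surface_area_um2 <- mesh[1, ]
    # sphericity from the mesh's own enclosed volume, so that the area and
    # volume entering Psi describe the same smoothed surface
    out$sphericity <- sphericity(mesh[2, ], mesh[1, ])
  }
  out
}
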