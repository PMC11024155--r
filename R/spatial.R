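#' Default geometric size-bin edges
#'
#' Factor-2 geometric volume bin edges (um^3) spanning and extending the
#' 400e3 - 12,800e3 um^3 range that holds ~75% of the beta-cell mass, with
#' a closed bottom at 0 and an open-ended top bin.
#'
#' @return numeric vector of bin edges in um^3.
#' @export
islet_size_bins <- function() {
  c(0, c(25, 50, 100, 200, 400, 800, 1600, 3200, 6400, 12800, 25600) * 1e3, Inf)
}

#' Partition islets into thirds-of-total-volume size categories
#'
#' Islets are sorted by ascending volume; the small (S), medium (M) and
#' large (L) categories each hold one third of the total labelled volume.
#' An islet straddling a cumulative boundary goes to the lower category, so
#' each category's summed volume is within one islet's volume of total/3.
#'
#' @param data a data frame with `volume_um3` (>= 3 rows).
#' @return the data with a `size_category` factor (`S`, `M`, `L`) added.
#' @export
partition_thirds <- function(data) {
  data <- as_tibble(data)
  if (nrow(data) < 3) abort("at least 3 islets are required for thirds partitioning")
  ord <- order(data$volume_um3)
  v <- data$volume_um3[ord]
  prev <- cumsum(v) - v  # cumulative volume before each islet
  total <- sum(v)
  cat_sorted <- ifelse(prev < total / 3, "S",
                       ifelse(prev < 2 * total / 3, "M", "L"))
  out <- character(nrow(data))
  out[ord] <- cat_sorted
  data$size_category <- factor(out, levels = c("S", "M", "L"))
  data
}

#' Fixed size-bin histograms
#'
#' Per volume bin: labelled volume density (bin volume / tissue volume),
#' volume fraction of the total labelled volume, object count per mm^3 of
#' tissue, and object count fraction. Fractions each sum to 1.
#'
#' @param data a data frame with `volume_um3`.
#' @param tissue_volume_um3 tissue volume (lumens excluded), um^3.
#' @param bin_edges volume bin edges in um^3.
#' @return a tibble of class `islet_bins`.
#' @export
bin_histograms <- function(data, tissue_volume_um3, bin_edges = islet_size_bins()) {
  if (!is.numeric(tissue_volume_um3) || tissue_volume_um3 <= 0)
    abort("`tissue_volume_um3` must be strictly positive")
  data <- as_tibble(data)
  idx <- findInterval(data$volume_um3, bin_edges, rightmost.closed = TRUE)
  idx[idx < 1] <- 1L
  idx[idx > length(bin_edges) - 1] <- length(bin_edges) - 1L
  n_tot <- nrow(data)
  v_tot <- sum(data$volume_um3)
  out <- purrr::map_dfr(seq_len(length(bin_edges) - 1L), function(b) {
    in_bin <- idx == b
    v_bin <- sum(data$volume_um3[in_bin])
    tibble(
      bin_lo_um3 = bin_edges[b], bin_hi_um3 = bin_edges[b + 1],
      eq_diameter_lo_um = if (bin_edges[b] > 0) eq_sphere_diameter(bin_edges[b]) else 0,
      eq_diameter_hi_um = if (is.finite(bin_edges[b + 1]))
        eq_sphere_diameter(bin_edges[b + 1]) else Inf,
      n = sum(in_bin),
      count_fraction = if (n_tot > 0) sum(in_bin) / n_tot else 0,
      count_per_mm3 = sum(in_bin) / (tissue_volume_um3 / 1e9),
      volume_um3 = v_bin,
      volume_fraction = if (v_tot > 0) v_bin / v_tot else 0,
      volume_density = v_bin / tissue_volume_um3
    )
  })
  structure(out, class = c("islet_bins", class(out)),
            tissue_volume_um3 = tissue_volume_um3)
}

#' k-nearest-neighbour centroid distances
#'
#' Euclidean centre-of-mass distances in physical um, via a k-d tree. For
#' every islet and every target group (its own category, each other
#' category, and `"All"`), the mean distance to the k nearest islets of
#' that group is reported (self excluded where applicable). Between-group
#' distances are directional (A to B differs from B to A). Groups with too
#' few members (<= k available neighbours) are flagged `NA` with a warning.
#'
#' @param data a data frame with `x_um`, `y_um`, `z_um` and (optionally)
#'   the grouping column.
#' @param k number of neighbours (default 5).
#' @param by name of the grouping column, usually `"size_category"`; `NULL`
#'   computes only the ungrouped `"All"` distances.
#' @return a tibble of class `islet_knn`: `id`, `from_category`,
#'   `to_category`, `mean_knn_um` (one row per islet per target group).
#' @export
knn_distances <- function(data, k = 5, by = "size_category") {
  data <- as_tibble(data)
  pts <- as.matrix(data[, c("x_um", "y_um", "z_um")])
  storage.mode(pts) <- "double"
  n <- nrow(pts)
  id <- data$id %||% seq_len(n)
  groups <- if (!is.null(by)) {
    if (!by %in% names(data)) abort(sprintf("grouping column '%s' not found", by))
    as.character(data[[by]])
  } else rep("All", n)
  targets <- unique(groups)
  if (!is.null(by)) targets <- c(targets, "All")
  from <- if (!is.null(by)) groups else rep("All", n)

  res <- purrr::map_dfr(unique(targets), function(tg) {
    sel <- if (tg == "All") rep(TRUE, n) else groups == tg
    ref <- pts[sel, , drop = FALSE]
    ref_ids <- which(sel)
    self_idx <- match(seq_len(n), ref_ids)  # NA when the query is not in ref
    avail <- nrow(ref) - !is.na(self_idx)
    if (any(avail < k))
      warn(sprintf("group '%s': %d islet(s) have fewer than k = %d neighbours; flagged NA",
                   tg, sum(avail < k), k))
    mean_d <- rep(NA_real_, n)
    ok <- avail >= k
    if (any(ok)) {
      d <- cpp_knn(ref, pts[ok, , drop = FALSE],
                   as.integer(ifelse(is.na(self_idx[ok]), 0L, self_idx[ok])), as.integer(k))
      mean_d[ok] <- rowMeans(d)
    }
    tibble(id = id, from_category = from, to_category = tg, mean_knn_um = mean_d)
  })
  structure(res, class = c("islet_knn", class(res)), k = k)
}

#' Summarise k-NN distances per category pair
#'
#' @param knn a tibble from [knn_distances()].
#' @return a tibble with `from_category`, `to_category`, `n`,
#'   `mean_um`, `sem_um`.
#' @export
knn_summary <- function(knn) {
  dplyr::group_by(as_tibble(knn), .data$from_category, .data$to_category) |>
    dplyr::summarise(
      n = sum(!is.na(.data$mean_knn_um)),
      mean_um = mean(.data$mean_knn_um, na.rm = TRUE),
      sem_um = sd(.data$mean_knn_um, na.rm = TRUE) /
        sqrt(pmax(1, sum(!is.na(.data$mean_knn_um)))),
      .groups = "drop"
    )
}

#' Region scheme for head-to-tail assignment
#'
#' Region 1 (the head) occupies `head_boundary_fraction` of the organ axis
#' (a configurable stand-in for the anatomical vein landmark); the
#' remainder is split into three equal-length regions 2-4.
#'
#' @param n_regions number of regions (fixed at 4).
#' @param head_boundary_fraction fraction of axis length forming region 1.
#' @param axis optional explicit unit axis `(x, y, z)`; when `NULL` the
#'   first principal component of the tissue mask is used.
#' @return an object of class `region_scheme`.
#' @export
region_scheme <- function(n_regions = 4, head_boundary_fraction = 0.30, axis = NULL) {
  if (head_boundary_fraction <= 0 || head_boundary_fraction >= 1)
    abort("`head_boundary_fraction` must be in (0, 1)")
  if (n_regions != 4) abort("the regional scheme is defined for 4 regions")
  if (!is.null(axis)) axis <- axis / sqrt(sum(axis^2))
  structure(list(n_regions = 4L, head_boundary_fraction = head_boundary_fraction,
                 axis = axis), class = "region_scheme")
}

#' Assign head-to-tail regions
#'
#' Projects islet centroids onto the organ axis (first principal component
#' of the tissue-mask voxel coordinates, or an explicit axis) and assigns
#' region 1 below the head boundary and regions 2-4 as equal-length splits
#' of the remainder.
#'
#' @param data a data frame with `x_um`, `y_um`, `z_um`.
#' @param mask logical 3D tissue mask (see [tissue_mask()]).
#' @param voxel_size um per voxel `(z, y, x)`.
#' @param scheme a [region_scheme()].
#' @return the data with an integer `region` column added.
#' @export
assign_regions <- function(data, mask, voxel_size, scheme = region_scheme()) {
  data <- as_tibble(data)
  if (!any(mask)) abort("tissue mask is empty")
  idx <- which(mask, arr.ind = TRUE)  # (z, y, x) indices
  coords <- cbind(x = (idx[, 3] - 0.5) * voxel_size[3],
                  y = (idx[, 2] - 0.5) * voxel_size[2],
                  z = (idx[, 1] - 0.5) * voxel_size[1])
  if (is.null(scheme$axis)) {
    samp <- coords[seq(1, nrow(coords), length.out = min(nrow(coords), 5e4)), , drop = FALSE]
    pc <- prcomp(samp, center = TRUE, scale. = FALSE)
    if (pc$sdev[1] / pc$sdev[2] < 1.05)
      abort(paste("tissue mask is near-isotropic; no unambiguous organ axis -",
                  "supply region_scheme(axis = ...) explicitly"))
    axis <- pc$rotation[, 1]
    if (axis[which.max(abs(axis))] < 0) axis <- -axis  # deterministic sign
  } else axis <- scheme$axis
  proj_mask <- as.numeric(coords %*% axis)
  lo <- min(proj_mask); hi <- max(proj_mask)
  f <- (as.matrix(data[, c("x_um", "y_um", "z_um")]) %*% axis - lo) / (hi - lo)
  f <- pmin(pmax(as.numeric(f), 0), 1 - 1e-12)
  hb <- scheme$head_boundary_fraction
  region <- ifelse(f < hb, 1L, 2L + pmin(2L, as.integer(floor((f - hb) / ((1 - hb) / 3)))))
  data$region <- as.integer(region)
  data
}
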