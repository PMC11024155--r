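#' Phantom configuration
#'
#' Parameters of the synthetic pancreatic-tissue generator. The phantom
#' emulates the statistical structure the downstream analysis assumes:
#' a right-skewed islet size law (log-normal on equivalent diameter,
#' truncated to ~30-300 um), a subpopulation of glucagon-negative islets
#' concentrated below a volume pivot, a core-to-rim staining intensity
#' gradient within each islet, an optional depth-dependent dimming of whole
#' islets (emulating antibody penetration across the slab), background
#' autofluorescence with zero-signal vessel lumens, and additive Gaussian
#' noise.
#'
#' @param dialect `"OPT"` (isotropic 21 um voxels) or `"LSFM"`
#'   (5 x 1.9 x 1.9 um voxels); sets grid/voxel/count defaults.
#' @param grid_shape voxels along `(z, y, x)`.
#' @param voxel_size um per voxel along `(z, y, x)`.
#' @param n_islets number of islets to plant.
#' @param size_median_um,size_gsd log-normal median equivalent diameter (um)
#'   and geometric standard deviation.
#' @param diameter_range_um truncation bounds on equivalent diameter (um).
#' @param gcg_neg_fraction_small,gcg_neg_fraction_large probability that an
#'   islet below / above `gcg_neg_pivot_um3` is glucagon-negative
#'   (glucagon fraction < 1%).
#' @param gcg_neg_pivot_um3 volume pivot separating "small" from "large".
#' @param gcg_fraction_shape Beta shape parameters for the glucagon volume
#'   fraction of mixed islets (truncated to `[0.01, 0.99]`).
#' @param gcg_cell_diameter_um diameter range of planted alpha-cell spheres.
#' @param gcg_placement `"intermingled"` (uniform within the islet; human
#'   islets are non-mantled) or `"mantle"` (peripheral shell).
#' @param axis_ratio_range bounds for the ellipsoid semi-axis scale factors
#'   (volume-preserving), controlling sphericity < 1.
#' @param gradient_floor core-to-rim intensity ratio in `[0, 1]`; 1 gives a
#'   flat profile.
#' @param intensity_depth_factor per-islet peak dimming with fractional z
#'   depth: peak scales by `1 - f * depth`; 0 disables.
#' @param peak_intensity rim intensity of an undimmed islet.
#' @param noise_sd additive Gaussian noise, intensity units.
#' @param n_vessels number of zero-lumen tubes carved into the anatomy
#'   channel.
#' @param vessel_radius_um lumen radius.
#' @param background_level anatomy-channel intensity inside the tissue mask.
#' @param margin_um empty border between the tissue mask and the grid edge.
#' @param min_separation_um minimum surface-to-surface clearance (via
#'   bounding-sphere surrogates) between planted islets.
#' @param max_place_attempts rejection-sampling attempts per islet before
#'   placement is declared failed.
#' @param seed integer; fully determines catalog and rendered volume.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(dialect = c("OPT", "LSFM"),
                           grid_shape = NULL,
                           voxel_size = NULL,
                           n_islets = NULL,
                           size_median_um = 65,
                           size_gsd = 1.6,
                           diameter_range_um = c(30, 300),
                           gcg_neg_fraction_small = 0.55,
                           gcg_neg_fraction_large = 0.10,
                           gcg_neg_pivot_um3 = 800e3,
                           gcg_fraction_shape = c(2, 12),
                           gcg_cell_diameter_um = c(10, 15),
                           gcg_placement = c("intermingled", "mantle"),
                           axis_ratio_range = c(1, 1.6),
                           gradient_floor = 0.3,
                           intensity_depth_factor = 0,
                           peak_intensity = 100,
                           noise_sd = 2,
                           n_vessels = 2,
                           vessel_radius_um = 40,
                           background_level = 20,
                           margin_um = 42,
                           min_separation_um = 25,
                           max_place_attempts = 500,
                           seed = 1L) {
  dialect <- match.arg(dialect)
  gcg_placement <- match.arg(gcg_placement)
  if (dialect == "OPT") {
    grid_shape <- grid_shape %||% c(128, 128, 128)
    voxel_size <- voxel_size %||% c(21, 21, 21)
    n_islets   <- n_islets %||% 80L
  } else {
    grid_shape <- grid_shape %||% c(160, 448, 448)
    voxel_size <- voxel_size %||% c(5, 1.9, 1.9)
    n_islets   <- n_islets %||% 125L
  }
  assert_prob(gcg_neg_fraction_small, "gcg_neg_fraction_small")
  assert_prob(gcg_neg_fraction_large, "gcg_neg_fraction_large")
  assert_prob(gradient_floor, "gradient_floor")
  assert_prob(intensity_depth_factor, "intensity_depth_factor")
  if (size_median_um <= 2 * max(voxel_size))
    abort("size_dist median must exceed twice the largest voxel dimension")
  if (size_gsd <= 1) abort("`size_gsd` must be > 1")
  if (length(diameter_range_um) != 2 || diff(diameter_range_um) <= 0)
    abort("`diameter_range_um` must be an increasing pair")
  if (length(axis_ratio_range) != 2 || axis_ratio_range[1] < 1 ||
      diff(axis_ratio_range) < 0)
    abort("`axis_ratio_range` must be increasing with lower bound >= 1")
  if (noise_sd < 0 || peak_intensity <= 0 || background_level < 0)
    abort("intensity parameters must be non-negative (peak strictly positive)")
  cfg <- list(
    dialect = dialect, grid_shape = as.integer(grid_shape),
    voxel_size = as.numeric(voxel_size), n_islets = as.integer(n_islets),
    size_median_um = size_median_um, size_gsd = size_gsd,
    diameter_range_um = diameter_range_um,
    gcg_neg_fraction_small = gcg_neg_fraction_small,
    gcg_neg_fraction_large = gcg_neg_fraction_large,
    gcg_neg_pivot_um3 = gcg_neg_pivot_um3,
    gcg_fraction_shape = gcg_fraction_shape,
    gcg_cell_diameter_um = gcg_cell_diameter_um,
    gcg_placement = gcg_placement,
    axis_ratio_range = axis_ratio_range,
    gradient_floor = gradient_floor,
    intensity_depth_factor = intensity_depth_factor,
    peak_intensity = peak_intensity, noise_sd = noise_sd,
    n_vessels = as.integer(n_vessels), vessel_radius_um = vessel_radius_um,
    background_level = background_level, margin_um = margin_um,
    min_separation_um = min_separation_um,
    max_place_attempts = as.integer(max_place_attempts),
    seed = as.integer(seed)
  )
  structure(cfg, class = "phantom_config")
}

comp_class_levels <- c("INS+GCG-", "INS+GCG+", "INS-GCG+")

classify_from_fraction <- function(f, threshold = 0.01) {
  cls <- ifelse(f < threshold, "INS+GCG-",
                ifelse(f > 1 - threshold, "INS-GCG+", "INS+GCG+"))
  factor(cls, levels = comp_class_levels)
}

# uniformly distributed rotation via QR of a Gaussian matrix
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Sample a ground-truth islet catalog
#'
#' Draws islet sizes, shapes, positions and glucagon compositions from the
#' configured distributions. Centres are placed by rejection sampling inside
#' the tissue mask with no two islets overlapping (conservative
#' bounding-sphere surrogate test plus the configured clearance).
#'
#' @param config a [phantom_config()].
#' @return a tibble of class `phantom_truth`: one row per islet with centre
#'   (um), semi-axes (um), rotation matrix entries, analytic volume (um^3),
#'   glucagon volume fraction and composition class.
#' @export
sample_islet_catalog <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(config$seed, {
    n <- config$n_islets
    # truncated log-normal equivalent diameters
    d <- numeric(0)
    while (length(d) < n) {
      x <- rlnorm(2L * n, meanlog = log(config$size_median_um),
                  sdlog = log(config$size_gsd))
      x <- x[x >= config$diameter_range_um[1] & x <= config$diameter_range_um[2]]
      d <- c(d, x)
    }
    d <- d[seq_len(n)]

    # volume-preserving anisotropic semi-axes
    s <- matrix(runif(3L * n, config$axis_ratio_range[1], config$axis_ratio_range[2]),
                ncol = 3)
    s <- s / exp(rowMeans(log(s)))
    semi <- s * d / 2
    vol <- 4 / 3 * pi * semi[, 1] * semi[, 2] * semi[, 3]
    rot <- lapply(seq_len(n), function(i) random_rotation())

    # composition
    small <- vol < config$gcg_neg_pivot_um3
    p_neg <- ifelse(small, config$gcg_neg_fraction_small, config$gcg_neg_fraction_large)
    neg <- rbinom(n, 1L, p_neg) == 1L
    frac <- numeric(n)
    mixed <- which(!neg)
    for (i in mixed) {
      f <- rbeta(1, config$gcg_fraction_shape[1], config$gcg_fraction_shape[2])
      tries <- 0L
      while ((f < 0.01 || f > 0.99) && tries < 100L) {
        f <- rbeta(1, config$gcg_fraction_shape[1], config$gcg_fraction_shape[2])
        tries <- tries + 1L
      }
      frac[i] <- min(max(f, 0.01), 0.99)
    }

    # placement, largest first
    ord <- order(-pmax(semi[, 1], pmax(semi[, 2], semi[, 3])))
    ext_xyz <- config$grid_shape[c(3, 2, 1)] * config$voxel_size[c(3, 2, 1)]
    centers <- matrix(NA_real_, n, 3)
    radii <- pmax(semi[, 1], pmax(semi[, 2], semi[, 3]))
    placed <- 0L
    for (i in ord) {
      r <- radii[i]
      lo <- config$margin_um + r
      hi <- ext_xyz - config$margin_um - r
      if (any(hi <= lo))
        abort(sprintf(
          "domain too crowded: islet radius %.1f um does not fit (placed %d of %d)",
          r, placed, n), class = "islet3d_crowded")
      ok <- FALSE
      for (a in seq_len(config$max_place_attempts)) {
        p <- lo + runif(3) * (hi - lo)
        if (placed > 0L) {
          prev <- which(!is.na(centers[, 1]))
          dd <- sqrt(colSums((t(centers[prev, , drop = FALSE]) - p)^2))
          if (any(dd < radii[prev] + r + config$min_separation_um)) next
        }
        centers[i, ] <- p
        placed <- placed + 1L
        ok <- TRUE
        break
      }
      if (!ok)
        abort(sprintf("domain too crowded: placement failed after %d attempts (placed %d of %d islets)",
                      config$max_place_attempts, placed, n),
              class = "islet3d_crowded")
    }

    rotflat <- t(vapply(rot, as.numeric, numeric(9)))
    colnames(rotflat) <- paste0("r", rep(1:3, 3), rep(1:3, each = 3))
    truth <- tibble(
      id = seq_len(n),
      cx_um = centers[, 1], cy_um = centers[, 2], cz_um = centers[, 3],
      a_um = semi[, 1], b_um = semi[, 2], c_um = semi[, 3],
      volume_um3 = vol,
      gcg_fraction = frac,
      class = classify_from_fraction(frac)
    )
    truth <- dplyr::bind_cols(truth, as_tibble(rotflat))
    class(truth) <- c("phantom_truth", class(truth))
    truth
  })
}

truth_rotation <- function(truth, i) {
  matrix(as.numeric(truth[i, paste0("r", rep(1:3, 3), rep(1:3, each = 3))]), 3, 3)
}

# tissue mask bounds in um, xyz
tissue_box <- function(config) {
  ext_xyz <- config$grid_shape[c(3, 2, 1)] * config$voxel_size[c(3, 2, 1)]
  list(lo = rep(config$margin_um, 3), hi = ext_xyz - config$margin_um, ext = ext_xyz)
}

#' Render a phantom volume from a truth catalog
#'
#' Rasterises the catalog into INS, GCG and AF channels. Insulin follows a
#' linear core-to-rim ramp `I(r) = peak * (floor + (1 - floor) * r/R)`
#' (dimmer core), optionally dimmed per islet with slab depth. Glucagon is
#' painted as small spheres (alpha cells) whose analytic volumes sum to the
#' islet's true glucagon fraction. The anatomy channel holds
#' `background_level` inside the tissue mask, zero inside vessel lumens and
#' outside tissue. Gaussian noise is added to all channels and intensities
#' are rounded and clipped to the 16-bit range.
#'
#' @param truth a `phantom_truth` catalog from [sample_islet_catalog()].
#' @param config the [phantom_config()] the catalog was drawn with.
#' @return a [voxel_grid()] with channels `INS`, `GCG`, `AF`.
#' @export
render_volume <- function(truth, config) {
  stopifnot(inherits(config, "phantom_config"))
  dims <- config$grid_shape
  vox <- config$voxel_size
  box <- tissue_box(config)
  ins <- array(0, dim = dims)
  gcg <- array(0, dim = dims)

  with_seed(config$seed + 1L, {
    for (i in seq_len(nrow(truth))) {
      depth <- truth$cz_um[i] / box$ext[3]
      peak <- config$peak_intensity * (1 - config$intensity_depth_factor * depth)
      cpp_paint_ellipsoid(ins, vox,
                          c(truth$cx_um[i], truth$cy_um[i], truth$cz_um[i]),
                          c(truth$a_um[i], truth$b_um[i], truth$c_um[i]),
                          truth_rotation(truth, i),
                          peak, config$gradient_floor)
      if (truth$gcg_fraction[i] > 0) {
        target <- truth$gcg_fraction[i] * truth$volume_um3[i]
        acc <- 0
        rotm <- truth_rotation(truth, i)
        semi <- c(truth$a_um[i], truth$b_um[i], truth$c_um[i])
        ctr <- c(truth$cx_um[i], truth$cy_um[i], truth$cz_um[i])
        while (acc < target) {
          dc <- runif(1, config$gcg_cell_diameter_um[1], config$gcg_cell_diameter_um[2])
          # body-frame position, uniform (or mantle shell) within the ellipsoid
          repeat {
            u <- runif(3, -1, 1)
            nr <- sqrt(sum(u^2))
            if (nr <= 1 && nr > 0) break
          }
          if (config$gcg_placement == "mantle") u <- u / nr * runif(1, 0.8, 0.98)
          pos <- ctr + as.numeric(rotm %*% (u * semi))
          cpp_paint_ellipsoid(gcg, vox, pos, rep(dc / 2, 3), diag(3),
                              config$peak_intensity, 1)
          acc <- acc + pi / 6 * dc^3
        }
      }
    }

    # anatomy: background inside the tissue box, zero in vessel lumens
    af <- array(0, dim = dims)
    zc <- (seq_len(dims[1]) - 0.5) * vox[1]
    yc <- (seq_len(dims[2]) - 0.5) * vox[2]
    xc <- (seq_len(dims[3]) - 0.5) * vox[3]
    inz <- zc > box$lo[3] & zc < box$hi[3]
    iny <- yc > box$lo[2] & yc < box$hi[2]
    inx <- xc > box$lo[1] & xc < box$hi[1]
    af[inz, iny, inx] <- config$background_level

    if (config$n_vessels > 0) {
      segs <- place_vessels(config, box)
      for (s in segs)
        cpp_paint_capsule(af, vox, s$p0, s$p1, config$vessel_radius_um, 0)
    }

    if (config$noise_sd > 0) {
      ins <- ins + rnorm(length(ins), 0, config$noise_sd)
      gcg <- gcg + rnorm(length(gcg), 0, config$noise_sd)
      af <- af + rnorm(length(af), 0, config$noise_sd)
    }
  })

  clip16 <- function(a) {
    a <- round(a)
    a[a < 0] <- 0
    a[a > 65535] <- 65535
    dim(a) <- dims
    a
  }
  voxel_grid(list(INS = clip16(ins), GCG = clip16(gcg), AF = clip16(af)),
             voxel_size = vox)
}

# non-touching interior capsule segments for vessel lumens
place_vessels <- function(config, box) {
  r <- config$vessel_radius_um
  lo <- box$lo + 2 * r
  hi <- box$hi - 2 * r
  if (any(hi <= lo)) abort("grid too small for the configured vessels")
  segs <- list()
  attempts <- 0L
  while (length(segs) < config$n_vessels && attempts < 1000L) {
    attempts <- attempts + 1L
    p0 <- lo + runif(3) * (hi - lo)
    p1 <- lo + runif(3) * (hi - lo)
    if (sqrt(sum((p1 - p0)^2)) < 4 * r) next
    ok <- TRUE
    for (s in segs) {
      if (segment_distance(p0, p1, s$p0, s$p1) < 2 * r + max(config$voxel_size)) {
        ok <- FALSE
        break
      }
    }
    if (ok) segs[[length(segs) + 1L]] <- list(p0 = p0, p1 = p1)
  }
  if (length(segs) < config$n_vessels)
    abort("could not place non-touching vessels; reduce n_vessels or radius")
  segs
}

# minimum distance between two 3D segments
segment_distance <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1; d2 <- q2 - p2; r <- p1 - p2
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  eps <- 1e-12
  if (a <= eps && e <= eps) return(sqrt(sum(r * r)))
  if (a <= eps) { s <- 0; t <- min(max(f / e, 0), 1) }
  else {
    c1 <- sum(d1 * r)
    if (e <= eps) { t <- 0; s <- min(max(-c1 / a, 0), 1) }
    else {
      b <- sum(d1 * d2); den <- a * e - b * b
      s <- if (den > eps) min(max((b * f - c1 * e) / den, 0), 1) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- min(max(-c1 / a, 0), 1) }
      else if (t > 1) { t <- 1; s <- min(max((b - c1) / a, 0), 1) }
    }
  }
  v <- (p1 + s * d1) - (p2 + t * d2)
  sqrt(sum(v * v))
}

#' Write / read a phantom bundle
#'
#' Writes one 16-bit multi-page TIFF per channel (z-planes as pages), the
#' truth catalog as CSV and the configuration as JSON. Voxel intensities are
#' integers in the 16-bit range, so the round trip is lossless; voxel-size
#' metadata travels in the JSON sidecar.
#'
#' @param grid a [voxel_grid()].
#' @param truth the matching `phantom_truth` catalog.
#' @param path output directory (created if needed).
#' @param config optional [phantom_config()] to store alongside.
#' @return `path`, invisibly.
#' @export
write_phantom <- function(grid, truth, path, config = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (ch in names(grid$channels)) {
    a <- grid$channels[[ch]]
    pages <- lapply(seq_len(dim(a)[1]), function(z) a[z, , ] / 65535)
    tiff::writeTIFF(pages, file.path(path, paste0(ch, ".tif")),
                    bits.per.sample = 16L, compression = "none")
  }
  readr::write_csv(as_tibble(truth), file.path(path, "truth.csv"))
  meta <- list(voxel_size_zyx_um = grid$voxel_size,
               grid_shape_zyx = dim(grid$channels[[1]]),
               channels = names(grid$channels),
               config = if (!is.null(config)) unclass(config))
  jsonlite::write_json(meta, file.path(path, "phantom.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_phantom
#' @return `read_phantom()` returns `list(grid, truth, meta)`.
#' @export
read_phantom <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "phantom.json"), simplifyVector = TRUE)
  chs <- list()
  for (ch in meta$channels) {
    pages <- tiff::readTIFF(file.path(path, paste0(ch, ".tif")), all = TRUE)
    a <- array(0, dim = c(length(pages), dim(pages[[1]])))
    for (z in seq_along(pages)) a[z, , ] <- round(pages[[z]] * 65535)
    chs[[ch]] <- a
  }
  truth <- readr::read_csv(file.path(path, "truth.csv"), show_col_types = FALSE)
  truth$class <- factor(truth$class, levels = comp_class_levels)
  list(grid = voxel_grid(chs, meta$voxel_size_zyx_um), truth = truth, meta = meta)
}
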