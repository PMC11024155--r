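test_that("catalog geometry: analytic volumes, class consistency, no overlaps", {
  cfg <- phantom_config("OPT", n_islets = 40, seed = 42)
  tr <- sample_islet_catalog(cfg)

  expect_equal(nrow(tr), 40)
  expect_equal(tr$volume_um3, 4 / 3 * pi * tr$a_um * tr$b_um * tr$c_um,
               tolerance = 1e-3)
  # class labels follow the < 1% rule applied to the sampled fraction
  expect_true(all((tr$gcg_fraction < 0.01) == (tr$class == "INS+GCG-")))
  expect_true(all(tr$gcg_fraction >= 0 & tr$gcg_fraction <= 1))

  # pairwise bounding-sphere surrogate: no two islets overlap
  ctr <- as.matrix(tr[, c("cx_um", "cy_um", "cz_um")])
  rad <- pmax(tr$a_um, pmax(tr$b_um, tr$c_um))
  d <- as.matrix(dist(ctr))
  lim <- outer(rad, rad, "+")
  diag(d) <- Inf
  expect_true(all(d > lim))

  # diameters honour the truncation range
  eq_d <- eq_sphere_diameter(tr$volume_um3)
  expect_true(all(eq_d >= cfg$diameter_range_um[1] - 1e-9 &
                  eq_d <= cfg$diameter_range_um[2] + 1e-9))
})

test_that("a sphere's catalog volume matches the closed form", {
  # semi-axes (50, 50, 50) um -> (4/3) pi 50^3
  expect_equal(4 / 3 * pi * 50^3, 523598.776, tolerance = 1e-6)
  cfg <- phantom_config("OPT", n_islets = 5, axis_ratio_range = c(1, 1),
                        size_median_um = 100, size_gsd = 1.000001,
                        diameter_range_um = c(99, 101), seed = 1)
  tr <- sample_islet_catalog(cfg)
  expect_equal(tr$a_um, rep(50, 5), tolerance = 0.02)
  expect_equal(tr$volume_um3, rep(523598.776, 5), tolerance = 0.05)
})

test_that("zero negativity probability yields no GCG-negative islets", {
  cfg <- phantom_config("OPT", n_islets = 60, gcg_neg_fraction_small = 0,
                        gcg_neg_fraction_large = 0, seed = 3)
  tr <- sample_islet_catalog(cfg)
  expect_false(any(tr$class == "INS+GCG-"))
  expect_true(all(tr$gcg_fraction >= 0.01))
})

test_that("realised GCG-negative fraction is binomially calibrated (n = 500)", {
  cfg <- phantom_config("OPT", grid_shape = c(256, 256, 256), n_islets = 500,
                        gcg_neg_fraction_small = 0.5, gcg_neg_fraction_large = 0.5,
                        seed = 7)
  tr <- sample_islet_catalog(cfg)
  ci <- stats::binom.test(sum(tr$class == "INS+GCG-"), 500, 0.5)$conf.int
  expect_true(ci[1] <= 0.5 && 0.5 <= ci[2])
})

test_that("catalog and volume are fully determined by the seed", {
  cfg <- phantom_config("OPT", n_islets = 12, seed = 9)
  tr1 <- sample_islet_catalog(cfg)
  tr2 <- sample_islet_catalog(cfg)
  expect_identical(tr1, tr2)
  g1 <- render_volume(tr1, cfg)
  g2 <- render_volume(tr2, cfg)
  expect_identical(g1$channels, g2$channels)
})

test_that("overcrowded domains fail with the achieved count", {
  cfg <- phantom_config("OPT", grid_shape = c(24, 24, 24), n_islets = 500,
                        max_place_attempts = 20, seed = 1)
  expect_error(sample_islet_catalog(cfg), class = "islet3d_crowded")
})

test_that("rendering: flat profile paints constant intensity, vessels carve tubes", {
  cfg <- phantom_config("OPT", n_islets = 6, noise_sd = 0, gradient_floor = 1,
                        n_vessels = 2, seed = 21)
  tr <- sample_islet_catalog(cfg)
  g <- render_volume(tr, cfg)
  ins <- g$channels$INS
  expect_setequal(unique(as.vector(ins)), c(0, cfg$peak_intensity))

  # anatomy: exactly 2 connected zero-intensity tubes inside the tissue
  af <- g$channels$AF
  inner <- af == 0
  # restrict to the tissue box (exclude the outside margin)
  box_margin <- ceiling(cfg$margin_um / cfg$voxel_size) + 1
  d <- dim(af)
  tissue_zero <- array(FALSE, d)
  idx <- list(
    (box_margin[1] + 1):(d[1] - box_margin[1]),
    (box_margin[2] + 1):(d[2] - box_margin[2]),
    (box_margin[3] + 1):(d[3] - box_margin[3])
  )
  tissue_zero[idx[[1]], idx[[2]], idx[[3]]] <- inner[idx[[1]], idx[[2]], idx[[3]]]
  storage.mode(tissue_zero) <- "integer"
  lab <- islet3d:::cpp_label3d(tissue_zero, 26L)
  expect_equal(attr(lab, "n_labels"), 2L)
})

test_that("voxelised islet volume approaches the analytic volume with resolution", {
  # one 100 um sphere at 21 um voxels: within 10%
  cfg <- phantom_config("OPT", grid_shape = c(32, 32, 32), n_islets = 1,
                        noise_sd = 0, gradient_floor = 1, axis_ratio_range = c(1, 1),
                        size_median_um = 100, size_gsd = 1.000001,
                        diameter_range_um = c(99.9, 100.1), n_vessels = 0, seed = 2)
  tr <- sample_islet_catalog(cfg)
  g <- render_volume(tr, cfg)
  vox_vol <- sum(g$channels$INS > 0) * prod(cfg$voxel_size)
  expect_equal(vox_vol, 523598.776, tolerance = 0.10)

  # same sphere at 2 um voxels: within 2%
  cfg2 <- phantom_config("OPT", grid_shape = c(80, 80, 80), voxel_size = c(2, 2, 2),
                         n_islets = 1, noise_sd = 0, gradient_floor = 1,
                         axis_ratio_range = c(1, 1), size_median_um = 100,
                         size_gsd = 1.000001, diameter_range_um = c(99.9, 100.1),
                         n_vessels = 0, margin_um = 8, min_separation_um = 2,
                         seed = 2)
  tr2 <- sample_islet_catalog(cfg2)
  g2 <- render_volume(tr2, cfg2)
  vox_vol2 <- sum(g2$channels$INS > 0) * prod(cfg2$voxel_size)
  expect_equal(vox_vol2, tr2$volume_um3, tolerance = 0.02)
})

test_that("phantom bundles round-trip losslessly through TIFF + CSV + JSON", {
  cfg <- phantom_config("OPT", grid_shape = c(24, 24, 24), n_islets = 3,
                        size_median_um = 60, diameter_range_um = c(45, 90),
                        n_vessels = 0, seed = 5)
  tr <- sample_islet_catalog(cfg)
  g <- render_volume(tr, cfg)
  dir <- withr::local_tempdir()
  write_phantom(g, tr, dir, config = cfg)
  back <- read_phantom(dir)
  expect_identical(lapply(back$grid$channels, as.vector),
                   lapply(g$channels, as.vector))
  expect_equal(back$grid$voxel_size, g$voxel_size)
  expect_equal(nrow(back$truth), cfg$n_islets)
  expect_equal(back$truth$volume_um3, tr$volume_um3)
  expect_equal(back$truth$class, tr$class)
})

test_that("configuration invariants are enforced", {
  expect_error(phantom_config("OPT", gcg_neg_fraction_small = 1.2), "probability")
  expect_error(phantom_config("OPT", size_median_um = 40), "twice the largest voxel")
  expect_error(phantom_config("OPT", axis_ratio_range = c(0.5, 2)), "axis_ratio_range")
})
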