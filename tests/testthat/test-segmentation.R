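test_that("preprocessing: top-hat removes flat background, identity limits hold", {
  # constant image -> all zero after top-hat
  g <- grid1(array(7, c(12, 12, 12)), voxel = c(21, 21, 21))
  p <- segmentation_params("OPT", gaussian_sigma_um = 0)
  out <- preprocess_channel(g, "INS", p)
  expect_true(all(out$channels$INS == 0))

  # sigma = 0 and structuring element >> image extent: output equals input
  a <- array(runif(12^3), c(12, 12, 12))
  g2 <- grid1(a, voxel = c(21, 21, 21))
  p2 <- segmentation_params("OPT", gaussian_sigma_um = 0,
                            background_structure_um = Inf)
  expect_equal(preprocess_channel(g2, "INS", p2)$channels$INS, a)

  # a bright sphere on zero background survives the top-hat with its peak
  ball <- digital_ball(24, 1.5, value = 100)  # ~60 um object at 21 um voxels
  g3 <- grid1(ball, voxel = c(21, 21, 21))
  out3 <- preprocess_channel(g3, "INS", segmentation_params("OPT", gaussian_sigma_um = 0))
  expect_true(all(out3$channels$INS >= 0))
  expect_gte(max(out3$channels$INS), 95)
})

test_that("structuring elements below one voxel name the offending axis", {
  g <- grid1(array(1, c(8, 8, 8)), voxel = c(5, 1.9, 1.9))
  p <- segmentation_params("LSFM", gaussian_sigma_um = 0,
                           background_structure_um = 4)  # radius 2 um < z voxel
  expect_error(preprocess_channel(g, "INS", p), "axis z")
})

test_that("thresholding labels connected components and is strictly greater-than", {
  p <- raw_params()
  g0 <- grid1(array(0, c(10, 10, 10)))
  expect_equal(threshold_objects(g0, "INS", 5, p)$n_labels, 0L)

  # two balls separated by background -> 2 objects; bridged -> 1
  a <- array(0, c(20, 20, 20))
  a[3:7, 3:7, 3:7] <- 10
  a[13:17, 13:17, 13:17] <- 10
  expect_equal(threshold_objects(grid1(a), "INS", 5, p)$n_labels, 2L)
  a[7:13, 7:13, 7:13] <- 10  # bright bridge fuses them
  expect_equal(threshold_objects(grid1(a), "INS", 5, p)$n_labels, 1L)

  # voxels exactly at the threshold are background
  b <- array(5, c(4, 4, 4))
  expect_equal(threshold_objects(grid1(b), "INS", 5, p)$n_labels, 0L)

  # physical minimum-volume filter
  a2 <- array(0, c(10, 10, 10))
  a2[2, 2, 2] <- 10            # 1 voxel = 9261 um3 at 21 um
  a2[5:7, 5:7, 5:7] <- 10      # 27 voxels
  g2 <- grid1(a2, voxel = c(21, 21, 21))
  p2 <- raw_params(min_object_volume_um3 = 1e4)
  expect_equal(threshold_objects(g2, "INS", 5, p2)$n_labels, 1L)
})

test_that("two-pass surfacing merges gradient objects and adds dim ones", {
  p <- raw_params(primary_threshold = 50, secondary_threshold = 10)
  vox <- c(21, 21, 21)

  # image with nothing between the thresholds: result identical to pass 1
  a <- array(0, c(16, 16, 16)); a[4:8, 4:8, 4:8] <- 100
  g <- grid1(a, voxel = vox)
  tp <- two_pass_segment(g, "INS", p, preprocess = FALSE)
  p1 <- threshold_objects(g, "INS", 50, p)
  expect_equal(tp$n_labels, p1$n_labels)
  expect_equal(tp$labels > 0L, p1$labels > 0L)

  # a dim islet (below primary, above secondary) not overlapping pass 1
  # is retained from pass 2
  a[11:14, 11:14, 11:14] <- 30
  tp2 <- two_pass_segment(grid1(a, voxel = vox), "INS", p, preprocess = FALSE)
  expect_equal(tp2$n_labels, 2L)

  # gradient islet: bright rim above primary, dim core between thresholds ->
  # exactly one merged object whose interior encloses the core (flood fill
  # from the border cannot reach it)
  n <- 32
  b <- array(0, c(n, n, n))
  ctr <- n / 2 + 0.5
  for (z in 1:n) for (y in 1:n) for (x in 1:n) {
    r <- sqrt((z - ctr)^2 + (y - ctr)^2 + (x - ctr)^2)
    if (r <= 10) b[z, y, x] <- if (r >= 6) 100 else 20
  }
  gb <- grid1(b, voxel = vox)
  tpb <- two_pass_segment(gb, "INS", p, preprocess = FALSE)
  expect_equal(tpb$n_labels, 1L)
  outside <- array(tpb$labels == 0L, dim(b))
  storage.mode(outside) <- "integer"
  bg <- islet3d:::cpp_label3d(outside, 6L)
  border_labels <- unique(c(bg[1, , ], bg[n, , ], bg[, 1, ], bg[, n, ],
                            bg[, , 1], bg[, , n]))
  core <- bg[ctr, ctr, ctr]  # background label at the core, if any
  expect_false(core %in% border_labels[border_labels > 0])
})

test_that("voxel conservation: pass1 mask within merged mask within secondary mask", {
  cfg <- phantom_config("OPT", n_islets = 15, noise_sd = 0,
                        intensity_depth_factor = 0.9, seed = 31)
  tr <- sample_islet_catalog(cfg)
  g <- render_volume(tr, cfg)
  p <- raw_params(primary_threshold = 20, secondary_threshold = 2)
  merged <- two_pass_segment(g, "INS", p, preprocess = FALSE)
  p1 <- threshold_objects(g, "INS", 20, p)
  sec <- g$channels$INS > 2
  expect_true(all(merged$labels[p1$labels > 0L] > 0L))
  expect_true(all(sec[merged$labels > 0L]))
})

test_that("6- and 26-connectivity differ exactly for diagonal contact", {
  a <- array(0, c(6, 6, 6))
  a[2, 2, 2] <- 10
  a[3, 3, 3] <- 10  # touches only diagonally
  g <- grid1(a)
  expect_equal(threshold_objects(g, "INS", 5, raw_params(connectivity = 26))$n_labels, 1L)
  expect_equal(threshold_objects(g, "INS", 5, raw_params(connectivity = 6))$n_labels, 2L)
})

test_that("objects outside the tissue mask are excluded; lumen interiors are not", {
  vox <- c(21, 21, 21)
  n <- 40
  af <- array(0, c(n, n, n))
  af[8:32, 8:32, 8:32] <- 20                      # tissue block
  # a lumen tube along x through the block interior
  af[18:22, 18:22, 12:28] <- 0
  ins <- array(0, c(n, n, n))
  ins[12:14, 12:14, 12:14] <- 50                  # inside tissue
  ins[36:38, 36:38, 36:38] <- 50                  # outside tissue
  ins[19:21, 19:21, 19:21] <- 50                  # centroid inside the lumen
  g <- voxel_grid(list(INS = ins, AF = af), vox)
  p <- raw_params()
  objs <- threshold_objects(g, "INS", 5, p)
  expect_equal(objs$n_labels, 3L)
  kept <- exclude_outside_tissue(objs, g, af_threshold = 10, closing_um = 80)
  expect_equal(kept$n_labels, 2L)

  # all objects inside -> identity
  ins2 <- array(0, c(n, n, n)); ins2[12:14, 12:14, 12:14] <- 50
  g2 <- voxel_grid(list(INS = ins2, AF = af), vox)
  objs2 <- threshold_objects(g2, "INS", 5, p)
  expect_equal(exclude_outside_tissue(objs2, g2, 10, 80)$n_labels, 1L)

  # empty tissue mask errors
  g3 <- voxel_grid(list(INS = ins2, AF = array(0, c(n, n, n))), vox)
  expect_error(exclude_outside_tissue(objs2, g3, 10, 80), "empty tissue mask")
})

test_that("noise-free phantom recovery is exact for well-separated islets", {
  cfg <- phantom_config("OPT", grid_shape = c(96, 96, 96), n_islets = 25,
                        noise_sd = 0, min_separation_um = 63, seed = 17)
  tr <- sample_islet_catalog(cfg)
  g <- render_volume(tr, cfg)
  lab <- two_pass_segment(g, "INS", raw_params())
  expect_equal(lab$n_labels, nrow(tr))
  vv <- sum(lab$labels > 0L) * prod(cfg$voxel_size)
  expect_equal(vv, sum(tr$volume_um3), tolerance = 0.15)
})

test_that("parameter invariants are enforced", {
  expect_error(segmentation_params("OPT", secondary_threshold = 6), "below")
  expect_error(segmentation_params("OPT", connectivity = 4), "connectivity")
})

test_that("label volumes round-trip through 32-bit TIFF with metadata", {
  a <- array(0L, c(6, 8, 9))
  a[2:3, 2:3, 2:3] <- 1L
  a[5, 5:6, 5] <- 2L
  attr(a, "n_labels") <- 2L
  lab <- label_volume(a, c(5, 1.9, 1.9), provenance = "merged")
  path <- file.path(withr::local_tempdir(), "labels.tif")
  write_labels(lab, path)
  back <- read_labels(path)
  expect_identical(as.vector(back$labels), as.vector(lab$labels))
  expect_equal(back$voxel_size, lab$voxel_size)
  expect_equal(back$n_labels, 2L)
  expect_equal(back$provenance, "merged")
})
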