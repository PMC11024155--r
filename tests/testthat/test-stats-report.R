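test_that("disc density: lumens reduce tissue volume by exactly their voxel volume", {
  vox <- c(21, 21, 21)
  n <- 40
  af <- array(0, c(n, n, n))
  af[6:34, 6:34, 6:34] <- 20
  g_solid <- voxel_grid(list(AF = af), vox)
  no_islets <- label_volume(array(0L, c(n, n, n)), vox)
  d_solid <- disc_density(g_solid, no_islets, af_threshold = 10, closing_um = 80)
  expect_equal(d_solid$ins_density, 0)  # no islets -> density 0
  expect_equal(d_solid$lumen_volume_um3, 0)

  # carve an interior tube of known voxel volume
  af2 <- af
  af2[18:22, 18:22, 10:30] <- 0
  tube_voxels <- 5 * 5 * 21
  g_tube <- voxel_grid(list(AF = af2), vox)
  d_tube <- disc_density(g_tube, no_islets, af_threshold = 10, closing_um = 80)
  expect_equal(d_solid$tissue_volume_um3 - d_tube$tissue_volume_um3,
               tube_voxels * prod(vox))
  expect_equal(d_tube$lumen_volume_um3, tube_voxels * prod(vox))

  # an open notch at the surface is outside, not lumen
  af3 <- af
  af3[6:10, 6:10, 6:10] <- 0
  g_notch <- voxel_grid(list(AF = af3), vox)
  d_notch <- disc_density(g_notch, no_islets, af_threshold = 10, closing_um = 80)
  expect_equal(d_notch$lumen_volume_um3, 0)

  expect_error(disc_density(voxel_grid(list(AF = array(0, c(8, 8, 8))), vox),
                            no_islets, 10, 40), "zero tissue")
})

test_that("planted insulin density is recovered on a noise-free disc", {
  cfg <- phantom_config("OPT", grid_shape = c(96, 96, 96), n_islets = 30,
                        noise_sd = 0, n_vessels = 0, seed = 29)
  tr <- sample_islet_catalog(cfg)
  g <- render_volume(tr, cfg)
  lab <- two_pass_segment(g, "INS", raw_params())
  d <- disc_density(g, lab, af_threshold = 10, closing_um = 50)
  truth_density <- sum(tr$volume_um3) / d$tissue_volume_um3
  expect_lt(abs(d$ins_density - truth_density), 0.003)  # within 0.3 pp
})

test_that("ROUT: degenerate spreads, Q = 0, and a gross outlier", {
  expect_warning(r0 <- rout_outliers(c(1, 2, 50)), "n >= 4")
  expect_equal(length(r0$removed), 0)

  r1 <- rout_outliers(c(5, 5, 5, 5, 5))
  expect_equal(length(r1$removed), 0)  # zero spread: scale floor, no removal

  v <- c(1, 1.1, 0.9, 1.05, 0.95, 50)
  r2 <- rout_outliers(v, Q = 0.01)
  expect_equal(r2$removed, 50)
  expect_equal(sort(r2$kept), sort(v[-6]))
  # oracle: the documented arithmetic for the constant-location reduction
  ctr <- median(v)
  rsdr <- unname(quantile(abs(v - ctr), 0.6827)) * 6 / 5
  expect_equal(r2$center, ctr)
  expect_equal(r2$rsdr, rsdr)
  p_extreme <- 2 * pt(-abs(50 - ctr) / rsdr, df = 5)
  expect_lt(p_extreme, 0.01 * 6 / 6)

  r3 <- rout_outliers(v, Q = 0)
  expect_equal(length(r3$removed), 0)
})

test_that("ROUT is permutation-invariant and scale-equivariant", {
  withr::local_seed(11)
  v <- c(rnorm(12), 9, -7)
  base <- rout_outliers(v, 0.05)
  perm <- sample(length(v))
  rp <- rout_outliers(v[perm], 0.05)
  expect_equal(rp$outlier, base$outlier[perm])
  rs <- rout_outliers(v * 1000, 0.05)
  expect_equal(rs$outlier, base$outlier)
})

test_that("paired comparison gates on normality and handles identical inputs", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  same <- paired_compare(x, x)
  expect_equal(same$p_value, 1)
  expect_equal(same$statistic, 0)

  # closed-form paired t for n = 3
  a <- c(1, 2, 4); b <- c(0.5, 1.2, 2.9)
  d <- a - b
  t_closed <- mean(d) / (sd(d) / sqrt(3))
  pc <- paired_compare(a, b)
  expect_equal(pc$method, "paired t-test")
  expect_equal(pc$statistic, t_closed)
  expect_equal(pc$p_value, 2 * pt(-abs(t_closed), df = 2))

  expect_error(paired_compare(1:5, 1:4), "paired")
  expect_error(paired_compare(c(1, 2), c(3, 4)), "n >= 3")

  # star codes at the printed boundaries
  expect_equal(islet3d:::star_code(0.2), "ns")
  expect_equal(islet3d:::star_code(0.05), "*")
  expect_equal(islet3d:::star_code(0.01), "**")
  expect_equal(islet3d:::star_code(0.001), "***")
  expect_equal(islet3d:::star_code(0.0001), "****")
})

test_that("test selection follows the data distribution across replicates", {
  withr::local_seed(33)
  chosen_t <- replicate(20, {
    x <- rnorm(40); y <- x + rnorm(40, 0.3)
    paired_compare(x, y)$method == "paired t-test"
  })
  expect_gte(mean(chosen_t), 0.9)

  chosen_w <- replicate(20, {
    x <- rt(40, df = 1); y <- rt(40, df = 1)
    paired_compare(x, y)$method
  })
  expect_gt(mean(chosen_w == "Wilcoxon matched-pairs signed-rank test"), 0.5)
})

test_that("tidiers summarise test and outlier objects", {
  pc <- paired_compare(c(1, 2, 3, 5), c(2, 2, 2, 2))
  td <- tidy(pc)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("method", "statistic", "p_value", "stars", "n"))
  expect_true(all(c("normal", "n") %in% names(glance(pc))))

  r <- rout_outliers(c(1, 1.1, 0.9, 1.05, 0.95, 50))
  expect_equal(sum(tidy(r)$outlier), 1)
  expect_equal(glance(r)$n_removed, 1)
})

test_that("volume-weighted disc densities pool exactly", {
  withr::local_seed(6)
  discs <- tibble::tibble(
    disc_id = 1:8,
    tissue_volume_um3 = runif(8, 1e9, 5e9),
    ins_volume_um3 = runif(8, 1e7, 9e7)
  )
  discs$ins_density <- discs$ins_volume_um3 / discs$tissue_volume_um3
  discs$n_islets <- 10L
  pooled <- sum(discs$ins_volume_um3) / sum(discs$tissue_volume_um3)
  weighted <- sum(discs$ins_density * discs$tissue_volume_um3) /
    sum(discs$tissue_volume_um3)
  expect_equal(weighted, pooled, tolerance = 1e-12)
  rep <- build_report(discs, tibble::tibble())
  expect_equal(rep$pooled$ins_density, pooled, tolerance = 1e-12)
  expect_true(rep$flags$no_objects)
})

test_that("report bundles are byte-stable and survive empty inputs", {
  discs <- tibble::tibble(disc_id = 1L, tissue_volume_um3 = 1e9,
                          lumen_volume_um3 = 0, ins_volume_um3 = 0,
                          ins_density = 0, n_islets = 0L)
  rep <- build_report(discs, tibble::tibble(), config = list(seed = 1))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_report(rep, d1)
  write_report(rep, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_equal(f1, f2)
  for (f in f1) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), label = f)
  }
})

test_that("report building rejects schema violations, naming the fields", {
  bad <- tibble::tibble(disc_id = 1L, ins_volume_um3 = 1)
  expect_error(build_report(bad, tibble::tibble()),
               "missing field.*tissue_volume_um3")
  neg <- tibble::tibble(disc_id = 1L, tissue_volume_um3 = -1,
                        ins_volume_um3 = 0, ins_density = 0, n_islets = 0L)
  expect_error(build_report(neg, tibble::tibble()), "schema")
})
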