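# fixtures are built in code at test time; no binary data ships with the
# package

# digital ball: 3D integer array with 1 inside a sphere of radius r (voxels)
digital_ball <- function(n, r, center = rep(n / 2 + 0.5, 3), value = 1) {
  a <- array(0, dim = c(n, n, n))
  for (z in seq_len(n)) {
    d2z <- (z - center[1])^2
    for (y in seq_len(n)) {
      d2zy <- d2z + (y - center[2])^2
      xs <- which(d2zy + (seq_len(n) - center[3])^2 <= r^2)
      if (length(xs)) a[z, y, xs] <- value
    }
  }
  a
}

# single-channel grid wrapper
grid1 <- function(arr, voxel = c(1, 1, 1), name = "INS") {
  chs <- setNames(list(arr), name)
  voxel_grid(chs, voxel)
}

# segmentation params with preprocessing disabled (noise-free fixtures)
raw_params <- function(dialect = "OPT", ...) {
  args <- utils::modifyList(
    list(gaussian_sigma_um = 0, background_structure_um = Inf,
         min_object_volume_um3 = 0),
    list(...))
  do.call(segmentation_params, c(list(dialect), args))
}

# brute-force mean k-NN distance oracle (O(n^2))
brute_knn <- function(pts, k, ref = pts, self = TRUE) {
  vapply(seq_len(nrow(pts)), function(i) {
    d <- sqrt(colSums((t(ref) - pts[i, ])^2))
    if (self) d <- d[-i]
    mean(sort(d)[seq_len(k)])
  }, numeric(1))
}
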