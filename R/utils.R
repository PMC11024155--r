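# internal helpers shared across modules

# evaluate `code` under a fixed RNG seed, restoring global RNG state after
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# integer (dz, dy, dx) offsets of a ball of physical radius `radius_um`
# sampled on an anisotropic voxel lattice; excludes the origin
ball_offsets <- function(radius_um, voxel_size) {
  r <- pmax(0L, as.integer(floor(radius_um / voxel_size + 1e-9)))
  if (all(r == 0L)) return(matrix(integer(0), ncol = 3))
  g <- expand.grid(dz = -r[1]:r[1], dy = -r[2]:r[2], dx = -r[3]:r[3])
  d2 <- (g$dz * voxel_size[1])^2 + (g$dy * voxel_size[2])^2 + (g$dx * voxel_size[3])^2
  g <- g[d2 <= radius_um^2 * (1 + 1e-9) & d2 > 0, , drop = FALSE]
  as.matrix(g)
}

# map old labels -> new consecutive labels, dropping labels where !keep
relabel_keep <- function(labels, keep) {
  n <- length(keep)
  map <- integer(n)
  map[keep] <- seq_len(sum(keep))
  lut <- c(0L, map)
  out <- lut[labels + 1L]
  dim(out) <- dim(labels)
  attr(out, "n_labels") <- sum(keep)
  out
}

# physical voxel volume in um^3
voxel_volume <- function(voxel_size) prod(voxel_size)

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(x < 0) || any(x > 1))
    abort(sprintf("`%s` must be a probability in [0, 1]", name))
}

# binary morphological closing (dilate then erode) with a Euclidean ball,
# via two exact distance transforms (fast for any radius)
binary_close <- function(mask, radius_um, voxel_size) {
  if (radius_um < min(voxel_size)) return(mask)
  dm <- dim(mask)
  m <- mask
  storage.mode(m) <- "integer"
  r2 <- radius_um^2 * (1 + 1e-9)
  dil <- cpp_edt2(m, voxel_size) <= r2           # dilation by the ball
  storage.mode(dil) <- "integer"
  bg <- 1L - dil
  dim(bg) <- dm
  out <- cpp_edt2(bg, voxel_size) > r2           # erosion of the dilation
  dim(out) <- dm
  out
}
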