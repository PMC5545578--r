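#' Build a grid-centered affine
#'
#' Constructs the 4x4 voxel-to-world affine for a regular grid whose center
#' lies at the world origin, so the midsagittal plane (world x = 0) bisects
#' the grid exactly. Voxel indices are 0-based in the affine convention
#' (NIfTI style); the R-side containers use 1-based array indices and convert
#' internally.
#'
#' @param voxel_size numeric length-3, mm per voxel along x, y, z.
#' @param grid_shape integer length-3, voxel counts per axis.
#' @return a 4x4 affine matrix.
#' @export
make_affine <- function(voxel_size, grid_shape) {
  stopifnot(length(voxel_size) == 3, length(grid_shape) == 3,
            all(voxel_size > 0), all(grid_shape >= 1))
  A <- diag(4)
  A[1:3, 1:3] <- diag(voxel_size)
  A[1:3, 4] <- -voxel_size * (grid_shape - 1) / 2
  A
}

# world (mm) coordinates of 1-based voxel indices; ijk is an n x 3 matrix
world_from_voxel <- function(affine, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  h <- cbind(ijk - 1, 1)
  t(affine[1:3, , drop = FALSE] %*% t(h))
}

# continuous 1-based voxel coordinates of world points; xyz is an n x 3 matrix
voxel_from_world <- function(affine, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  h <- cbind(xyz, 1)
  t(solve(affine)[1:3, , drop = FALSE] %*% t(h)) + 1
}

nearest_voxel <- function(affine, xyz) {
  v <- round(voxel_from_world(affine, xyz))
  storage.mode(v) <- "integer"
  v
}

voxel_sizes <- function(affine) sqrt(colSums(affine[1:3, 1:3]^2))

# world x coordinate of every voxel column i (1-based) along the first axis
axis_x_world <- function(affine, nx) {
  affine[1, 1] * (seq_len(nx) - 1) + affine[1, 4]
}

in_grid <- function(ijk, dims) {
  ijk[1] >= 1L && ijk[1] <= dims[1] &&
    ijk[2] >= 1L && ijk[2] <= dims[2] &&
    ijk[3] >= 1L && ijk[3] <= dims[3]
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

# 6-connected neighbors of 1-based linear indices within dims; returns a list
neighbors6 <- function(idx, dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  i0 <- idx - 1L
  i <- i0 %% nx
  j <- (i0 %/% nx) %% ny
  k <- i0 %/% (nx * ny)
  res <- integer(0)
  if (i > 0)      res <- c(res, idx - 1L)
  if (i < nx - 1) res <- c(res, idx + 1L)
  if (j > 0)      res <- c(res, idx - nx)
  if (j < ny - 1) res <- c(res, idx + nx)
  if (k > 0)      res <- c(res, idx - nx * ny)
  if (k < nz - 1) res <- c(res, idx + nx * ny)
  res
}
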