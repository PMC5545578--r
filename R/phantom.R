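#' Specify a tensor-field phantom
#'
#' A phantom is a regular 3D grid of diffusion tensors containing straight
#' cylindrical fiber bundles embedded in an isotropic-ish background. Each
#' bundle is a capsule (segment plus radius, in world mm) whose voxels carry a
#' cylindrically symmetric tensor with principal direction along the bundle
#' axis and a prescribed FA; curved tracts are composed by chaining bundles.
#' Phantoms drive the tractography and network tests: the tracker's FA
#' stopping rule (FA < 0.2) must separate bundle from background, so every
#' bundle FA must exceed 0.2 and the background FA must not.
#'
#' @param grid_shape integer length-3 voxel counts.
#' @param voxel_size numeric length-3 mm per voxel (default 1 mm isotropic).
#' @param bundles list of [bundle()] descriptors.
#' @param background_fa background FA in `[0, 0.2]`.
#' @param noise_sd standard deviation of Gaussian perturbation added to each
#'   tensor component (0 = noise-free).
#' @param seed RNG seed used for the noise draw.
#' @return a `phantom_spec` object.
#' @seealso [make_tensor_phantom()]
#' @export
phantom_spec <- function(grid_shape, voxel_size = c(1, 1, 1), bundles = list(),
                         background_fa = 0.05, noise_sd = 0, seed = 1L) {
  grid_shape <- as.integer(unlist(grid_shape))
  voxel_size <- as.numeric(unlist(voxel_size))
  background_fa <- as.numeric(background_fa)
  noise_sd <- as.numeric(noise_sd)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1),
            length(voxel_size) == 3, all(voxel_size > 0))
  if (background_fa < 0 || background_fa > 0.2)
    stop("background_fa must lie in [0, 0.2] (tracking stop threshold)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  bundles <- lapply(bundles, function(b) {
    if (!inherits(b, "phantom_bundle"))
      b <- do.call(bundle, b[c("start", "end", "radius", "fa")])
    b
  })
  for (b in bundles) {
    if (b$fa <= 0.2) stop("bundle inside FA must exceed 0.2 (tracking stop threshold)")
    if (b$radius <= max(voxel_size))
      stop("bundle radius must exceed the voxel size")
  }
  structure(list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
                 bundles = bundles, background_fa = background_fa,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @param start,end segment endpoints in world mm (length-3).
#' @param radius capsule radius in mm; must exceed the voxel size.
#' @param fa target FA inside the bundle, in `(0.2, 1]`.
#' @export
bundle <- function(start, end, radius, fa) {
  start <- as.numeric(unlist(start))
  end <- as.numeric(unlist(end))
  radius <- as.numeric(radius)
  fa <- as.numeric(fa)
  stopifnot(length(start) == 3, length(end) == 3, radius > 0,
            fa > 0, fa <= 1)
  if (sum((end - start)^2) == 0) stop("bundle start and end coincide")
  structure(list(start = as.numeric(start), end = as.numeric(end),
                 radius = radius, fa = fa), class = "phantom_bundle")
}

# Minor eigenvalue of a cylindrically symmetric tensor (lambda1 = 1,
# lambda2 = lambda3 = b) with prescribed FA. Closed form from
# FA = (1 - b) / sqrt(1 + 2 b^2), inverted for b in [0, 1].
cyl_lambda23 <- function(fa) {
  stopifnot(fa >= 0, fa < 1 + 1e-12)
  if (fa == 0) return(1)
  den <- 1 - 2 * fa^2
  if (abs(den) < 1e-10) return((1 - fa^2) / 2)
  (1 - fa * sqrt(3 - 2 * fa^2)) / den
}

# 6-component upper triangle (xx, xy, xz, yy, yz, zz) of b*I + (1-b) u u^T
cyl_tensor6 <- function(direction, fa) {
  u <- direction / sqrt(sum(direction^2))
  b <- cyl_lambda23(fa)
  D <- b * diag(3) + (1 - b) * tcrossprod(u)
  c(D[1, 1], D[1, 2], D[1, 3], D[2, 2], D[2, 3], D[3, 3])
}

#' Build a tensor-field phantom
#'
#' Realizes a [phantom_spec()] as a [tensor_volume()] plus ground truth.
#' Tensors are cylindrically symmetric with unit principal eigenvalue; the
#' minor eigenvalues are solved in closed form from the target FA, so the FA
#' map of a noise-free phantom reproduces the requested values exactly.
#' Overlapping bundles are only permitted where their axes are parallel;
#' conflicting overlaps raise an error naming the colliding bundles.
#'
#' @param spec a `phantom_spec`.
#' @return list with `tensors` (a `tensor_volume`), `fa` (an `fa_volume`
#'   computed from the tensors), and `truth` (integer array, per-voxel bundle
#'   membership; 0 = background).
#' @export
make_tensor_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$grid_shape
  affine <- make_affine(spec$voxel_size, dims)
  nvox <- prod(dims)
  ijk <- arrayInd(seq_len(nvox), dims)
  xyz <- world_from_voxel(affine, ijk)

  truth <- integer(nvox)
  dirs <- lapply(spec$bundles, function(b) {
    d <- b$end - b$start
    d / sqrt(sum(d^2))
  })
  for (bi in seq_along(spec$bundles)) {
    b <- spec$bundles[[bi]]
    seg <- b$end - b$start
    seglen2 <- sum(seg^2)
    w <- sweep(xyz, 2, b$start)
    tproj <- pmin(pmax((w %*% seg) / seglen2, 0), 1)
    px <- b$start[1] + tproj * seg[1]
    py <- b$start[2] + tproj * seg[2]
    pz <- b$start[3] + tproj * seg[3]
    d2 <- (xyz[, 1] - px)^2 + (xyz[, 2] - py)^2 + (xyz[, 3] - pz)^2
    inside <- d2 <= b$radius^2
    clash <- inside & truth > 0L
    if (any(clash)) {
      others <- unique(truth[clash])
      for (o in others) {
        cosang <- abs(sum(dirs[[o]] * dirs[[bi]]))
        if (cosang < 1 - 1e-9)
          stop(sprintf("bundles %d and %d overlap with conflicting directions",
                       o, bi))
      }
      inside <- inside & truth == 0L  # parallel overlap: first bundle keeps it
    }
    truth[inside] <- bi
  }

  tens <- matrix(0, nvox, 6)
  bg6 <- cyl_tensor6(c(1, 0, 0), spec$background_fa)
  tens[] <- rep(bg6, each = nvox)
  for (bi in seq_along(spec$bundles)) {
    sel <- truth == bi
    if (any(sel))
      tens[sel, ] <- rep(cyl_tensor6(dirs[[bi]], spec$bundles[[bi]]$fa),
                         each = sum(sel))
  }
  if (spec$noise_sd > 0) {
    tens <- tens + with_seed(spec$seed,
                             matrix(stats::rnorm(nvox * 6, 0, spec$noise_sd),
                                    nvox, 6))
  }
  tv <- tensor_volume(array(tens, c(dims, 6)), affine)
  list(tensors = tv, fa = fa_map(tv), truth = array(truth, dims))
}

#' FA map of a tensor volume
#'
#' Computes fractional anisotropy per voxel from the tensor components using
#' the rotation-invariant Frobenius form
#' `FA = sqrt(3/2) * ||D - (tr D / 3) I||_F / ||D||_F`,
#' which equals the eigenvalue formula without diagonalization. Zero tensors
#' map to FA = 0.
#'
#' @param tensors a `tensor_volume`.
#' @return an `fa_volume` sharing the affine.
#' @export
fa_map <- function(tensors) {
  stopifnot(inherits(tensors, "tensor_volume"))
  d <- dim(tensors$data)
  m <- matrix(tensors$data, prod(d[1:3]), 6)
  xx <- m[, 1]; xy <- m[, 2]; xz <- m[, 3]
  yy <- m[, 4]; yz <- m[, 5]; zz <- m[, 6]
  tr3 <- (xx + yy + zz) / 3
  norm2 <- xx^2 + yy^2 + zz^2 + 2 * (xy^2 + xz^2 + yz^2)
  dev2 <- (xx - tr3)^2 + (yy - tr3)^2 + (zz - tr3)^2 + 2 * (xy^2 + xz^2 + yz^2)
  fa <- numeric(length(xx))
  nz <- norm2 > 0
  fa[nz] <- sqrt(1.5) * sqrt(dev2[nz] / norm2[nz])
  fa_volume(array(pmin(fa, 1), d[1:3]), tensors$affine)
}

#' Write a phantom to disk
#'
#' Tensor components, FA map, brain mask, and bundle ground truth as NIfTI.
#'
#' @param phantom result of [make_tensor_phantom()].
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tensor_nifti(phantom$tensors, file.path(dir, "tensors.nii.gz"))
  write_fa_nifti(phantom$fa, file.path(dir, "fa.nii.gz"))
  write_mask_nifti(binary_mask(phantom$tensors$mask, phantom$tensors$affine),
                   file.path(dir, "mask.nii.gz"))
  write_nifti_array(phantom$truth, phantom$tensors$affine,
                    file.path(dir, "truth.nii.gz"))
  invisible(dir)
}
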