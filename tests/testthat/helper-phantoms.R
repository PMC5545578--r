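# Shared phantom fixtures, built in code at test time.

# single straight bundle along +x through the grid center
straight_bundle_phantom <- function(fa_in = 0.8, fa_bg = 0.05,
                                    half_len = 10, radius = 2.5,
                                    grid = c(30L, 16L, 16L)) {
  phantom_spec(grid, bundles = list(
    bundle(c(-half_len, 0, 0), c(half_len, 0, 0), radius, fa_in)),
    background_fa = fa_bg)
}

# contiguous two-arm elbow built directly as a tensor field: arm A runs along
# +y below the apex plane (world y <= 0), arm B continues from the apex at
# `turn_deg` from +y in the xy-plane. The direction changes across one voxel
# boundary, so only the turning-angle rule can stop a streamline there.
elbow_field <- function(turn_deg = 60, fa_in = 0.7, fa_bg = 0.05,
                        halfwidth = 2, arm_len = 10, grid = c(32L, 32L, 8L)) {
  th <- turn_deg * pi / 180
  d2 <- c(sin(th), cos(th), 0)
  affine <- make_affine(c(1, 1, 1), grid)
  nvox <- prod(grid)
  xyz <- hemiconn:::world_from_voxel(affine, arrayInd(seq_len(nvox), grid))
  inA <- xyz[, 2] <= 0 & xyz[, 2] >= -arm_len &
    abs(xyz[, 1]) <= halfwidth & abs(xyz[, 3]) <= halfwidth
  tB <- xyz %*% d2
  perpB <- xyz - tB %*% t(d2)
  inB <- xyz[, 2] > 0 & tB > 0 & tB <= arm_len &
    sqrt(rowSums(perpB^2)) <= halfwidth
  t6 <- function(dir, fa) hemiconn:::cyl_tensor6(dir, fa)
  tens <- matrix(rep(t6(c(1, 0, 0), fa_bg), each = nvox), nvox, 6)
  tens[inA, ] <- rep(t6(c(0, 1, 0), fa_in), each = sum(inA))
  tens[inB, ] <- rep(t6(d2, fa_in), each = sum(inB))
  list(tensors = tensor_volume(array(tens, c(grid, 6)), affine),
       d2 = d2, inA = array(inA, grid), inB = array(inB, grid))
}

# bilaterally mirror-symmetric phantom: one bundle per hemisphere running
# along +y at x = +/- x0, with per-side FA; axis-aligned so the tensor field
# is exactly flip-symmetric in floating point when fa_right == fa_left
hemi_pair_phantom <- function(fa_right = 0.7, fa_left = 0.7, x0 = 6.5,
                              grid = c(24L, 24L, 12L)) {
  phantom_spec(grid, bundles = list(
    bundle(c(x0, -8, 0), c(x0, 8, 0), 1.6, fa_right),
    bundle(c(-x0, -8, 0), c(-x0, 8, 0), 1.6, fa_left)),
    background_fa = 0.05)
}

# run the full track -> parcellate -> build -> metrics chain on a hemi-pair
# phantom; returns left/right metric lists
hemi_chain_metrics <- function(spec, n_rois = 6L, seed = 1L) {
  ph <- make_tensor_phantom(spec)
  mask <- binary_mask(ph$fa$data >= 0.2, ph$fa$affine)
  labels <- build_parcellation(mask, n_rois = n_rois, seed = seed)
  sl <- fact_track(ph$tensors)
  right <- build_network(sl, labels, ph$fa, "right")
  left <- build_network(sl, labels, ph$fa, "left")
  list(right = network_metrics(right), left = network_metrics(left),
       nets = list(right = right, left = left), labels = labels,
       streamlines = sl, phantom = ph)
}

# small covariate frame of pure noise
noise_covariates <- function(n) {
  data.frame(age = rnorm(n, 75, 6), sex = rbinom(n, 1, 0.5),
             icv_diff = rnorm(n, 0, 1e4), tr = rnorm(n, 12500, 400),
             te = rnorm(n, 68, 3))
}

group_noise_covariates <- function(n) {
  cbind(noise_covariates(n), whole_icv = rnorm(n, 1.45e6, 1.3e5))
}
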