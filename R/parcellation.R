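#' Symmetrize a binary mask about the midsagittal plane
#'
#' Flips the mask along the x-axis and combines it with the original so the
#' result is exactly invariant under the flip. The grid must be flip-alignable:
#' the affine's x-axis must be grid-aligned (no rotation mixing x with y/z)
#' and the grid centered on the midplane, so that reversing the first array
#' index maps world x to -x exactly.
#'
#' The combine rule for the original and flipped masks defaults to `union`
#' (a voxel is kept if present in either), which preserves coverage;
#' `intersection` is available for a stricter template.
#'
#' @param mask a [binary_mask()].
#' @param combine `"union"` or `"intersection"`.
#' @return a symmetric `binary_mask`.
#' @export
symmetrize_mask <- function(mask, combine = c("union", "intersection")) {
  combine <- match.arg(combine)
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$data)) stop("mask nonempty: the input mask has no voxels")
  check_flip_alignable(mask$affine, dim(mask$data)[1])
  flipped <- flip_x(mask$data)
  out <- if (combine == "union") mask$data | flipped else mask$data & flipped
  binary_mask(out, mask$affine)
}

flip_x <- function(arr) arr[dim(arr)[1]:1, , , drop = FALSE]

check_flip_alignable <- function(affine, nx, tol = 1e-6) {
  offaxis <- c(affine[1, 2:3], affine[2:3, 1])
  if (any(abs(offaxis) > tol))
    stop("grid is not flip-alignable: the x-axis is not grid-aligned; ",
         "resample the volume onto an axis-aligned grid first")
  # reversing index i (0-based) must negate world x: requires t_x = -a*(nx-1)/2
  if (abs(affine[1, 4] + affine[1, 1] * (nx - 1) / 2) > tol)
    stop("grid is not flip-alignable: voxel columns are not centered on the ",
         "midsagittal plane (world x = 0); resample the volume first")
  invisible(TRUE)
}

# linear indices of mask voxels lying strictly in one hemisphere
# (world x < 0 = left, x > 0 = right; x = 0 columns excluded)
hemisphere_indices <- function(mask, side = c("right", "left")) {
  side <- match.arg(side)
  dims <- dim(mask$data)
  xw <- axis_x_world(mask$affine, dims[1])
  keep_col <- if (side == "right") xw > 0 else xw < 0
  sel <- array(keep_col, dims) & mask$data  # recycles along x, the first dim
  which(sel)
}

#' Randomly partition one hemisphere into equal-sized connected ROIs
#'
#' Seeded region growing: `n_rois` seed voxels are drawn uniformly without
#' replacement from the hemisphere mask, then ROIs grow by single-voxel
#' accretion under 6-connectivity, always extending the currently smallest
#' ROI and breaking ties by lowest linear voxel index. This keeps ROI sizes
#' near-equal by construction and is fully deterministic given the seed.
#' Voxels unreachable from any seed (disconnected fragments) are assigned to
#' the ROI with the nearest centroid, guaranteeing a tiling of the mask.
#'
#' @param mask a symmetric [binary_mask()].
#' @param hemisphere which side to partition (`"right"`, the template side).
#' @param n_rois number of ROIs (the full-template default is 512 per
#'   hemisphere).
#' @param seed RNG seed for the seed-voxel draw.
#' @return a `label_volume` with labels `1..n_rois` confined to the chosen
#'   hemisphere.
#' @export
random_partition <- function(mask, hemisphere = "right", n_rois = 512L,
                             seed = 1L) {
  stopifnot(inherits(mask, "binary_mask"), n_rois >= 1)
  dims <- dim(mask$data)
  vox <- hemisphere_indices(mask, hemisphere)
  if (length(vox) < n_rois)
    stop(sprintf("hemisphere mask has %d voxels, fewer than n_rois = %d",
                 length(vox), n_rois))
  inhemi <- logical(prod(dims)); inhemi[vox] <- TRUE

  comp_sizes <- connected_component_sizes(vox, inhemi, dims)
  if (length(comp_sizes) > n_rois)
    stop(sprintf(
      "hemisphere mask splits into %d connected components, more than n_rois = %d (component sizes: %s)",
      length(comp_sizes), n_rois, paste(comp_sizes, collapse = ", ")))

  label <- integer(prod(dims))
  seeds <- with_seed(seed, sort(sample(vox, n_rois)))
  label[seeds] <- seq_len(n_rois)
  size <- rep(1L, n_rois)
  frontier <- lapply(seeds, function(s) {
    nb <- neighbors6(s, dims)
    nb[inhemi[nb] & label[nb] == 0L]
  })
  active <- rep(TRUE, n_rois)
  while (any(active)) {
    act <- which(active)
    r <- act[which.min(size[act])]          # ROI ties: lowest id
    cand <- frontier[[r]]
    cand <- cand[label[cand] == 0L]
    if (!length(cand)) { active[r] <- FALSE; next }
    v <- min(cand)                          # voxel ties: lowest linear index
    label[v] <- r
    size[r] <- size[r] + 1L
    nb <- neighbors6(v, dims)
    frontier[[r]] <- c(cand[cand != v], nb[inhemi[nb] & label[nb] == 0L])
  }

  orphans <- vox[label[vox] == 0L]
  if (length(orphans)) {
    cent <- roi_centroids(label, vox, n_rois, dims)
    oij <- arrayInd(orphans, dims)
    for (q in seq_along(orphans)) {
      d2 <- colSums((t(cent) - as.numeric(oij[q, ]))^2)
      label[orphans[q]] <- which.min(d2)    # ties: lowest ROI id
    }
  }
  label_volume(array(label, dims), mask$affine, n_rois, hemisphere = hemisphere)
}

connected_component_sizes <- function(vox, inset, dims) {
  seen <- logical(length(inset))
  sizes <- integer(0)
  for (v in vox) {
    if (seen[v]) next
    queue <- v; seen[v] <- TRUE; n <- 0L
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]; n <- n + 1L
      nb <- neighbors6(cur, dims)
      nb <- nb[inset[nb] & !seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    sizes <- c(sizes, n)
  }
  sort(sizes, decreasing = TRUE)
}

roi_centroids <- function(label, vox, n_rois, dims) {
  ij <- arrayInd(vox, dims)
  lab <- label[vox]
  cent <- matrix(NA_real_, n_rois, 3)
  for (r in seq_len(n_rois)) {
    sel <- lab == r
    if (any(sel)) cent[r, ] <- colMeans(ij[sel, , drop = FALSE])
  }
  cent
}

#' Mirror a right-hemisphere parcellation into the left hemisphere
#'
#' Flips the right-hemisphere label grid along the x-axis to produce the left
#' hemisphere, yielding the bilateral template. Left labels are offset by
#' `n_rois`, and the homolog map records the one-to-one correspondence
#' between mirrored ROI pairs that permits direct comparison of the two
#' hemispheric networks.
#'
#' @param right_labels a right-hemisphere `label_volume` from
#'   [random_partition()].
#' @return a bilateral `label_volume` with populated `homologs`.
#' @export
mirror_parcellation <- function(right_labels) {
  stopifnot(inherits(right_labels, "label_volume"))
  if (right_labels$hemisphere != "right")
    stop("mirror_parcellation expects a right-hemisphere parcellation")
  dims <- dim(right_labels$data)
  check_flip_alignable(right_labels$affine, dims[1])
  xw <- axis_x_world(right_labels$affine, dims[1])
  bad_cols <- which(xw <= 0)
  if (length(bad_cols)) {
    straddle <- unique(as.vector(right_labels$data[bad_cols, , ]))
    straddle <- straddle[straddle > 0L]
    if (length(straddle))
      stop("labels straddling the midplane: ",
           paste(sort(straddle), collapse = ", "))
  }
  n <- right_labels$n_rois
  lf <- flip_x(right_labels$data)
  lf[lf > 0L] <- lf[lf > 0L] + n
  out <- right_labels$data + lf    # disjoint supports: strict x>0 vs x<0
  label_volume(out, right_labels$affine, n, hemisphere = "bilateral",
               homologs = data.frame(right_label = seq_len(n),
                                     left_label = seq_len(n) + n))
}

#' One-call bilateral template construction
#'
#' Convenience wrapper: symmetrize the mask, randomly partition the right
#' hemisphere, and mirror it into the left.
#'
#' @inheritParams symmetrize_mask
#' @inheritParams random_partition
#' @return a bilateral `label_volume`.
#' @export
build_parcellation <- function(mask, n_rois = 512L, seed = 1L,
                               combine = "union") {
  sym <- symmetrize_mask(mask, combine)
  mirror_parcellation(random_partition(sym, "right", n_rois, seed))
}
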