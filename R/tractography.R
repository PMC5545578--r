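#' Fractional anisotropy from tensor eigenvalues
#'
#' `FA = sqrt(3/2) * sqrt(sum((lambda_i - mean)^2)) / sqrt(sum(lambda_i^2))`.
#' FA is 0 for an all-zero tensor by convention. Small negative eigenvalues
#' within `tol` (numerical noise) are clamped to zero; larger ones are an
#' error, since a diffusion tensor is positive semi-definite.
#'
#' @param lambda numeric length-3 eigenvalues.
#' @param tol tolerance for negative eigenvalues.
#' @return FA in `[0, 1]`.
#' @export
fractional_anisotropy <- function(lambda, tol = 1e-8) {
  stopifnot(length(lambda) == 3)
  if (any(lambda < -tol * max(abs(lambda), 1)))
    stop("negative eigenvalue beyond tolerance: tensor is not PSD")
  lambda <- pmax(lambda, 0)
  s2 <- sum(lambda^2)
  if (s2 == 0) return(0)
  lbar <- mean(lambda)
  min(sqrt(1.5) * sqrt(sum((lambda - lbar)^2) / s2), 1)
}

# principal eigenvector field for voxels above the FA threshold;
# array [x, y, z, 3], NA elsewhere
principal_directions <- function(tensors, fa, fa_stop) {
  dims <- dim(tensors$data)[1:3]
  m <- matrix(tensors$data, prod(dims), 6)
  sel <- which(as.vector(fa$data) >= fa_stop & as.vector(tensors$mask))
  out <- array(NA_real_, c(prod(dims), 3))
  for (v in sel) {
    D <- matrix(c(m[v, 1], m[v, 2], m[v, 3],
                  m[v, 2], m[v, 4], m[v, 5],
                  m[v, 3], m[v, 5], m[v, 6]), 3, 3)
    out[v, ] <- eigen(D, symmetric = TRUE)$vectors[, 1]
  }
  array(out, c(dims, 3))
}

#' Deterministic FACT-style streamline tracking
#'
#' Propagates streamlines along the per-voxel principal diffusion direction
#' (nearest-voxel lookup, no interpolation), bidirectionally from each seed,
#' with the two classical stopping rules: tracking stops when the next
#' position falls in a voxel with `FA < fa_stop` (default 0.2) or when the
#' angle between consecutive path segments exceeds `angle_stop` degrees
#' (default 45). The eigenvector sign at each step is chosen to minimize
#' turning. Tracking is fully deterministic: identical inputs yield identical
#' streamline sets.
#'
#' Seeds default to one per in-mask voxel with `FA >= fa_stop` (whole-brain
#' seeding). A seed in a sub-threshold voxel yields a single-point streamline
#' of length 0 (recorded, not an error). `max_len` is a numerical guard
#' against cycles, not a biological constraint.
#'
#' @param tensors a [tensor_volume()].
#' @param seeds optional integer matrix of 1-based voxel indices (n x 3);
#'   default: all suprathreshold in-mask voxels.
#' @param fa_stop FA termination threshold, in `(0, 1)`.
#' @param angle_stop turning-angle threshold in degrees, in `(0, 90]`.
#' @param step step length in mm; default half the smallest voxel dimension.
#' @param max_len maximum half-track length in mm.
#' @return an object of class `streamlines`: a list of point matrices
#'   (world mm, one row per point) each carrying a `seed` attribute.
#' @export
fact_track <- function(tensors, seeds = NULL, fa_stop = 0.2, angle_stop = 45,
                       step = NULL, max_len = 300) {
  stopifnot(inherits(tensors, "tensor_volume"))
  if (fa_stop <= 0 || fa_stop >= 1) stop("fa_stop must lie in (0, 1)")
  if (angle_stop <= 0 || angle_stop > 90) stop("angle_stop must lie in (0, 90]")
  if (any(!is.finite(tensors$data))) {
    bad <- arrayInd(which(!is.finite(tensors$data))[1], dim(tensors$data))
    stop(sprintf("non-finite tensor at voxel (%d, %d, %d)",
                 bad[1], bad[2], bad[3]))
  }
  dims <- dim(tensors$data)[1:3]
  affine <- tensors$affine
  fa <- fa_map(tensors)
  if (is.null(step)) step <- min(voxel_sizes(affine)) / 2
  stopifnot(step > 0)
  dirfield <- principal_directions(tensors, fa, fa_stop)
  dirmat <- matrix(dirfield, prod(dims), 3)
  favec <- as.vector(fa$data)
  maskvec <- as.vector(tensors$mask)

  if (is.null(seeds)) {
    seeds <- arrayInd(which(favec >= fa_stop & maskvec), dims)
  }
  seeds <- matrix(as.integer(seeds), ncol = 3)
  cos_stop <- cos(angle_stop * pi / 180)
  maxsteps <- ceiling(max_len / step)
  inv_aff <- solve(affine)

  lin <- function(ijk) (ijk[3] - 1L) * dims[1] * dims[2] +
    (ijk[2] - 1L) * dims[1] + ijk[1]

  track_half <- function(p0, dir) {
    pts <- matrix(0, maxsteps, 3)
    np <- 0L
    pos <- p0
    repeat {
      if (np >= maxsteps) break
      pn <- pos + step * dir
      v <- as.integer(round((inv_aff[1:3, ] %*% c(pn, 1)) + 1))
      if (!in_grid(v, dims)) break
      vl <- lin(v)
      if (!maskvec[vl] || favec[vl] < fa_stop) break
      np <- np + 1L
      pts[np, ] <- pn
      nd <- dirmat[vl, ]
      dp <- sum(nd * dir)
      if (dp < 0) { nd <- -nd; dp <- -dp }
      if (dp < cos_stop - 1e-12) break   # turn exceeds angle_stop; pn is last
      dir <- nd
      pos <- pn
    }
    pts[seq_len(np), , drop = FALSE]
  }

  out <- vector("list", nrow(seeds))
  for (s in seq_len(nrow(seeds))) {
    v <- seeds[s, ]
    p0 <- as.vector(world_from_voxel(affine, matrix(v, 1)))
    vl <- lin(v)
    if (!in_grid(v, dims) || !maskvec[vl] || favec[vl] < fa_stop) {
      sl <- matrix(p0, 1)                 # sub-threshold seed: length 0
    } else {
      d0 <- dirmat[vl, ]
      fwd <- track_half(p0, d0)
      bwd <- track_half(p0, -d0)
      sl <- rbind(bwd[rev(seq_len(nrow(bwd))), , drop = FALSE],
                  matrix(p0, 1), fwd)
    }
    attr(sl, "seed") <- v
    out[[s]] <- sl
  }
  structure(out, class = "streamlines",
            fa_stop = fa_stop, angle_stop = angle_stop, step = step)
}

#' @export
print.streamlines <- function(x, ...) {
  npts <- vapply(x, nrow, 1L)
  cat(sprintf("<streamlines> %d tracks (%d with >= 2 points), step %.3g mm\n",
              length(x), sum(npts >= 2), attr(x, "step")))
  invisible(x)
}

#' Streamline length in mm
#' @param s a single streamline point matrix.
#' @export
streamline_length <- function(s) {
  if (nrow(s) < 2) return(0)
  sum(sqrt(rowSums(diff(s)^2)))
}

#' Write / read streamlines as JSON-lines
#'
#' One JSON object per line with the seed voxel and the point coordinates;
#' a plain-text interchange and debugging format.
#'
#' @param streamlines a `streamlines` object.
#' @param file output path.
#' @export
write_streamlines_jsonl <- function(streamlines, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (s in streamlines) {
    writeLines(jsonlite::toJSON(list(seed = attr(s, "seed"),
                                     points = unname(s)),
                                digits = NA), con)
  }
  invisible(file)
}

#' @rdname write_streamlines_jsonl
#' @export
read_streamlines_jsonl <- function(file) {
  lines <- readLines(file)
  out <- lapply(lines, function(l) {
    o <- jsonlite::fromJSON(l)
    m <- matrix(as.numeric(o$points), ncol = 3)
    attr(m, "seed") <- as.integer(o$seed)
    m
  })
  structure(out, class = "streamlines")
}
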