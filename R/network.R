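#' Hemispheric network container
#'
#' An intra-hemispheric weighted network: `weights` is the N x N symmetric
#' FA-weight matrix (zero diagonal, entries in `[0, 1]`), `counts` the
#' matching streamline-count matrix. Node `i` is the ROI with homolog index
#' `i` in the bilateral template, so left and right networks of one subject
#' share a node set and are directly comparable.
#'
#' @param weights N x N symmetric nonnegative matrix, zero diagonal.
#' @param counts optional N x N integer matrix (defaults to `weights > 0`).
#' @param hemisphere `"left"` or `"right"`.
#' @export
hemispheric_network <- function(weights, counts = NULL,
                                hemisphere = c("right", "left")) {
  hemisphere <- match.arg(hemisphere)
  weights <- as.matrix(weights)
  n <- nrow(weights)
  stopifnot(ncol(weights) == n)
  if (any(abs(weights - t(weights)) > 1e-12)) stop("weight matrix must be symmetric")
  if (any(diag(weights) != 0)) stop("weight matrix must have a zero diagonal")
  if (any(weights < 0) || any(weights > 1 + 1e-12))
    stop("weights must lie in [0, 1]")
  if (is.null(counts)) counts <- (weights > 0) * 1L
  structure(list(weights = weights, counts = counts, hemisphere = hemisphere,
                 n_nodes = n),
            class = "hemispheric_network")
}

#' @export
print.hemispheric_network <- function(x, ...) {
  ne <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("<hemispheric_network> %s, %d nodes, %d edges\n",
              x$hemisphere, x$n_nodes, ne))
  invisible(x)
}

#' Assign a streamline's endpoints to ROI pairs
#'
#' Looks up the ROI labels containing the two terminal points of a streamline
#' (nearest-voxel). Returns `NULL` ("none") when either endpoint is
#' unlabelled or outside the grid, when both endpoints fall in one ROI
#' (self-loop), or when the two ROIs lie in different hemispheres — the
#' hemispheric networks are intra-hemispheric by construction.
#'
#' @param s a streamline point matrix (world mm, >= 2 points).
#' @param labels a bilateral [label_volume()].
#' @return integer length-2 label pair, or `NULL`.
#' @export
assign_endpoints <- function(s, labels) {
  stopifnot(inherits(labels, "label_volume"))
  if (nrow(s) < 2) return(NULL)
  dims <- dim(labels$data)
  ep <- nearest_voxel(labels$affine, s[c(1, nrow(s)), , drop = FALSE])
  lab <- integer(2)
  for (q in 1:2) {
    v <- ep[q, ]
    lab[q] <- if (in_grid(v, dims)) labels$data[v[1], v[2], v[3]] else 0L
  }
  if (any(lab == 0L)) return(NULL)
  if (lab[1] == lab[2]) return(NULL)
  if (label_side(labels, lab[1]) != label_side(labels, lab[2])) return(NULL)
  lab
}

#' Build one FA-weighted hemispheric network from streamlines
#'
#' Streamlines whose endpoints fall in two distinct ROIs of the requested
#' hemisphere contribute to the connection between those nodes. The edge
#' weight is the mean FA of the connected fibers: FA is sampled at every
#' point of every connecting streamline (nearest-voxel lookup, consistent
#' with the non-interpolating tracker) and pooled across streamlines of an
#' ROI pair. An edge is kept when at least `edge_min_fibers` streamlines
#' connect the pair; the strict "more than one fiber" reading corresponds to
#' `edge_min_fibers = 2`.
#'
#' @param streamlines a `streamlines` object.
#' @param labels a bilateral `label_volume`.
#' @param fa an [fa_volume()] sharing the label grid.
#' @param hemisphere which network to build.
#' @param edge_min_fibers minimum streamline count per edge (default 1).
#' @return a [hemispheric_network()] with attributes `dropped_fibers`
#'   (streamlines with unlabelled/outside endpoints) recorded.
#' @export
build_network <- function(streamlines, labels, fa,
                          hemisphere = c("right", "left"),
                          edge_min_fibers = 1L) {
  hemisphere <- match.arg(hemisphere)
  stopifnot(inherits(labels, "label_volume"), inherits(fa, "fa_volume"))
  if (!isTRUE(all.equal(labels$affine, fa$affine, tolerance = 1e-8)) ||
      !identical(dim(labels$data), dim(fa$data)))
    stop("labels and FA volume must share a grid and affine")
  n <- labels$n_rois
  C <- matrix(0L, n, n)
  S <- matrix(0, n, n)    # summed FA samples
  P <- matrix(0, n, n)    # sample counts
  dims <- dim(fa$data)
  dropped <- 0L
  offset <- if (hemisphere == "right") 0L else n
  for (s in streamlines) {
    if (nrow(s) < 2) next
    pair <- assign_endpoints(s, labels)
    if (is.null(pair)) { dropped <- dropped + 1L; next }
    if (label_side(labels, pair[1]) != hemisphere) next
    i <- min(pair) - offset
    j <- max(pair) - offset
    vx <- nearest_voxel(fa$affine, s)
    keep <- vx[, 1] >= 1 & vx[, 1] <= dims[1] &
      vx[, 2] >= 1 & vx[, 2] <= dims[2] &
      vx[, 3] >= 1 & vx[, 3] <= dims[3]
    vx <- vx[keep, , drop = FALSE]
    favals <- fa$data[vx]
    C[i, j] <- C[i, j] + 1L
    S[i, j] <- S[i, j] + sum(favals)
    P[i, j] <- P[i, j] + length(favals)
  }
  if (all(C == 0L))
    warning("no streamline connected any ROI pair; returning all-zero matrices")
  W <- matrix(0, n, n)
  keep <- C >= edge_min_fibers & P > 0
  W[keep] <- S[keep] / P[keep]
  W <- W + t(W)
  C <- C + t(C)
  net <- hemispheric_network(W, C, hemisphere)
  attr(net, "dropped_fibers") <- dropped
  net
}

#' Write / read a network's matrices as delimited text
#'
#' Weight and count matrices as whitespace-delimited text with full numeric
#' precision.
#'
#' @param net a `hemispheric_network`.
#' @param weights_file,counts_file output paths (`counts_file` optional).
#' @export
write_network <- function(net, weights_file, counts_file = NULL) {
  utils::write.table(format(net$weights, digits = 17, trim = TRUE),
                     weights_file, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  if (!is.null(counts_file))
    utils::write.table(net$counts, counts_file, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  invisible(weights_file)
}

#' @rdname write_network
#' @param hemisphere hemisphere tag to attach on read.
#' @export
read_network <- function(weights_file, counts_file = NULL,
                         hemisphere = "right") {
  W <- as.matrix(utils::read.table(weights_file))
  dimnames(W) <- NULL
  C <- if (!is.null(counts_file)) {
    cc <- as.matrix(utils::read.table(counts_file)); dimnames(cc) <- NULL; cc
  } else NULL
  hemispheric_network(W, C, hemisphere)
}
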