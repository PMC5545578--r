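#' Volume containers
#'
#' Lightweight S3 containers for the image-like objects moving through the
#' pipeline. All carry a 4x4 affine mapping 0-based voxel indices to world
#' coordinates in mm (NIfTI convention); array storage is 1-based R style.
#'
#' * `tensor_volume`: per-voxel symmetric diffusion tensors stored as a
#'   4D array `[x, y, z, 6]` holding the upper-triangle components
#'   (xx, xy, xz, yy, yz, zz), plus a logical brain mask.
#' * `binary_mask`: logical 3D grid.
#' * `fa_volume`: scalar fractional-anisotropy map in `[0, 1]`.
#' * `label_volume`: integer ROI labels, 0 = background. Right-hemisphere
#'   ROIs carry labels `1..n_rois`, left-hemisphere homologs
#'   `n_rois+1..2*n_rois`; `homologs` maps them pairwise.
#'
#' @param data the array (see above per class).
#' @param affine 4x4 voxel-to-world matrix.
#' @param mask logical 3D array (tensor volumes only); defaults to all-TRUE.
#' @param n_rois,hemisphere,homologs label-volume metadata.
#' @name volumes
NULL

#' @rdname volumes
#' @export
tensor_volume <- function(data, affine, mask = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 4, dim(data)[4] == 6)
  if (is.null(mask)) mask <- array(TRUE, dim(data)[1:3])
  stopifnot(identical(dim(mask), dim(data)[1:3]))
  structure(list(data = data, affine = affine, mask = mask),
            class = "tensor_volume")
}

#' @rdname volumes
#' @export
binary_mask <- function(data, affine) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  structure(list(data = array(as.logical(data), dim(data)), affine = affine),
            class = "binary_mask")
}

#' @rdname volumes
#' @export
fa_volume <- function(data, affine) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (any(data < -1e-9 | data > 1 + 1e-9, na.rm = TRUE))
    stop("FA values must lie in [0, 1]")
  structure(list(data = pmin(pmax(data, 0), 1), affine = affine),
            class = "fa_volume")
}

#' @rdname volumes
#' @export
label_volume <- function(data, affine, n_rois,
                         hemisphere = c("right", "left", "bilateral"),
                         homologs = NULL) {
  hemisphere <- match.arg(hemisphere)
  stopifnot(is.array(data), length(dim(data)) == 3)
  storage.mode(data) <- "integer"
  structure(list(data = data, affine = affine, n_rois = as.integer(n_rois),
                 hemisphere = hemisphere, homologs = homologs),
            class = "label_volume")
}

# hemisphere of a label id under the right = 1..n, left = n+1..2n convention
label_side <- function(labels, lab) {
  ifelse(lab == 0L, NA_character_,
         ifelse(lab <= labels$n_rois, "right", "left"))
}

#' @export
print.tensor_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<tensor_volume> %d x %d x %d voxels, %d in mask\n",
              d[1], d[2], d[3], sum(x$mask)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s, %d ROIs/hemisphere, %d labelled voxels\n",
              x$hemisphere, x$n_rois, sum(x$data > 0L)))
  invisible(x)
}

# ---- NIfTI IO -------------------------------------------------------------

#' Read and write pipeline volumes as NIfTI
#'
#' Scalar volumes (masks, FA, labels) are stored as 3D NIfTI images; tensor
#' volumes as 4D images whose fourth dimension holds the six upper-triangle
#' components (xx, xy, xz, yy, yz, zz). The affine is written to the sform.
#'
#' @param x a volume container.
#' @param file path to a `.nii` or `.nii.gz` file.
#' @return `read_*` return the corresponding container.
#' @name nifti_io
NULL

write_nifti_array <- function(arr, affine, file) {
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, file)
  invisible(file)
}

read_nifti_array <- function(file) {
  img <- RNifti::readNifti(file)
  list(data = array(as.numeric(img), dim(img)),
       affine = structure(RNifti::xform(img), dim = c(4, 4))[1:4, 1:4])
}

#' @rdname nifti_io
#' @export
write_mask_nifti <- function(x, file) {
  stopifnot(inherits(x, "binary_mask"))
  write_nifti_array(array(as.integer(x$data), dim(x$data)), x$affine, file)
}

#' @rdname nifti_io
#' @export
read_mask_nifti <- function(file) {
  r <- read_nifti_array(file)
  binary_mask(r$data != 0, r$affine)
}

#' @rdname nifti_io
#' @export
write_fa_nifti <- function(x, file) {
  stopifnot(inherits(x, "fa_volume"))
  write_nifti_array(x$data, x$affine, file)
}

#' @rdname nifti_io
#' @export
read_fa_nifti <- function(file) {
  r <- read_nifti_array(file)
  fa_volume(r$data, r$affine)
}

#' @rdname nifti_io
#' @export
write_tensor_nifti <- function(x, file) {
  stopifnot(inherits(x, "tensor_volume"))
  write_nifti_array(x$data, x$affine, file)
}

#' @rdname nifti_io
#' @param mask_file optional path to a companion brain-mask NIfTI.
#' @export
read_tensor_nifti <- function(file, mask_file = NULL) {
  r <- read_nifti_array(file)
  mask <- if (!is.null(mask_file)) read_mask_nifti(mask_file)$data else NULL
  tensor_volume(r$data, r$affine, mask)
}

#' @rdname nifti_io
#' @export
write_labels_nifti <- function(x, file) {
  stopifnot(inherits(x, "label_volume"))
  write_nifti_array(x$data, x$affine, file)
}

#' @rdname nifti_io
#' @param n_rois,hemisphere,homologs metadata to attach on read (labels
#'   themselves carry no sidecar in NIfTI).
#' @export
read_labels_nifti <- function(file, n_rois, hemisphere = "bilateral",
                              homologs = NULL) {
  r <- read_nifti_array(file)
  label_volume(array(as.integer(round(r$data)), dim(r$data)), r$affine,
               n_rois, hemisphere, homologs)
}

#' Write / read the homologous-node map
#'
#' Two-column tab-separated table pairing each right-hemisphere label with its
#' mirrored left-hemisphere label.
#' @param labels a bilateral `label_volume`.
#' @param file path to a `.tsv` file.
#' @export
write_homologs <- function(labels, file) {
  stopifnot(inherits(labels, "label_volume"), !is.null(labels$homologs))
  utils::write.table(labels$homologs, file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' @rdname write_homologs
#' @export
read_homologs <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t")
}
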