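#' fMRI data containers
#'
#' Lightweight containers used throughout the package: a 4D fMRI volume with
#' its voxel-to-world affine and repetition time, a 3D map, a binary brain
#' mask, and an integer label atlas with a label table.
#'
#' @param data numeric array (4D for \code{image4d}, 3D otherwise; integer
#'   labels with 0 = background for \code{label_atlas}; nonzero = in-mask for
#'   \code{brain_mask}).
#' @param affine 4x4 voxel-to-world matrix (mm), 0-based voxel indices.
#' @param repetition_time repetition time in seconds (\code{image4d} only).
#' @param label_table data.frame with columns \code{label} and \code{name};
#'   defaults to "region_<label>" names.
#' @return an object of the corresponding class.
#' @name containers
NULL

#' @rdname containers
#' @export
image4d <- function(data, affine = diag(4), repetition_time = 2.4) {
  stopifnot(length(dim(data)) == 4L, dim(data)[4L] >= 2L,
            is.matrix(affine), all(dim(affine) == c(4L, 4L)),
            repetition_time > 0)
  if (abs(det(affine)) < .Machine$double.eps) stop("affine is singular")
  structure(list(data = data, affine = affine,
                 repetition_time = repetition_time),
            class = "image4d")
}

#' @rdname containers
#' @export
image3d <- function(data, affine = diag(4)) {
  stopifnot(length(dim(data)) == 3L, all(dim(affine) == c(4L, 4L)))
  structure(list(data = data, affine = affine), class = "image3d")
}

#' @rdname containers
#' @export
brain_mask <- function(data, affine = diag(4)) {
  stopifnot(length(dim(data)) == 3L)
  data <- array(as.numeric(data != 0), dim(data))
  if (sum(data) < 1) stop("mask has no in-mask voxels")
  structure(list(data = data, affine = affine), class = "brain_mask")
}

#' @rdname containers
#' @export
label_atlas <- function(data, affine = diag(4), label_table = NULL) {
  stopifnot(length(dim(data)) == 3L)
  if (any(data < 0) || any(data != round(data)))
    stop("atlas labels must be non-negative integers")
  data <- array(as.integer(round(data)), dim(data))
  labs <- sort(unique(data[data > 0]))
  if (is.null(label_table))
    label_table <- data.frame(label = labs,
                              name = sprintf("region_%d", labs),
                              stringsAsFactors = FALSE)
  if (!all(labs %in% label_table$label))
    stop("every nonzero voxel label must appear in label_table")
  if (anyDuplicated(label_table$label)) stop("duplicate labels in label_table")
  rownames(label_table) <- NULL
  # the table may carry labels with no voxels (e.g. emptied by resampling);
  # downstream extraction flags them as missing
  structure(list(data = data, affine = affine, label_table = label_table),
            class = "label_atlas")
}

#' @export
print.image4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image4d> %d x %d x %d voxels, %d timepoints, TR = %g s\n",
              d[1], d[2], d[3], d[4], x$repetition_time))
  invisible(x)
}

#' @export
print.label_atlas <- function(x, ...) {
  cat(sprintf("<label_atlas> %s grid, %d regions\n",
              paste(dim(x$data), collapse = " x "), nrow(x$label_table)))
  invisible(x)
}

#' Read / write images as NIfTI-1
#'
#' 3D and 4D volumes round-trip through NIfTI-1 files; the repetition time is
#' stored in (and read from) the time-axis pixdim, overridable on read.
#' Atlases also write a sidecar TSV label table (columns \code{label},
#' \code{name}) next to the image.
#'
#' @param x object to write.
#' @param path file path (\code{.nii} or \code{.nii.gz}).
#' @param repetition_time optional override of the header repetition time (s).
#' @param label_table_path sidecar TSV path; defaults to
#'   \code{<path without extension>_labels.tsv}.
#' @name nifti_io
NULL

#' @rdname nifti_io
#' @export
write_image <- function(x, path) {
  UseMethod("write_image")
}

#' @export
write_image.image4d <- function(x, path) {
  im <- RNifti::asNifti(x$data)
  im <- RNifti::`pixdim<-`(im, c(1, 1, 1, x$repetition_time))
  im <- RNifti::`sform<-`(im, structure(x$affine, code = 2L))
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' @export
write_image.image3d <- function(x, path) {
  im <- RNifti::asNifti(x$data)
  im <- RNifti::`sform<-`(im, structure(x$affine, code = 2L))
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' @export
write_image.brain_mask <- write_image.image3d

#' @rdname nifti_io
#' @export
write_atlas <- function(x, path, label_table_path = NULL) {
  stopifnot(inherits(x, "label_atlas"))
  im <- RNifti::asNifti(array(as.numeric(x$data), dim(x$data)))
  im <- RNifti::`sform<-`(im, structure(x$affine, code = 2L))
  RNifti::writeNifti(im, path)
  if (is.null(label_table_path))
    label_table_path <- paste0(sub("\\.nii(\\.gz)?$", "", path), "_labels.tsv")
  utils::write.table(x$label_table, label_table_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_image4d <- function(path, repetition_time = NULL) {
  im <- RNifti::readNifti(path)
  a <- unclass(im)
  stopifnot(length(dim(a)) == 4L)
  tr <- if (!is.null(repetition_time)) repetition_time else
    RNifti::pixdim(im)[4L]
  if (!is.finite(tr) || tr <= 0) tr <- 2.4
  image4d(array(as.numeric(a), dim(a)), affine = .affine_of(im),
          repetition_time = tr)
}

#' @rdname nifti_io
#' @export
read_image3d <- function(path) {
  im <- RNifti::readNifti(path)
  a <- unclass(im)
  stopifnot(length(dim(a)) == 3L)
  image3d(array(as.numeric(a), dim(a)), affine = .affine_of(im))
}

#' @rdname nifti_io
#' @export
read_mask <- function(path) {
  m <- read_image3d(path)
  brain_mask(m$data, m$affine)
}

#' @rdname nifti_io
#' @export
read_atlas <- function(path, label_table_path = NULL) {
  m <- read_image3d(path)
  if (is.null(label_table_path)) {
    cand <- paste0(sub("\\.nii(\\.gz)?$", "", path), "_labels.tsv")
    label_table_path <- if (file.exists(cand)) cand else NULL
  }
  tab <- if (!is.null(label_table_path))
    utils::read.table(label_table_path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  else NULL
  label_atlas(round(m$data), m$affine, label_table = tab)
}

.affine_of <- function(im) {
  x <- RNifti::xform(im)
  matrix(as.numeric(x), 4L, 4L)
}
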