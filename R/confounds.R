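#' Framewise displacement from motion parameters
#'
#' Per-volume head-motion summary: the sum of absolute volume-to-volume
#' differences of the six rigid-body motion parameters, with rotations
#' converted to arc displacements on a sphere of the given radius.
#'
#' @param motion T x 6 numeric matrix: three translations (mm) then three
#'   rotations (radians), or the reverse per \code{convention}.
#' @param radius sphere radius in mm (default 50).
#' @param rotation_scale \code{"radius"} (default; arc length = radius x
#'   angle) or \code{"two_pi_radius"} (angle multiplied by 2 pi radius).
#' @param convention column ordering of \code{motion}.
#' @return object of class \code{fd_series}: list with \code{values} (T-1
#'   non-negative displacements, mm), \code{mean_fd}, and \code{flag_high}
#'   (\code{mean_fd > 0.55} mm, the lenient exclusion screen).
#' @export
framewise_displacement <- function(motion, radius = 50,
                                   rotation_scale = c("radius", "two_pi_radius"),
                                   convention = c("translations_first",
                                                  "rotations_first")) {
  rotation_scale <- match.arg(rotation_scale)
  convention <- match.arg(convention)
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("motion must have 6 columns")
  if (nrow(motion) < 2L) stop("need at least 2 timepoints")
  if (!all(is.finite(motion))) stop("non-finite motion parameters")
  if (convention == "rotations_first") motion <- motion[, c(4:6, 1:3)]
  d <- abs(diff(motion))
  scale <- if (rotation_scale == "radius") radius else 2 * pi * radius
  values <- rowSums(d[, 1:3, drop = FALSE]) +
    scale * rowSums(d[, 4:6, drop = FALSE])
  structure(list(values = values, mean_fd = mean(values),
                 flag_high = mean(values) > 0.55,
                 radius = radius, rotation_scale = rotation_scale),
            class = "fd_series")
}

#' @export
print.fd_series <- function(x, ...) {
  cat(sprintf("<fd_series> %d displacements, mean FD = %.3f mm%s\n",
              length(x$values), x$mean_fd,
              if (x$flag_high) " [FLAGGED: mean FD > 0.55 mm]" else ""))
  invisible(x)
}

#' Mean timeseries within a tissue mask
#'
#' Arithmetic mean over in-mask voxels at each timepoint; the standard way to
#' obtain white-matter and CSF nuisance regressors from tissue masks.
#'
#' @param img an \code{image4d}.
#' @param tissue_mask a \code{brain_mask} on the same grid.
#' @return numeric vector of length T.
#' @export
mean_mask_timeseries <- function(img, tissue_mask) {
  stopifnot(inherits(img, "image4d"), inherits(tissue_mask, "brain_mask"))
  dm <- dim(img$data)
  if (!identical(dm[1:3], dim(tissue_mask$data)))
    stop("mask grid does not match image")
  idx <- which(tissue_mask$data != 0)
  Y <- matrix(img$data, nrow = prod(dm[1:3]), ncol = dm[4L])
  colMeans(Y[idx, , drop = FALSE])
}

#' One-step nuisance confound regression
#'
#' Regresses all confound columns out of every voxel timeseries in a single
#' joint ordinary-least-squares fit (an intercept is always included, so
#' residuals are mean-zero). Volumes are never censored; motion is handled by
#' regression plus FD reporting only.
#'
#' @param img an \code{image4d}.
#' @param confounds T x C numeric matrix (named columns recommended): motion
#'   parameters, tissue means, component timeseries, all concatenated.
#' @param mask optional \code{brain_mask}; defaults to all voxels.
#' @return an \code{image4d} of residuals. If the design is rank-deficient
#'   the collinear columns are reported in a warning and the minimum-norm
#'   (pivoted QR) solution is used.
#' @export
regress_confounds <- function(img, confounds, mask = NULL) {
  stopifnot(inherits(img, "image4d"))
  confounds <- as.matrix(confounds)
  dm <- dim(img$data)
  Tn <- dm[4L]
  if (nrow(confounds) != Tn) stop("confounds must have one row per timepoint")
  if (!all(is.finite(confounds))) stop("non-finite confound values")
  if (ncol(confounds) + 1L >= Tn)
    stop("need C + 1 < T for the regression to be identifiable")
  X <- cbind(intercept = 1, confounds)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    warning(sprintf("rank-deficient confound design; collinear column(s): %s",
                    paste(dropped, collapse = ", ")))
  }
  Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
  idx <- if (is.null(mask)) seq_len(prod(dm[1:3])) else which(mask$data != 0)
  Y <- matrix(img$data, nrow = prod(dm[1:3]), ncol = Tn)
  Ym <- t(Y[idx, , drop = FALSE])                    # T x V
  R <- Ym - Q %*% crossprod(Q, Ym)
  out <- matrix(0, nrow = prod(dm[1:3]), ncol = Tn)
  out[idx, ] <- t(R)
  image4d(array(out, dm), img$affine, img$repetition_time)
}

#' Read a 6-column motion trace
#'
#' Whitespace-delimited text, one row per timepoint, columns ordered per the
#' declared convention.
#'
#' @param path file path.
#' @return T x 6 numeric matrix.
#' @export
read_motion <- function(path) {
  m <- as.matrix(utils::read.table(path))
  if (ncol(m) != 6L) stop("motion trace must have 6 columns")
  dimnames(m) <- list(NULL, c("tx", "ty", "tz", "rx", "ry", "rz"))
  m
}

#' @rdname read_motion
#' @param motion T x 6 matrix to write.
#' @export
write_motion <- function(motion, path) {
  utils::write.table(format(motion, digits = 10), path, sep = " ",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
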