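#' Kendall's coefficient of concordance for a block of timeseries
#'
#' Computes Kendall's W over \code{K} timeseries (the "judges") ranking
#' \code{n} timepoints (the "items"). This is the statistic underlying
#' regional homogeneity (ReHo): each voxel's series is rank-transformed over
#' time and W measures the agreement of the rankings.
#'
#' @param block numeric matrix, K x n: one row per timeseries, one column per
#'   timepoint. K >= 2, n >= 2.
#' @param tie_policy \code{"midrank_no_correction"} (default; ties receive
#'   midranks but the tie-correction term is omitted, as in classic ReHo
#'   implementations) or \code{"midrank_tie_correction"} (the tie-corrected
#'   denominator).
#' @return scalar W in [0, 1]. A fully degenerate block (every series
#'   constant) has no defined W; 0 is returned with attribute
#'   \code{degenerate = TRUE}.
#' @details W = 12 S / (K^2 (n^3 - n) - K T), where S is the sum of squared
#'   deviations of the per-timepoint rank sums from their mean and T is the
#'   tie-correction term (0 under \code{midrank_no_correction}).
#' @examples
#' b <- matrix(rep(1:10, each = 5), nrow = 5, byrow = FALSE) # identical rankings
#' kendall_w(rbind(1:10, 1:10, 1:10))
#' @export
kendall_w <- function(block, tie_policy = c("midrank_no_correction",
                                            "midrank_tie_correction")) {
  tie_policy <- match.arg(tie_policy)
  if (!is.matrix(block) || nrow(block) < 2L || ncol(block) < 2L)
    stop("`block` must be a K x n matrix with K >= 2 and n >= 2")
  if (!all(is.finite(block))) stop("`block` contains non-finite values")
  K <- nrow(block); n <- ncol(block)
  ranks <- t(apply(block, 1L, rank))      # midranks over time, per series
  R <- colSums(ranks)                     # rank sum at each timepoint
  S <- sum((R - mean(R))^2)
  Tcorr <- 0
  if (tie_policy == "midrank_tie_correction") {
    Tcorr <- sum(apply(block, 1L, function(x) {
      tt <- table(x); sum(tt^3 - tt)
    }))
  }
  denom <- K^2 * (n^3 - n) - K * Tcorr
  if (denom <= 0) {           # every series constant under the policy
    w <- 0
    attr(w, "degenerate") <- TRUE
    return(w)
  }
  min(max(12 * S / denom, 0), 1)
}

#' Voxelwise regional homogeneity (ReHo) map
#'
#' For every in-mask voxel, computes Kendall's W between the voxel's
#' timeseries and those of its in-mask neighbours within the chosen
#' neighbourhood (27 = face/edge/corner connectivity including the centre).
#' Edge voxels use the truncated in-mask neighbourhood; voxels with fewer
#' than \code{min_neighbors} in-mask neighbours are set to 0, as are
#' out-of-mask voxels, so the map's support equals the mask.
#'
#' @param img an \code{image4d} (see \code{\link{image4d}}).
#' @param mask a \code{brain_mask} on the same grid.
#' @param neighborhood_size 7, 19 or 27 voxels (including the centre).
#' @param min_neighbors minimum number of in-mask neighbours (excluding the
#'   centre) for W to be computed; default 2.
#' @param tie_policy passed to the W denominator; see \code{\link{kendall_w}}.
#' @return an \code{image3d} ReHo map with the input affine.
#' @export
reho_map <- function(img, mask, neighborhood_size = 27L, min_neighbors = 2L,
                     tie_policy = c("midrank_no_correction",
                                    "midrank_tie_correction")) {
  tie_policy <- match.arg(tie_policy)
  stopifnot(inherits(img, "image4d"), inherits(mask, "brain_mask"))
  if (!neighborhood_size %in% c(7L, 19L, 27L))
    stop("`neighborhood_size` must be 7, 19 or 27")
  if (min_neighbors < 2L) stop("`min_neighbors` must be >= 2")
  dm <- dim(img$data)
  if (!identical(dm[1:3], dim(mask$data))) stop("mask grid does not match image")
  n <- dm[4L]
  if (n < 4L) stop("need at least 4 timepoints for rank-based ReHo")

  m <- mask$data != 0
  # rank-transform every in-mask voxel series over time (midranks)
  Y <- matrix(img$data, nrow = prod(dm[1:3]), ncol = n)
  idx <- which(m)
  Rk_flat <- apply(Y[idx, , drop = FALSE], 1L, rank)  # n x V
  Rk <- array(0, dm)
  for (t in seq_len(n)) {
    sl <- array(0, dm[1:3]); sl[idx] <- Rk_flat[t, ]
    Rk[, , , t] <- sl
  }
  tiecor <- array(0, dm[1:3])
  if (tie_policy == "midrank_tie_correction") {
    tc <- apply(Y[idx, , drop = FALSE], 1L, function(x) {
      tt <- table(x); sum(tt^3 - tt)
    })
    tiecor[idx] <- tc
  }

  offs <- .neighborhood_offsets(neighborhood_size)
  Rsum <- array(0, dm)          # per-voxel, per-timepoint neighbourhood rank sum
  Kcnt <- array(0, dm[1:3])     # per-voxel number of in-mask series used
  Csum <- array(0, dm[1:3])     # per-voxel summed tie corrections
  mnum <- array(as.numeric(m), dm[1:3])
  for (o in seq_len(nrow(offs))) {
    sh <- offs[o, ]
    Rsum <- Rsum + .shift4(Rk, sh)
    Kcnt <- Kcnt + .shift3(mnum, sh)
    if (tie_policy == "midrank_tie_correction")
      Csum <- Csum + .shift3(tiecor, sh)
  }
  Rbar <- Kcnt * (n + 1) / 2    # each series' ranks sum to n(n+1)/2 over time
  S <- apply((Rsum - array(rep(Rbar, n), dm))^2, 1:3, sum)
  denom <- Kcnt^2 * (n^3 - n) - Kcnt * Csum
  W <- array(0, dm[1:3])
  ok <- m & (Kcnt - 1 >= min_neighbors) & denom > 0
  W[ok] <- pmin(pmax(12 * S[ok] / denom[ok], 0), 1)
  image3d(W, img$affine)
}

# integer offsets for the 7/19/27-voxel neighbourhoods (centre included)
.neighborhood_offsets <- function(size) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- rowSums(abs(g))
  keep <- switch(as.character(size),
                 "7"  = d <= 1,
                 "19" = d <= 2,
                 "27" = d <= 3)
  g[keep, , drop = FALSE]
}

# shift a 3D array by integer offset, zero-filling; sh = c(dx, dy, dz)
.shift3 <- function(a, sh) {
  d <- dim(a)
  out <- array(0, d)
  src <- dst <- vector("list", 3L)
  for (i in 1:3) {
    s <- sh[i]
    if (s >= 0) { src[[i]] <- seq_len(d[i] - s); dst[[i]] <- src[[i]] + s }
    else        { src[[i]] <- seq_len(d[i] + s) - s; dst[[i]] <- seq_len(d[i] + s) }
    if (length(src[[i]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

.shift4 <- function(a, sh) {
  d <- dim(a)
  out <- array(0, d)
  src <- dst <- vector("list", 3L)
  for (i in 1:3) {
    s <- sh[i]
    if (s >= 0) { src[[i]] <- seq_len(d[i] - s); dst[[i]] <- src[[i]] + s }
    else        { src[[i]] <- seq_len(d[i] + s) - s; dst[[i]] <- seq_len(d[i] + s) }
    if (length(src[[i]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]], ] <- a[src[[1]], src[[2]], src[[3]], ]
  out
}

#' ALFF and fractional ALFF maps
#'
#' Per in-mask voxel: linear detrend, band-pass to \code{band} (default
#' 0.01-0.1 Hz), then ALFF = standard deviation of the filtered series and
#' fALFF = ALFF divided by the standard deviation of the denominator series
#' (the detrended-but-unfiltered series by default).
#'
#' @param img an \code{image4d}; the repetition time sets the frequency grid.
#' @param mask a \code{brain_mask} on the same grid.
#' @param band numeric length-2, band edges in Hz; must satisfy
#'   0 <= f_lo < f_hi <= Nyquist = 1/(2 TR).
#' @param filter \code{"fft_ideal"} (zero all FFT bins strictly outside the
#'   band, edges inclusive; default) or \code{"butterworth"} (order-2,
#'   zero-phase).
#' @param falff_denominator \code{"detrended_unfiltered"} (default) or
#'   \code{"raw"}.
#' @return list with \code{alff} and \code{falff}, both \code{image3d}.
#'   Voxels whose denominator is (near) zero get fALFF 0 and are flagged in
#'   attribute \code{flagged} of the fALFF map (linear voxel indices).
#' @export
alff_falff <- function(img, mask, band = c(0.01, 0.1),
                       filter = c("fft_ideal", "butterworth"),
                       falff_denominator = c("detrended_unfiltered", "raw")) {
  filter <- match.arg(filter)
  falff_denominator <- match.arg(falff_denominator)
  stopifnot(inherits(img, "image4d"), inherits(mask, "brain_mask"))
  dm <- dim(img$data)
  if (!identical(dm[1:3], dim(mask$data))) stop("mask grid does not match image")
  n <- dm[4L]
  if (n < 16L) stop("need at least 16 timepoints for spectral features")
  tr <- img$repetition_time
  nyq <- 1 / (2 * tr)
  if (!(length(band) == 2L && band[1] >= 0 && band[1] < band[2]))
    stop("invalid band")
  if (band[2] > nyq + 1e-12)
    stop(sprintf("band upper edge %.4g Hz exceeds Nyquist %.4g Hz", band[2], nyq))

  idx <- which(mask$data != 0)
  Y <- t(matrix(img$data, nrow = prod(dm[1:3]), ncol = n)[idx, , drop = FALSE]) # n x V

  # linear detrend via projection onto [1, t]
  X <- cbind(1, seq_len(n))
  Q <- qr.Q(qr(X))
  Yd <- Y - Q %*% crossprod(Q, Y)

  if (filter == "fft_ideal") {
    fr <- (seq_len(n) - 1) / (n * tr)
    fr <- pmin(fr, 1 / tr - fr)           # two-sided frequency of each bin
    keep <- fr >= band[1] - 1e-12 & fr <= band[2] + 1e-12
    Fy <- stats::mvfft(Yd)
    Fy[!keep, ] <- 0
    Yf <- Re(stats::mvfft(Fy, inverse = TRUE)) / n
  } else {
    bf <- signal::butter(2, band / nyq, type = "pass")
    Yf <- apply(Yd, 2L, function(x) signal::filtfilt(bf, x))
  }

  sd_col <- function(M) sqrt(colMeans(M^2) - colMeans(M)^2)
  alff_v <- sd_col(Yf)
  den_v <- if (falff_denominator == "detrended_unfiltered") sd_col(Yd) else sd_col(Y)
  eps <- 1e-12
  bad <- den_v < eps
  falff_v <- ifelse(bad, 0, alff_v / pmax(den_v, eps))

  alff <- array(0, dm[1:3]); alff[idx] <- alff_v
  falff <- array(0, dm[1:3]); falff[idx] <- falff_v
  out_f <- image3d(falff, img$affine)
  if (any(bad)) attr(out_f, "flagged") <- idx[bad]
  list(alff = image3d(alff, img$affine), falff = out_f)
}

#' Participant-level z-scoring of a map within a mask
#'
#' Standardizes a 3D map over the in-mask voxels using the population (1/N)
#' standard deviation; out-of-mask voxels are set to 0.
#'
#' @param map an \code{image3d}.
#' @param mask a \code{brain_mask} on the same grid.
#' @return an \code{image3d} whose in-mask mean is 0 and population SD is 1.
#' @export
zscore_map <- function(map, mask) {
  stopifnot(inherits(map, "image3d"), inherits(mask, "brain_mask"))
  if (!identical(dim(map$data), dim(mask$data))) stop("mask grid does not match map")
  idx <- which(mask$data != 0)
  if (length(idx) < 2L) stop("need at least 2 in-mask voxels")
  v <- map$data[idx]
  mu <- mean(v)
  sdp <- sqrt(mean((v - mu)^2))
  if (sdp == 0) stop("constant in-mask map: z-score undefined")
  out <- array(0, dim(map$data))
  out[idx] <- (v - mu) / sdp
  image3d(out, map$affine)
}
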