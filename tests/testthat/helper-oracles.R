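# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# Kendall's W by explicit rank sums
bf_kendall_w <- function(block, tie_correction = FALSE) {
  K <- nrow(block); n <- ncol(block)
  R <- matrix(0, K, n)
  for (i in seq_len(K)) R[i, ] <- rank(block[i, ])
  Rsum <- numeric(n)
  for (t in seq_len(n)) Rsum[t] <- sum(R[, t])
  S <- sum((Rsum - mean(Rsum))^2)
  Tc <- 0
  if (tie_correction)
    for (i in seq_len(K)) { tt <- table(block[i, ]); Tc <- Tc + sum(tt^3 - tt) }
  12 * S / (K^2 * (n^3 - n) - K * Tc)
}

# voxel-by-voxel ReHo by explicit neighbourhood gathering
bf_reho <- function(data4d, mask, min_neighbors = 2) {
  d <- dim(data4d)
  out <- array(0, d[1:3])
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (mask[x, y, z] == 0) next
    block <- NULL
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      xx <- x + dx; yy <- y + dy; zz <- z + dz
      if (xx < 1 || yy < 1 || zz < 1 || xx > d[1] || yy > d[2] || zz > d[3]) next
      if (mask[xx, yy, zz] == 0) next
      block <- rbind(block, data4d[xx, yy, zz, ])
    }
    if (nrow(block) - 1 < min_neighbors) next
    out[x, y, z] <- bf_kendall_w(block)
  }
  out
}

# FFT in-band power fraction of a linearly detrended series
bf_band_fraction <- function(x, tr, band = c(0.01, 0.1)) {
  n <- length(x)
  xd <- stats::residuals(stats::lm(x ~ seq_len(n)))
  p <- Mod(stats::fft(xd))^2
  fr <- (seq_len(n) - 1) / (n * tr)
  fr <- pmin(fr, 1 / tr - fr)
  keep <- fr >= band[1] - 1e-12 & fr <= band[2] + 1e-12
  sum(p[keep]) / sum(p[-1])
}

# small all-labelled test atlas on an identity-scaled grid
tiny_atlas <- function(dim3 = c(6, 6, 6), nlab = 2, affine = diag(c(2, 2, 2, 1))) {
  lab <- array(rep(seq_len(nlab), length.out = prod(dim3)), dim3)
  label_atlas(lab, affine)
}

full_mask <- function(dim3, affine = diag(c(2, 2, 2, 1))) {
  brain_mask(array(1, dim3), affine)
}

# mask of voxels whose full 27-neighbourhood is in-mask
interior_of <- function(mask3d) {
  d <- dim(mask3d)
  out <- array(FALSE, d)
  for (x in 2:(d[1] - 1)) for (y in 2:(d[2] - 1)) for (z in 2:(d[3] - 1))
    out[x, y, z] <- all(mask3d[(x - 1):(x + 1), (y - 1):(y + 1),
                               (z - 1):(z + 1)] != 0)
  out & (mask3d != 0)
}
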