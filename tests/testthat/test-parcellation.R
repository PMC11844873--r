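test_that("merging 100 + 28 + 7 region parts yields contiguous labels 1..135", {
  mk <- function(n, fill_offset = 0) {
    # one voxel per region on a long thin grid, plus background
    d <- c(150, 1, 3)
    a <- array(0L, d)
    a[seq_len(n), 1, 1 + fill_offset] <- seq_len(n)
    label_atlas(a, diag(4))
  }
  parts <- list(mk(100, 0), mk(28, 1), mk(7, 2))
  merged <- merge_atlases(parts)
  expect_equal(merged$label_table$label, 1:135)
  expect_equal(sort(unique(merged$data[merged$data > 0])), 1:135)
  expect_equal(attr(merged, "overlap_voxels"), 0L)
})

test_that("disjoint single-region parts merge to a relabelled union", {
  a1 <- array(0L, c(4, 4, 1)); a1[1:2, 1, 1] <- 1L
  a2 <- array(0L, c(4, 4, 1)); a2[3:4, 4, 1] <- 1L
  m <- merge_atlases(list(label_atlas(a1, diag(4)), label_atlas(a2, diag(4))))
  expect_equal(sort(unique(m$data[m$data > 0])), c(1L, 2L))
  expect_equal(m$data[1, 1, 1], 1L)
  expect_equal(m$data[3, 4, 1], 2L)
})

test_that("overlap policies resolve colliding voxels and count the overlap", {
  a1 <- array(1L, c(3, 3, 1))
  a2 <- array(2L, c(3, 3, 1))
  p1 <- label_atlas(a1, diag(4)); p2 <- label_atlas(a2, diag(4))
  later <- merge_atlases(list(p1, p2))
  expect_true(all(later$data == 2L))            # relabelled last part
  expect_equal(attr(later, "overlap_voxels"), 9L)
  earlier <- merge_atlases(list(p1, p2), overlap_policy = "earlier_wins")
  expect_true(all(earlier$data == 1L))
})

test_that("label resampling: identity, 2x upsampling, and a brute-force oracle", {
  set.seed(41)
  src <- label_atlas(array(sample(0:3, 5 * 4 * 3, TRUE), c(5, 4, 3)),
                     diag(c(3, 3, 3, 1)))
  ident <- resample_labels(src, dim(src$data), src$affine)
  expect_identical(ident$data, src$data)

  one <- array(0L, c(3, 3, 3)); one[2, 2, 2] <- 1L
  up <- resample_labels(label_atlas(one, diag(c(2, 2, 2, 1))),
                        c(6, 6, 6), diag(c(1, 1, 1, 1)))
  expect_equal(sum(up$data == 1L), 8)           # a 2x2x2 block

  tgt_dim <- c(7, 6, 4); tgt_aff <- diag(c(2, 2, 2, 1))
  got <- resample_labels(src, tgt_dim, tgt_aff)
  # oracle: exhaustive nearest-source-centre search in world coordinates
  sd3 <- dim(src$data)
  sg <- as.matrix(expand.grid(i = seq_len(sd3[1]) - 1, j = seq_len(sd3[2]) - 1,
                              k = seq_len(sd3[3]) - 1))
  sw <- t(src$affine %*% t(cbind(sg, 1)))[, 1:3]
  for (i in 0:(tgt_dim[1] - 1)) for (j in 0:(tgt_dim[2] - 1))
    for (k in 0:(tgt_dim[3] - 1)) {
      w <- (tgt_aff %*% c(i, j, k, 1))[1:3]
      d2 <- (sw[, 1] - w[1])^2 + (sw[, 2] - w[2])^2 + (sw[, 3] - w[3])^2
      lab <- src$data[matrix(sg[which.min(d2), ] + 1, 1)]
      expect_identical(got$data[i + 1, j + 1, k + 1], lab)
    }
  expect_true(all(unique(got$data) %in% unique(src$data)))
})

test_that("regional means: constants, single voxels, oracle, conservation", {
  set.seed(43)
  atl <- tiny_atlas(c(6, 5, 4), 3)
  cmap <- image3d(array(7.5, dim(atl$data)), atl$affine)
  expect_true(all(abs(regional_means(cmap, atl) - 7.5) < 1e-12))

  rmap <- image3d(array(rnorm(prod(dim(atl$data))), dim(atl$data)), atl$affine)
  got <- regional_means(rmap, atl, "reho")
  for (lab in atl$label_table$label) {
    want <- mean(rmap$data[atl$data == lab])
    expect_equal(unname(unclass(got)[lab]), want, tolerance = 1e-12)
  }
  # conservation: sum over regions of mean x count equals the labelled sum
  cnt <- table(atl$data[atl$data > 0])
  lhs <- sum(unclass(got) * as.numeric(cnt))
  rhs <- sum(rmap$data[atl$data > 0])
  expect_equal(lhs, rhs, tolerance = 1e-8 * abs(rhs))

  one <- array(0L, c(3, 3, 3)); one[1, 2, 3] <- 1L
  g1 <- regional_means(rmap <- image3d(array(seq_len(27), c(3, 3, 3))),
                       label_atlas(one))
  expect_equal(unname(unclass(g1)[1]), rmap$data[1, 2, 3])
})

test_that("empty regions after resampling are flagged missing, not zeroed", {
  a <- array(0L, c(4, 4, 1)); a[1, 1, 1] <- 1L; a[4, 4, 1] <- 2L
  atl <- label_atlas(a, diag(4),
                     data.frame(label = 1:3, name = c("a", "b", "ghost")))
  v <- regional_means(image3d(array(1, c(4, 4, 1))), atl)
  expect_true(is.na(unclass(v)[3]))
  expect_equal(attr(v, "empty_labels"), 3)
})

test_that("centroid naming: containment, nearest fallback, identity", {
  ref <- array(0L, c(10, 1, 1)); ref[1:3, 1, 1] <- 1L; ref[8:10, 1, 1] <- 2L
  reference <- label_atlas(ref, diag(4),
                           data.frame(label = 1:2, name = c("left", "right")))
  # region strictly inside reference region 1
  a <- array(0L, c(10, 1, 1)); a[2, 1, 1] <- 1L
  expect_equal(unname(name_regions_by_centroid(label_atlas(a, diag(4)),
                                               reference)), "left")
  # centroid in background, nearer to region 2
  b <- array(0L, c(10, 1, 1)); b[6, 1, 1] <- 1L; b[7, 1, 1] <- 1L
  expect_equal(unname(name_regions_by_centroid(label_atlas(b, diag(4)),
                                               reference)), "right")
  # exact tie at the midpoint resolves to the lower reference label
  cmid <- array(0L, c(11, 1, 1)); cmid[6, 1, 1] <- 1L
  ref11 <- array(0L, c(11, 1, 1)); ref11[1:3, 1, 1] <- 1L; ref11[9:11, 1, 1] <- 2L
  reference11 <- label_atlas(ref11, diag(4),
                             data.frame(label = 1:2, name = c("left", "right")))
  expect_equal(unname(name_regions_by_centroid(label_atlas(cmid, diag(4)),
                                               reference11)), "left")
  # self-reference gives identity naming
  self <- name_regions_by_centroid(reference, reference)
  expect_equal(unname(self), reference$label_table$name)
})

test_that("atlases round-trip through NIfTI with their label tables", {
  atl <- tiny_atlas(c(4, 4, 4), 3)
  p <- tempfile(fileext = ".nii.gz")
  write_atlas(atl, p)
  back <- read_atlas(p)
  expect_equal(back$data, atl$data)
  expect_equal(back$label_table, atl$label_table)
  expect_equal(back$affine, atl$affine, tolerance = 1e-6)
})
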