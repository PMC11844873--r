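#' Merge label atlases into one custom atlas
#'
#' Concatenates the regions of several label atlases on a shared grid into a
#' single atlas, offsetting the labels of part k by the cumulative region
#' counts of parts 1..k-1 (so e.g. 100 + 28 + 7 regions merge to labels
#' 1..135). Overlapping voxels are resolved by \code{overlap_policy}; the
#' number of overwritten voxels is recorded in attribute
#' \code{overlap_voxels}.
#'
#' @param parts ordered list of \code{label_atlas} objects on identical
#'   grids/affines (resample first otherwise).
#' @param overlap_policy \code{"later_overwrites"} (default; later parts win,
#'   mirroring a merge order that puts refining subcortical parcels last) or
#'   \code{"earlier_wins"}.
#' @return a \code{label_atlas} with a concatenated label table.
#' @export
merge_atlases <- function(parts,
                          overlap_policy = c("later_overwrites", "earlier_wins")) {
  overlap_policy <- match.arg(overlap_policy)
  stopifnot(is.list(parts), length(parts) >= 1L,
            all(vapply(parts, inherits, TRUE, "label_atlas")))
  ref <- parts[[1L]]
  for (p in parts[-1L]) {
    if (!identical(dim(p$data), dim(ref$data)))
      stop("atlas grids differ; resample_labels() first")
    if (max(abs(p$affine - ref$affine)) > 1e-6)
      stop("atlas affines differ; resample_labels() first")
  }
  out <- array(0L, dim(ref$data))
  tabs <- list()
  offset <- 0L
  overlap <- 0L
  for (p in parts) {
    labs <- p$label_table
    relab <- p$data
    nz <- relab > 0L
    relab[nz] <- match(relab[nz], labs$label) + offset
    if (overlap_policy == "later_overwrites") {
      overlap <- overlap + sum(nz & out > 0L)
      out[nz] <- relab[nz]
    } else {
      take <- nz & out == 0L
      overlap <- overlap + sum(nz & out > 0L)
      out[take] <- relab[take]
    }
    tabs[[length(tabs) + 1L]] <- data.frame(
      label = seq_len(nrow(labs)) + offset, name = labs$name,
      stringsAsFactors = FALSE)
    offset <- offset + nrow(labs)
  }
  tab <- do.call(rbind, tabs)
  tab$name <- make.unique(tab$name, sep = "_")
  # drop regions emptied by overwriting from the data but keep table contiguous
  res <- label_atlas(out, ref$affine, label_table = tab)
  res$label_table <- tab[tab$label %in% sort(unique(out[out > 0L])), ,
                         drop = FALSE]
  attr(res, "overlap_voxels") <- overlap
  res
}

#' Nearest-neighbour resampling of a label atlas onto a target grid
#'
#' Each target voxel takes the label of the nearest source voxel centre,
#' with voxel centres compared in world coordinates through both affines.
#' No new labels are created. Ties in distance resolve to the lower voxel
#' index.
#'
#' @param atlas a \code{label_atlas}.
#' @param target_dim integer length-3 target grid.
#' @param target_affine 4x4 target voxel-to-world affine.
#' @return a \code{label_atlas} on the target grid.
#' @export
resample_labels <- function(atlas, target_dim, target_affine) {
  stopifnot(inherits(atlas, "label_atlas"), length(target_dim) == 3L)
  if (abs(det(atlas$affine)) < .Machine$double.eps ||
      abs(det(target_affine)) < .Machine$double.eps)
    stop("degenerate affine")
  M <- solve(atlas$affine) %*% target_affine   # target voxel -> source voxel
  g <- as.matrix(expand.grid(i = seq_len(target_dim[1]) - 1,
                             j = seq_len(target_dim[2]) - 1,
                             k = seq_len(target_dim[3]) - 1))
  src <- t(M %*% t(cbind(g, 1)))[, 1:3, drop = FALSE]
  sd3 <- dim(atlas$data)
  out <- integer(nrow(g))
  nearest <- function(x, n) pmin(pmax(.round_half_down(x), 0), n - 1)
  ii <- nearest(src[, 1], sd3[1])
  jj <- nearest(src[, 2], sd3[2])
  kk <- nearest(src[, 3], sd3[3])
  out <- atlas$data[cbind(ii + 1, jj + 1, kk + 1)]
  label_atlas(array(out, target_dim), target_affine,
              label_table = atlas$label_table)
}

# nearest integer with exact .5 ties resolved to the lower integer
.round_half_down <- function(x) {
  f <- floor(x)
  ifelse(x - f <= 0.5, f, f + 1)
}

#' Regional mean features from a 3D map
#'
#' Per atlas label, the mean of the map voxels carrying that label. Labels
#' with zero voxels are returned as \code{NA} and flagged; missingness is
#' propagated for the modelling layer to impute, never silently zeroed.
#'
#' @param map an \code{image3d} feature map (e.g. z-scored fALFF or ReHo).
#' @param atlas a \code{label_atlas} on the same grid.
#' @param feature_type one of \code{"reho"}, \code{"falff"}, \code{"alff"}.
#' @return object of class \code{regional_features}: named numeric vector in
#'   label order with attributes \code{feature_type} and \code{empty_labels}.
#' @export
regional_means <- function(map, atlas, feature_type = c("falff", "reho", "alff")) {
  feature_type <- match.arg(feature_type)
  stopifnot(inherits(map, "image3d"), inherits(atlas, "label_atlas"))
  if (!identical(dim(map$data), dim(atlas$data)))
    stop("grids differ; resample_labels() first")
  labs <- atlas$label_table$label
  lab_vec <- as.vector(atlas$data)
  nz <- lab_vec > 0L
  sums <- tapply(as.vector(map$data)[nz], lab_vec[nz], sum)
  cnts <- tapply(rep(1, sum(nz)), lab_vec[nz], sum)
  v <- rep(NA_real_, length(labs))
  names(v) <- sprintf("%s_%s", feature_type, atlas$label_table$name)
  hit <- match(as.integer(names(sums)), labs)
  v[hit] <- as.numeric(sums) / as.numeric(cnts)
  structure(v, feature_type = feature_type,
            empty_labels = labs[is.na(v)], class = "regional_features")
}

#' Name regions by world-space centroid lookup in a reference atlas
#'
#' For each region: compute the centroid of its voxels in world mm. If the
#' centroid falls inside a nonzero reference label, take that label's name;
#' otherwise take the name of the nearest nonzero reference voxel (Euclidean
#' distance in mm; exact ties resolve to the lower reference label).
#'
#' @param atlas a \code{label_atlas} whose regions are to be named.
#' @param reference a \code{label_atlas} in the same world space.
#' @return named character vector, one name per atlas label (names are the
#'   labels).
#' @export
name_regions_by_centroid <- function(atlas, reference) {
  stopifnot(inherits(atlas, "label_atlas"), inherits(reference, "label_atlas"))
  ref_nz <- which(reference$data > 0L)
  if (length(ref_nz) == 0L) stop("reference atlas is empty")
  rd <- dim(reference$data)
  ref_ijk <- cbind(arrayInd(ref_nz, rd) - 1L, 1)
  ref_world <- t(reference$affine %*% t(ref_ijk))[, 1:3, drop = FALSE]
  ref_lab <- reference$data[ref_nz]
  ref_name <- reference$label_table$name[match(ref_lab, reference$label_table$label)]

  ad <- dim(atlas$data)
  out <- character(nrow(atlas$label_table))
  names(out) <- atlas$label_table$label
  for (r in seq_len(nrow(atlas$label_table))) {
    lab <- atlas$label_table$label[r]
    vox <- which(atlas$data == lab)
    ijk <- cbind(arrayInd(vox, ad) - 1L, 1)
    cen <- colMeans(t(atlas$affine %*% t(ijk))[, 1:3, drop = FALSE])
    # voxel of the reference containing the centroid (nearest centre)
    cv <- solve(reference$affine) %*% c(cen, 1)
    cvi <- pmin(pmax(.round_half_down(cv[1:3]), 0), rd - 1)
    hit <- reference$data[cvi[1] + 1, cvi[2] + 1, cvi[3] + 1]
    if (hit > 0L) {
      out[r] <- reference$label_table$name[match(hit, reference$label_table$label)]
    } else {
      d2 <- (ref_world[, 1] - cen[1])^2 + (ref_world[, 2] - cen[2])^2 +
        (ref_world[, 3] - cen[3])^2
      cand <- which(d2 == min(d2))
      out[r] <- ref_name[cand[which.min(ref_lab[cand])]]
    }
  }
  out
}
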