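# Synthetic study generator: small 4D volumes with controllable local
# temporal coherence (ReHo ground truth) and in-band spectral power fraction
# (fALFF ground truth), label atlases, motion traces, and cohorts whose
# MDS-UPDRS totals follow a known linear generative model. Everything is
# deterministic given its seed.

#' Synthetic Voronoi label atlas
#'
#' Partitions the grid (minus a one-voxel background shell) into regions by
#' nearest seeded centre, giving irregular contiguous regions.
#'
#' @param grid_shape integer length-3, each >= 3.
#' @param n_regions number of regions.
#' @param seed integer seed.
#' @param shell background margin in voxels (default 1).
#' @param affine voxel-to-world matrix (default 2 mm isotropic).
#' @param name_prefix region-name prefix (default \code{"region"}).
#' @return a \code{\link{label_atlas}}.
#' @export
synth_atlas <- function(grid_shape, n_regions, seed = 1L, shell = 1L,
                        affine = diag(c(2, 2, 2, 1)), name_prefix = "region") {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 3L), n_regions >= 1L)
  set.seed(seed)
  centers <- cbind(stats::runif(n_regions, shell, grid_shape[1] - shell),
                   stats::runif(n_regions, shell, grid_shape[2] - shell),
                   stats::runif(n_regions, shell, grid_shape[3] - shell))
  g <- as.matrix(expand.grid(i = seq_len(grid_shape[1]) - 1,
                             j = seq_len(grid_shape[2]) - 1,
                             k = seq_len(grid_shape[3]) - 1))
  inside <- g[, 1] >= shell & g[, 1] <= grid_shape[1] - 1 - shell &
    g[, 2] >= shell & g[, 2] <= grid_shape[2] - 1 - shell &
    g[, 3] >= shell & g[, 3] <= grid_shape[3] - 1 - shell
  lab <- integer(nrow(g))
  if (any(inside)) {
    pts <- g[inside, , drop = FALSE]
    d <- sapply(seq_len(n_regions), function(r)
      (pts[, 1] - centers[r, 1])^2 + (pts[, 2] - centers[r, 2])^2 +
        (pts[, 3] - centers[r, 3])^2)
    if (is.null(dim(d))) d <- matrix(d, ncol = n_regions)
    lab[inside] <- max.col(-d, ties.method = "first")
  }
  present <- sort(unique(lab[lab > 0L]))
  label_atlas(array(lab, grid_shape), affine,
              label_table = data.frame(
                label = present,
                name = sprintf("%s_%d", name_prefix, present),
                stringsAsFactors = FALSE))
}

#' Synthetic 4D fMRI with known coherence and spectral ground truth
#'
#' Each region gets a latent signal whose power fraction inside the analysis
#' band equals phi exactly (constructed from disjoint FFT bins and
#' unit-normalized). Each voxel's series is
#' sqrt(rho) x (regional latent) + sqrt(1 - rho) x (voxel-private white
#' noise), so rho is the fraction of voxel variance from the shared latent
#' (the ReHo ground truth) and phi the in-band power fraction of the shared
#' part (the fALFF ground truth).
#'
#' @param atlas a \code{\link{label_atlas}} defining the regions.
#' @param coherence numeric in [0,1]: one value per region (recycled),
#'   named by label or in label-table order.
#' @param inband_fraction numeric in [0,1]: per-region phi, same conventions.
#' @param n_timepoints >= 16.
#' @param repetition_time seconds (default 2.4).
#' @param band analysis band in Hz (default 0.01-0.1).
#' @param seed integer seed.
#' @return list with \code{img} (\code{image4d}), \code{mask}
#'   (\code{brain_mask} over all labelled voxels) and \code{truth} (list with
#'   per-voxel coherence array, per-region phi, and the band).
#' @export
synth_fmri <- function(atlas, coherence = 0.5, inband_fraction = 0.5,
                       n_timepoints = 200L, repetition_time = 2.4,
                       band = c(0.01, 0.1), seed = 1L) {
  stopifnot(inherits(atlas, "label_atlas"), n_timepoints >= 16L)
  labs <- atlas$label_table$label
  rho <- .per_region(coherence, labs, "coherence")
  phi <- .per_region(inband_fraction, labs, "inband_fraction")
  if (any(rho < 0 | rho > 1) || any(phi < 0 | phi > 1))
    stop("coherence and inband_fraction must lie in [0, 1]")
  n <- as.integer(n_timepoints)
  fr <- (seq_len(n) - 1) / (n * repetition_time)
  fr <- pmin(fr, 1 / repetition_time - fr)
  inb <- fr >= band[1] - 1e-12 & fr <= band[2] + 1e-12
  inb[1] <- FALSE                                   # never place power at DC
  outb <- !inb; outb[1] <- FALSE
  if (!any(inb))
    stop("no FFT bin falls in the band: n_timepoints too small for this TR")

  set.seed(seed)
  unit <- function(x) {
    s <- sqrt(mean((x - mean(x))^2))
    if (s == 0) x else (x - mean(x)) / s
  }
  shaped <- function(keep) {
    z <- stats::rnorm(n)
    f <- stats::fft(z); f[!keep] <- 0
    unit(Re(stats::fft(f, inverse = TRUE)) / n)
  }
  latents <- sapply(seq_along(labs), function(r)
    sqrt(phi[r]) * shaped(inb) + sqrt(1 - phi[r]) * shaped(outb))

  dm <- dim(atlas$data)
  dat <- array(0, c(dm, n))
  vox <- which(atlas$data > 0L)
  lab_of <- atlas$data[vox]
  noise <- matrix(stats::rnorm(length(vox) * n), nrow = length(vox))
  noise <- t(apply(noise, 1L, unit))
  ridx <- match(lab_of, labs)
  series <- sweep(latents[, ridx, drop = FALSE], 2L, sqrt(rho[ridx]), "*")
  series <- t(series) + sweep(noise, 1L, sqrt(1 - rho[ridx]), "*")
  flat <- matrix(dat, nrow = prod(dm), ncol = n)
  flat[vox, ] <- series
  img <- image4d(array(flat, c(dm, n)), atlas$affine, repetition_time)
  mask <- brain_mask(array(as.numeric(atlas$data > 0L), dm), atlas$affine)
  coh <- array(0, dm); coh[vox] <- rho[ridx]
  list(img = img, mask = mask,
       truth = list(coherence = coh, phi = stats::setNames(phi, labs),
                    band = band, latents = latents))
}

# relabel an atlas contiguously after voxels were carved away
.compact_atlas <- function(p) {
  present <- sort(unique(p$data[p$data > 0L]))
  nd <- array(0L, dim(p$data)); nz <- p$data > 0L
  nd[nz] <- match(p$data[nz], present)
  tb <- p$label_table[match(present, p$label_table$label), , drop = FALSE]
  label_atlas(nd, p$affine,
              data.frame(label = seq_along(present), name = tb$name,
                         stringsAsFactors = FALSE))
}

.per_region <- function(x, labs, what) {
  if (!is.null(names(x))) {
    miss <- setdiff(as.character(labs), names(x))
    if (length(miss))
      stop(sprintf("%s missing for label(s) %s", what,
                   paste(miss, collapse = ", ")))
    unname(x[as.character(labs)])
  } else rep_len(x, length(labs))
}

#' Synthetic motion trace (random walk)
#'
#' Six-column random-walk trace: three translations (mm) and three rotations
#' (radians). The default step sizes are calibrated so the mean framewise
#' displacement across timepoints is about 0.258 mm under the 50 mm radius
#' convention, matching a realistic resting-state cohort.
#'
#' @param n_timepoints >= 2.
#' @param step_sd_trans per-step translation SD in mm.
#' @param step_sd_rot per-step rotation SD in radians.
#' @param seed integer seed.
#' @return T x 6 matrix (tx, ty, tz, rx, ry, rz).
#' @export
synth_motion <- function(n_timepoints, step_sd_trans = 0.06,
                         step_sd_rot = 0.00095, seed = 1L) {
  stopifnot(n_timepoints >= 2L)
  if (step_sd_trans < 0 || step_sd_rot < 0) stop("negative step SD")
  set.seed(seed)
  steps <- cbind(matrix(stats::rnorm(3 * (n_timepoints - 1), 0, step_sd_trans),
                        ncol = 3),
                 matrix(stats::rnorm(3 * (n_timepoints - 1), 0, step_sd_rot),
                        ncol = 3))
  m <- rbind(0, apply(steps, 2L, cumsum))
  dimnames(m) <- list(NULL, c("tx", "ty", "tz", "rx", "ry", "rz"))
  m
}

#' Synthetic longitudinal cohort with a known linear generative model
#'
#' Baseline MDS-UPDRS totals are a linear combination of encoded clinical /
#' demographic features and the supplied regional imaging features plus
#' Gaussian noise (clipped to [0, 199] and rounded); follow-up totals are
#' \code{alpha_baseline_score} x baseline + imaging terms + noise. Part
#' scores are decomposed from the total by a fixed Dirichlet split; NP4TOT is
#' set missing with probability \code{np4_missing_prob} (its mass folded into
#' part III so the missing-to-zero rule reproduces the generative total).
#' Visit dates sit at 365 / 730 / 1460 days plus uniform jitter within the
#' matching window; retained participants form nested subsets of sizes
#' \code{round(n_baseline * retention)}.
#'
#' @param imaging participants x regions \code{\link{feature_matrix}} of
#'   baseline regional imaging features; needs at least \code{n_baseline}
#'   rows.
#' @param n_baseline number of baseline participants.
#' @param retention length-3 non-increasing fractions in (0, 1] for
#'   Year 1 / 2 / 4 (defaults mirror a 82 -> 51 -> 41 -> 30 longitudinal
#'   attrition profile).
#' @param beta_clinical named weights on encoded clinical/demographic columns.
#' @param beta_imaging named weights on imaging feature columns.
#' @param alpha_baseline_score weight of the baseline total on follow-ups.
#' @param noise_sd baseline noise SD (score units); if \code{NULL} it is set
#'   so the theoretical baseline R2 equals \code{target_r2}.
#' @param target_r2 theoretical baseline R2 used when \code{noise_sd} is
#'   \code{NULL} (default 0.5).
#' @param followup_r2 theoretical follow-up R2 used to set follow-up noise.
#' @param intercept baseline mean total.
#' @param np4_missing_prob probability a visit's NP4TOT is missing.
#' @param jitter_days visit-date jitter half-width (default 45, inside the
#'   60-day matching window).
#' @param seed integer seed.
#' @return list with \code{cohort} (long data.frame, one row per participant
#'   x visit) and \code{truth} (class \code{synth_truth}: betas, noise SDs,
#'   and theoretical R2 per time point computed from the empirical variance
#'   decomposition Var(X beta) / (Var(X beta) + noise_sd^2)).
#' @export
synth_cohort <- function(imaging, n_baseline = 120L,
                         retention = c(Year1 = 51 / 82, Year2 = 41 / 82,
                                       Year4 = 30 / 82),
                         beta_clinical = c(age = 0.15, disease_duration = 0.004,
                                           moca = -0.8, gds = 0.8, tremor = 2),
                         beta_imaging = NULL,
                         alpha_baseline_score = 0.9,
                         noise_sd = NULL, target_r2 = 0.5, followup_r2 = 0.75,
                         intercept = 38, np4_missing_prob = 0.3,
                         jitter_days = 45, seed = 1L) {
  stopifnot(nrow(imaging) >= n_baseline, length(retention) == 3L,
            all(retention > 0 & retention <= 1))
  if (any(diff(unname(retention)) > 0))
    stop("retention must be non-increasing (longitudinal attrition)")
  imaging <- imaging[seq_len(n_baseline), , drop = FALSE]
  set.seed(seed)
  demo <- .synth_demographics(n_baseline)
  if (is.null(beta_imaging)) {
    k <- min(4L, ncol(imaging))
    beta_imaging <- stats::setNames(c(4, -3, 3, -2)[seq_len(k)],
                                    colnames(imaging)[seq_len(k)])
  }
  Xc <- encode_features(demo, feature_set = "clinical_only")
  miss_c <- setdiff(names(beta_clinical), colnames(Xc))
  miss_i <- setdiff(names(beta_imaging), colnames(imaging))
  if (length(miss_c) || length(miss_i))
    stop(sprintf("beta names not found in features: %s",
                 paste(c(miss_c, miss_i), collapse = ", ")))
  eta <- as.numeric(Xc[, names(beta_clinical), drop = FALSE] %*% beta_clinical +
                      imaging[, names(beta_imaging), drop = FALSE] %*% beta_imaging)
  if (is.null(noise_sd)) {
    v <- stats::var(eta) * (length(eta) - 1) / length(eta)
    noise_sd <- sqrt(v * (1 - target_r2) / target_r2)
  }
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  y_bl <- pmin(pmax(intercept + eta + stats::rnorm(n_baseline, 0, noise_sd), 0), 199)
  y_bl <- round(y_bl)

  # follow-up structure: alpha x baseline + imaging terms + noise
  eta_f <- alpha_baseline_score * y_bl +
    as.numeric(imaging[, names(beta_imaging), drop = FALSE] %*%
                 (0.5 * beta_imaging))
  v_f <- stats::var(eta_f) * (length(eta_f) - 1) / length(eta_f)
  noise_sd_f <- sqrt(v_f * (1 - followup_r2) / followup_r2)

  keep <- list()
  keep$Year1 <- sort(sample(seq_len(n_baseline), round(n_baseline * retention[[1]])))
  keep$Year2 <- sort(sample(keep$Year1, round(n_baseline * retention[[2]])))
  keep$Year4 <- sort(sample(keep$Year2, round(n_baseline * retention[[3]])))

  bl_date <- as.Date("2020-01-15") + sample.int(120L, n_baseline, replace = TRUE)
  ev_code <- c(Year1 = "V04", Year2 = "V06", Year4 = "V10")
  targets <- c(Year1 = 365, Year2 = 730, Year4 = 1460)

  rows <- .cohort_rows(demo, "BL", bl_date, y_bl, seq_len(n_baseline),
                       np4_missing_prob)
  y_tp <- list()
  for (tp in names(targets)) {
    ids <- keep[[tp]]
    yf <- pmin(pmax(eta_f[ids] + stats::rnorm(length(ids), 0, noise_sd_f), 0), 199)
    yf <- round(yf)
    y_tp[[tp]] <- yf
    dt <- bl_date[ids] + targets[[tp]] +
      sample(seq(-jitter_days, jitter_days), length(ids), replace = TRUE)
    rows <- rbind(rows, .cohort_rows(demo[ids, , drop = FALSE], ev_code[[tp]],
                                     dt, yf, ids, np4_missing_prob))
  }

  th_bl <- {
    v <- stats::var(eta) * (length(eta) - 1) / length(eta)
    v / (v + noise_sd^2)
  }
  th_f <- v_f / (v_f + noise_sd_f^2)
  truth <- structure(
    list(beta_clinical = beta_clinical, beta_imaging = beta_imaging,
         alpha_baseline_score = alpha_baseline_score,
         intercept = intercept, noise_sd = noise_sd, noise_sd_followup = noise_sd_f,
         eta_baseline = eta + intercept, eta_followup = eta_f,
         theoretical_r2 = c(Baseline = th_bl, Year1 = th_f, Year2 = th_f,
                            Year4 = th_f),
         retained = keep),
    class = "synth_truth")
  list(cohort = rows, truth = truth)
}

#' @export
print.synth_truth <- function(x, ...) {
  cat("<synth_truth> theoretical R2:",
      paste(sprintf("%s = %.3f", names(x$theoretical_r2), x$theoretical_r2),
            collapse = ", "), "\n")
  invisible(x)
}

# one row per participant for a given visit; decompose totals into parts via
# a fixed Dirichlet(2, 2, 4, 10, 1) split over parts Ia/Ib/II/III/IV
.cohort_rows <- function(demo, event_id, dates, totals, ids, np4_missing_prob) {
  n <- length(totals)
  alpha <- c(2, 2, 4, 10, 1)
  g <- matrix(stats::rgamma(n * 5L, shape = rep(alpha, each = n)), nrow = n)
  frac <- g / rowSums(g)
  parts <- matrix(0L, n, 5L)
  for (i in seq_len(n)) {
    p <- floor(frac[i, ] * totals[i])
    rem <- totals[i] - sum(p)
    if (rem > 0) {                      # largest remainders absorb the rest
      ord <- order(frac[i, ] * totals[i] - p, decreasing = TRUE)
      p[ord[seq_len(rem)]] <- p[ord[seq_len(rem)]] + 1L
    }
    parts[i, ] <- p
  }
  np4_missing <- stats::runif(n) < np4_missing_prob
  parts[np4_missing, 4L] <- parts[np4_missing, 4L] + parts[np4_missing, 5L]
  np4 <- ifelse(np4_missing, NA_integer_, parts[, 5L])
  out <- data.frame(PATNO = ids, EVENT_ID = event_id,
                    INFODT = format(as.Date(dates), "%Y-%m-%d"),
                    NP1RTOT = parts[, 1L], NP1PTOT = parts[, 2L],
                    NP2TOT = parts[, 3L], NP3TOT = parts[, 4L], NP4TOT = np4,
                    stringsAsFactors = FALSE)
  cbind(out, demo[, setdiff(colnames(demo), colnames(out)), drop = FALSE],
        row.names = NULL)
}

.synth_demographics <- function(n) {
  dx <- pmax(round(stats::rnorm(n, 770, 450)), 30)
  data.frame(
    PATNO = seq_len(n),
    AGE = round(stats::rnorm(n, 61.5, 9.8), 1),
    SEX = sample(c("M", "F"), n, TRUE, prob = c(0.67, 0.33)),
    EDUCYRS = pmax(round(stats::rnorm(n, 15.6, 3)), 6),
    HANDED = sample(c("right", "left", "mixed"), n, TRUE,
                    prob = c(0.88, 0.10, 0.02)),
    RACE = sample(c("white", "black", "asian", "other"), n, TRUE,
                  prob = c(0.92, 0.03, 0.03, 0.02)),
    ETHNICITY = sample(c("not_hispanic", "hispanic"), n, TRUE,
                       prob = c(0.97, 0.03)),
    DOMSIDE = sample(c("right", "left", "symmetric"), n, TRUE,
                     prob = c(0.55, 0.40, 0.05)),
    DXDUR = dx,
    SYMPDUR = dx + pmax(round(stats::rnorm(n, 250, 150)), 0),
    GDS = pmin(pmax(round(stats::rnorm(n, 5.4, 1.5)), 0), 15),
    MOCA = pmin(pmax(round(stats::rnorm(n, 26.7, 2.8)), 0), 30),
    TREMOR = stats::rbinom(n, 1, 0.8),
    RIGIDITY = stats::rbinom(n, 1, 0.75),
    POSTINST = stats::rbinom(n, 1, 0.3),
    PAG_NAME = "NUPDRS3A",
    stringsAsFactors = FALSE)
}

#' Monte-Carlo check of the theoretical R2
#'
#' Resamples participants (rows of the linear predictor) with replacement,
#' adds fresh Gaussian noise, and estimates R2 as the variance-decomposition
#' ratio over the simulated draws — an independent check of the closed-form
#' theoretical R2.
#'
#' @param eta linear-predictor values (one per participant).
#' @param noise_sd noise standard deviation.
#' @param n_draws number of simulated subjects (default 10000).
#' @param seed integer seed.
#' @return Monte-Carlo R2 estimate.
#' @export
mc_theoretical_r2 <- function(eta, noise_sd, n_draws = 10000L, seed = 1L) {
  set.seed(seed)
  e <- sample(eta, n_draws, replace = TRUE)
  y <- e + stats::rnorm(n_draws, 0, noise_sd)
  stats::var(e) / stats::var(y)
}

#' Generate a complete synthetic study
#'
#' Builds the full set of inputs the pipeline needs, end to end: a merged
#' primary parcellation (cortical-like + cerebellar-like + striatal-like
#' parts, mirroring a 100 + 28 + 7 merge at desk scale) plus coarser and
#' finer alternative parcellations; per-participant 4D volumes with
#' participant-varying in-band power; regional z-scored fALFF (and optionally
#' ReHo) features computed with the package's own imaging pipeline; motion
#' traces; and a cohort whose totals follow the known linear generative
#' model.
#'
#' @param n_baseline participants at baseline (default 120).
#' @param grid_shape voxel grid (default 12 x 12 x 12).
#' @param n_timepoints timepoints per volume (default 200).
#' @param repetition_time seconds (default 2.4).
#' @param target_r2 theoretical baseline R2 (default 0.5).
#' @param noise_sd optional explicit baseline noise SD (overrides
#'   \code{target_r2}).
#' @param compute_reho also compute regional ReHo features (slower).
#' @param n_keep_images how many raw volumes to retain in the result (for
#'   inspection/tests; default 2).
#' @param seed master seed.
#' @param ... passed on to \code{\link{synth_cohort}}.
#' @return object of class \code{synth_study}: list with \code{cohort},
#'   \code{truth}, \code{features} (nested list: feature type -> parcellation
#'   -> participants x regions matrix; types \code{falff} (z-scored),
#'   \code{falff_nz} (no z-scoring), \code{alff}, and \code{reho} when
#'   requested), \code{atlases}, \code{mask}, \code{motion} (list of
#'   traces), \code{fd} (per-participant mean FD), \code{images} (first
#'   \code{n_keep_images} volumes) and the generation parameters. The cohort
#'   generative model runs on the z-scored fALFF features of the primary
#'   parcellation.
#' @export
synth_study <- function(n_baseline = 120L, grid_shape = c(12L, 12L, 12L),
                        n_timepoints = 200L, repetition_time = 2.4,
                        target_r2 = 0.5, noise_sd = NULL,
                        compute_reho = FALSE,
                        n_keep_images = 2L, seed = 1L, ...) {
  seeds <- .seed_stream(seed, 7L + n_baseline)
  # primary parcellation built by merging three parts, as the custom atlas is
  parts <- list(
    synth_atlas(grid_shape, 6L, seed = seeds[1], name_prefix = "cortical"),
    synth_atlas(grid_shape, 4L, seed = seeds[2], name_prefix = "cerebellar"),
    synth_atlas(grid_shape, 2L, seed = seeds[3], name_prefix = "striatal"))
  # carve the cerebellar-/striatal-like parts to small subvolumes (a top slab
  # and a central block) so the later-overwrites merge refines, not replaces,
  # the cortical-like parcels
  g3 <- grid_shape[3]
  parts[[2]]$data[, , seq_len(ceiling(3 * g3 / 4))] <- 0L
  mid <- floor(grid_shape / 2)
  blk <- lapply(1:3, function(d) max(2L, mid[d] - 1L):min(grid_shape[d] - 1L, mid[d] + 1L))
  keep <- array(FALSE, grid_shape)
  keep[blk[[1]], blk[[2]], blk[[3]]] <- TRUE
  parts[[3]]$data[!keep] <- 0L
  parts[2:3] <- lapply(parts[2:3], .compact_atlas)
  primary <- merge_atlases(parts)
  atlases <- list(
    primary = primary,
    coarse = synth_atlas(grid_shape, 6L, seed = seeds[4]),
    fine = synth_atlas(grid_shape, 24L, seed = seeds[5]))

  mask <- brain_mask(array(as.numeric(primary$data > 0L), grid_shape),
                     primary$affine)
  labs <- primary$label_table$label
  nlab <- length(labs)

  blank <- function(prefix) lapply(atlases, function(a)
    matrix(NA_real_, n_baseline, nrow(a$label_table),
           dimnames = list(NULL, sprintf("%s_%s", prefix, a$label_table$name))))
  # falff: z-scored fALFF (the default input); falff_nz: no z-scoring (C.1
  # analogue); alff: z-scored ALFF (C.2 analogue); reho: z-scored ReHo
  feats <- list(falff = blank("falff"), falff_nz = blank("falff"),
                alff = blank("alff"))
  if (compute_reho) feats$reho <- blank("reho")
  motion <- vector("list", n_baseline)
  fd_mean <- numeric(n_baseline)
  images <- list()

  set.seed(seeds[6])
  phi_base <- stats::runif(nlab, 0.35, 0.65)
  for (i in seq_len(n_baseline)) {
    si <- seeds[7L + i]
    set.seed(si)
    sub <- sample.int(2147483646L, 2L)
    phi_i <- pmin(pmax(phi_base + stats::runif(nlab, -0.25, 0.25), 0.02), 0.98)
    rho_i <- stats::runif(nlab, 0.3, 0.8)
    sim <- synth_fmri(primary, coherence = stats::setNames(rho_i, labs),
                      inband_fraction = stats::setNames(phi_i, labs),
                      n_timepoints = n_timepoints,
                      repetition_time = repetition_time, seed = sub[1])
    motion[[i]] <- synth_motion(n_timepoints, seed = sub[2])
    fd_mean[i] <- framewise_displacement(motion[[i]])$mean_fd
    den <- regress_confounds(sim$img, motion[[i]], mask = mask)
    sp <- alff_falff(den, mask)
    maps <- list(falff = zscore_map(sp$falff, mask),
                 falff_nz = sp$falff,
                 alff = zscore_map(sp$alff, mask))
    if (compute_reho) maps$reho <- zscore_map(reho_map(den, mask), mask)
    for (ft in names(maps)) for (an in names(atlases)) {
      ftype <- if (ft == "alff") "alff" else if (ft == "reho") "reho" else "falff"
      feats[[ft]][[an]][i, ] <-
        as.numeric(regional_means(maps[[ft]], atlases[[an]], ftype))
    }
    if (i <= n_keep_images) images[[i]] <- sim$img
  }

  feats <- lapply(feats, function(bytype) lapply(bytype, function(M)
    feature_matrix(M, provenance = rep("imaging", ncol(M)),
                   continuous = rep(TRUE, ncol(M)))))

  coh <- synth_cohort(feats$falff$primary, n_baseline = n_baseline,
                      target_r2 = target_r2, noise_sd = noise_sd,
                      seed = seeds[7], ...)
  structure(list(cohort = coh$cohort, truth = coh$truth,
                 features = feats,
                 atlases = atlases, mask = mask, motion = motion,
                 fd = fd_mean, images = images,
                 params = list(n_baseline = n_baseline,
                               grid_shape = grid_shape,
                               n_timepoints = n_timepoints,
                               repetition_time = repetition_time,
                               target_r2 = target_r2,
                               seed = seed)),
            class = "synth_study")
}

#' @export
print.synth_study <- function(x, ...) {
  cat(sprintf("<synth_study> n = %d, grid %s, T = %d, TR = %g s\n",
              x$params$n_baseline,
              paste(x$params$grid_shape, collapse = "x"),
              x$params$n_timepoints, x$params$repetition_time))
  print(x$truth)
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Writes the cohort TSV, atlases (NIfTI + label TSVs), mask, retained raw
#' volumes, and motion traces under a directory, using the package's
#' external formats.
#'
#' @param study a \code{synth_study}.
#' @param dir output directory (created if needed).
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(study$cohort, file.path(dir, "cohort.tsv"))
  for (an in names(study$atlases))
    write_atlas(study$atlases[[an]], file.path(dir, sprintf("atlas_%s.nii.gz", an)))
  write_image(study$mask, file.path(dir, "mask.nii.gz"))
  for (i in seq_along(study$images))
    write_image(study$images[[i]], file.path(dir, sprintf("bold_%03d.nii.gz", i)))
  for (i in seq_along(study$motion))
    write_motion(study$motion[[i]], file.path(dir, sprintf("motion_%03d.txt", i)))
  invisible(dir)
}
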