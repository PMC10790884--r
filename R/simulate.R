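#' Simulate a reference-region curve
#'
#' Emulates a cerebellum time-activity curve: zero at injection, a single
#' early peak, then washout. The gamma-variate model is
#' `A * t^alpha * exp(-t/beta)` (t in seconds); the biexponential model is
#' `A * (exp(-t/tau_slow) - exp(-t/tau_fast))` with `tau_fast < tau_slow`.
#' With the default parameters the peak occurs within the first 10 minutes
#' and more than 80% of the peak has washed out by 90 minutes.
#'
#' @param t_grid time grid in seconds.
#' @param model `"gamma_variate"` (default) or `"biexponential"`.
#' @param params named list. Gamma-variate: `alpha` (default 2), `beta`
#'   (seconds, default 180), and either `A` or `peak` (curve maximum,
#'   default 20, used to set `A` when `A` is absent). Biexponential: `A`
#'   (default 30), `tau_fast` (default 60 s), `tau_slow` (default 1800 s).
#' @return nonnegative curve on `t_grid` with value 0 at t = 0.
#' @export
simulate_reference_curve <- function(t_grid,
                                     model = c("gamma_variate",
                                               "biexponential"),
                                     params = list()) {
  model <- match.arg(model)
  if (model == "gamma_variate") {
    alpha <- params$alpha %||% 2
    beta <- params$beta %||% 180
    if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive")
    a <- params$A
    if (is.null(a)) {
      peak <- params$peak %||% 20
      a <- peak / ((alpha * beta)^alpha * exp(-alpha))
    }
    if (a <= 0) stop("amplitude must be positive")
    curve <- a * t_grid^alpha * exp(-t_grid / beta)
  } else {
    a <- params$A %||% 30
    tf <- params$tau_fast %||% 60
    ts <- params$tau_slow %||% 1800
    if (a <= 0 || tf <= 0 || ts <= tf) {
      stop("need A > 0 and 0 < tau_fast < tau_slow")
    }
    curve <- a * (exp(-t_grid / ts) - exp(-t_grid / tf))
  }
  if (any(curve < -1e-12) || !any(curve > 0)) {
    stop("parameters yield a nonpositive curve")
  }
  pmax(curve, 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a baseline/blocking PET study with known ground truth
#'
#' Draws per-region SRTM parameters, generates noiseless TACs as
#' frame-averaged SRTM forward curves from a simulated reference, derives
#' the blocking-scan binding potentials from the planted occupancy field
#' (`BP_blocking = BP_baseline * (1 - occupancy/100)` exactly), and adds
#' zero-mean Gaussian frame noise with standard deviation
#' `noise_cv * peak / sqrt(duration_f / max duration)` (longer frames are
#' less noisy, mimicking count statistics). R1 and k2REF are shared across
#' the two scans, and both scans reuse one set of standard-normal draws, so
#' a zero occupancy field yields identical scans for the same seed.
#'
#' @param n_rois number of target regions (default 8).
#' @param r1_range,bp_range uniform sampling ranges for R1 and baseline
#'   BP_ND.
#' @param occupancy planted occupancy field in percent: a scalar (recycled),
#'   a length-2 range to sample uniformly, or a length-`n_rois` vector.
#' @param k2ref shared reference efflux rate, per minute (default 0.14).
#' @param noise_cv fractional noise level at the curve peak (default 0).
#' @param schedule [frame_schedule()] (default the 30-frame protocol).
#' @param ref_model,ref_params passed to [simulate_reference_curve()].
#' @param dt fine grid step in seconds.
#' @param seed integer seed; every stochastic draw is derived from it.
#' @return list with `baseline` and `blocking` ([tac_set()]s), `truth`
#'   (data.frame roi, R1, bp_baseline, bp_blocking, occupancy, k2ref),
#'   `t_grid`, `ref_dense`, `noise_cv`, `seed`.
#' @export
simulate_study <- function(n_rois = 8L,
                           r1_range = c(0.7, 1.3),
                           bp_range = c(0.2, 4),
                           occupancy = c(20, 75),
                           k2ref = 0.14,
                           noise_cv = 0,
                           schedule = default_frame_schedule(),
                           ref_model = "gamma_variate",
                           ref_params = list(),
                           dt = 1, seed = 1L) {
  stopifnot(inherits(schedule, "frame_schedule"), noise_cv >= 0)
  end <- frame_end(schedule)
  t_grid <- seq(0, end, by = dt)
  if (t_grid[length(t_grid)] < end) t_grid <- c(t_grid, end)
  ref_dense <- simulate_reference_curve(t_grid, ref_model, ref_params)
  nf <- length(schedule)
  draws <- with_seed(seed, {
    r1 <- stats::runif(n_rois, r1_range[1], r1_range[2])
    bp <- stats::runif(n_rois, bp_range[1], bp_range[2])
    occ <- if (length(occupancy) == 1L) rep(occupancy, n_rois)
      else if (length(occupancy) == 2L && n_rois != 2L)
        stats::runif(n_rois, occupancy[1], occupancy[2])
      else occupancy
    z <- matrix(stats::rnorm((n_rois + 1L) * nf), n_rois + 1L, nf)
    list(r1 = r1, bp = bp, occ = occ, z = z)
  })
  occ <- draws$occ
  if (length(occ) != n_rois) stop("occupancy field length mismatch")
  if (any(occ < 0 | occ > 100)) stop("occupancy field must lie in [0, 100]")
  bp_base <- draws$bp
  bp_block <- bp_base * (1 - occ / 100)
  rel_dur <- schedule$duration / max(schedule$duration)
  make_scan <- function(bps) {
    clean <- t(vapply(seq_len(n_rois), function(i) {
      frame_average(srtm_forward(draws$r1[i], k2ref, bps[i],
                                 ref_dense, t_grid),
                    t_grid, schedule)
    }, numeric(nf)))
    ref_f <- frame_average(ref_dense, t_grid, schedule)
    if (noise_cv > 0) {
      sd_mat <- outer(noise_cv * apply(clean, 1, max), 1 / sqrt(rel_dur))
      clean <- clean + draws$z[seq_len(n_rois), , drop = FALSE] * sd_mat
      ref_f <- ref_f + draws$z[n_rois + 1L, ] *
        (noise_cv * max(ref_f)) / sqrt(rel_dur)
    }
    tac_set(clean, ref_f, schedule,
            roi_ids = sprintf("roi%02d", seq_len(n_rois)),
            reference_id = "cerebellum")
  }
  baseline <- make_scan(bp_base)
  blocking <- make_scan(bp_block)
  truth <- data.frame(roi = sprintf("roi%02d", seq_len(n_rois)),
                      R1 = draws$r1, bp_baseline = bp_base,
                      bp_blocking = bp_block, occupancy = occ,
                      k2ref = k2ref, stringsAsFactors = FALSE)
  list(baseline = baseline, blocking = blocking, truth = truth,
       t_grid = t_grid, ref_dense = ref_dense,
       noise_cv = noise_cv, seed = seed)
}

#' Paint a dynamic 4D phantom from a label volume and a TAC set
#'
#' Every voxel of label i carries that label's TAC plus independent
#' Gaussian voxel noise; background (label 0) is zero everywhere.
#'
#' @param labels 3D integer label array.
#' @param tacs a [tac_set()]; every nonzero label must match a target ROI id
#'   or the reference id.
#' @param voxel_noise Gaussian noise SD added per voxel and frame.
#' @param seed integer seed.
#' @return 4D array (x, y, z, frame).
#' @export
simulate_dynamic_phantom <- function(labels, tacs, voxel_noise = 0,
                                     seed = 1L) {
  stopifnot(inherits(tacs, "tac_set"), length(dim(labels)) == 3L)
  nf <- length(tacs$schedule)
  curves <- rbind(tacs$values, tacs$reference)
  rownames(curves)[nrow(curves)] <- as.character(tacs$reference_id)
  lab <- as.integer(labels)
  ids <- sort(unique(lab[lab > 0L]))
  missing_ids <- setdiff(as.character(ids), rownames(curves))
  if (length(missing_ids)) {
    stop("no TAC for label(s): ", paste(missing_ids, collapse = ", "))
  }
  nvox <- length(lab)
  mat <- matrix(0, nvox, nf)
  for (id in ids) {
    sel <- lab == id
    mat[sel, ] <- rep(curves[as.character(id), ], each = sum(sel))
  }
  if (voxel_noise > 0) {
    nz <- lab > 0L
    mat[nz, ] <- mat[nz, ] + with_seed(seed, {
      matrix(stats::rnorm(sum(nz) * nf, sd = voxel_noise), sum(nz), nf)
    })
  }
  array(mat, dim = c(dim(labels), nf))
}

#' Partition a mask into K contiguous, near-equal blocks
#'
#' Recursive coordinate bisection: the voxel set is repeatedly split along
#' its longest spatial axis in proportion to the cluster counts assigned to
#' each half. Used to plant spatially compact ground-truth parcels.
#'
#' @param mask 3D logical array.
#' @param k number of blocks.
#' @return integer vector of labels 1..k over `which(mask)` voxel order.
#' @export
partition_mask_blocks <- function(mask, k) {
  coords <- which(mask, arr.ind = TRUE)
  n <- nrow(coords)
  if (k > n) stop("k exceeds voxel count")
  labels <- integer(n)
  next_label <- 0L
  recurse <- function(idx, kk) {
    if (kk == 1L) {
      next_label <<- next_label + 1L
      labels[idx] <<- next_label
      return(invisible())
    }
    rng <- apply(coords[idx, , drop = FALSE], 2, function(v) diff(range(v)))
    ax <- which.max(rng)
    ord <- idx[order(coords[idx, ax], coords[idx, (ax %% 3) + 1],
                     coords[idx, ((ax + 1) %% 3) + 1])]
    k1 <- kk %/% 2L
    n1 <- round(length(ord) * k1 / kk)
    n1 <- min(max(n1, k1), length(ord) - (kk - k1))
    recurse(ord[seq_len(n1)], k1)
    recurse(ord[-seq_len(n1)], kk - k1)
  }
  recurse(seq_len(n), as.integer(k))
  labels
}

#' Simulate resting-state voxel time series with planted parcel structure
#'
#' Each planted parcel has a latent standard-normal series; voxel series mix
#' the parcel latent with independent noise so the expected within-parcel
#' correlation is `within_r`. Latents across parcels share a global
#' component so the expected between-parcel voxel correlation is
#' `between_r`. Parcels are spatially contiguous blocks
#' ([partition_mask_blocks()]), so the spatially constrained parcellation
#' graph can recover them.
#'
#' @param mask 3D logical array, or an integer vector of dimensions (a full
#'   cuboid mask of those dimensions is used).
#' @param k number of planted parcels.
#' @param within_r expected within-parcel correlation (0 < within_r <= 1).
#' @param between_r expected between-parcel correlation
#'   (0 <= between_r < within_r).
#' @param t_len timepoints per subject (default 180).
#' @param n_subjects number of subjects (default 1).
#' @param seed integer seed.
#' @return list with `subjects` (list of voxels x time matrices), `mask`,
#'   `labels` (true labels over `which(mask)` order), `labels_volume`, `k`.
#' @export
simulate_rsfmri <- function(mask = c(8L, 8L, 8L), k = 8L,
                            within_r = 0.8, between_r = 0,
                            t_len = 180L, n_subjects = 1L, seed = 1L) {
  if (!is.array(mask)) mask <- array(TRUE, dim = mask)
  if (t_len < 2L) stop("need at least 2 timepoints")
  if (!(between_r >= 0 && between_r < within_r && within_r <= 1)) {
    stop("need 0 <= between_r < within_r <= 1")
  }
  labels <- partition_mask_blocks(mask, k)
  n <- sum(mask)
  rho_l <- between_r / within_r
  subjects <- with_seed(seed, {
    lapply(seq_len(n_subjects), function(s) {
      g <- stats::rnorm(t_len)
      lat <- sqrt(rho_l) * matrix(g, k, t_len, byrow = TRUE) +
        sqrt(1 - rho_l) * matrix(stats::rnorm(k * t_len), k, t_len)
      ts <- sqrt(within_r) * lat[labels, , drop = FALSE]
      if (within_r < 1) {
        ts <- ts + sqrt(1 - within_r) * matrix(stats::rnorm(n * t_len),
                                               n, t_len)
      }
      ts
    })
  })
  vol <- array(0L, dim(mask))
  vol[mask] <- labels
  list(subjects = subjects, mask = mask, labels = labels,
       labels_volume = vol, k = as.integer(k), seed = seed)
}
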