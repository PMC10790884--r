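# Rates are expressed per minute at every API boundary (PET convention) and
# converted to per second in this one place; all internal time axes are in
# seconds.
per_min <- function(k) k / 60

# Trapezoidal convolution of a curve sampled on a uniform grid (step dt,
# first point t = 0) with the kernel exp(-k * t); k in per second.
# Computed via cumulative sums of v * exp(k t); for very stiff kernels
# (k * t_max > 600, where the exponentials would overflow) an equivalent
# O(n) recursion is used.
exp_conv <- function(v, dt, k) {
  n <- length(v)
  tmax <- (n - 1) * dt
  if (k * tmax < 600) {
    tt <- (seq_len(n) - 1) * dt
    g <- v * exp(k * tt)
    ci <- c(0, cumsum((g[-1] + g[-n]) / 2)) * dt
    exp(-k * tt) * ci
  } else {
    e <- exp(-k * dt)
    y <- numeric(n)
    for (i in 2:n) y[i] <- e * y[i - 1] + dt / 2 * (v[i] + e * v[i - 1])
    y
  }
}

check_uniform_grid <- function(t_grid) {
  if (length(t_grid) < 2L) stop("grid must have at least 2 points")
  dts <- diff(t_grid)
  if (abs(t_grid[1]) > 1e-9 || max(abs(dts - dts[1])) > 1e-6 * dts[1]) {
    stop("reference must be sampled on a uniform fine grid starting at 0")
  }
  dts[1]
}

#' SRTM forward model on a dense time grid
#'
#' The simplified reference tissue model expresses a target-region curve in
#' terms of the reference-region curve:
#' `C_T(t) = R1 * C_R(t) + R1 * (k2REF - k2a) * [C_R (x) exp(-k2a t)](t)`
#' with `k2 = R1 * k2REF` and apparent efflux `k2a = k2 / (1 + BP_ND)`.
#' The convolution is evaluated by the trapezoid rule on the fine grid.
#'
#' @param r1 delivery ratio (dimensionless, > 0).
#' @param k2ref reference efflux rate in per minute (> 0).
#' @param bp binding potential BP_ND (dimensionless, > -1).
#' @param reference reference curve sampled on `t_grid`.
#' @param t_grid uniform time grid in seconds starting at 0.
#' @return target curve on `t_grid`; `C_T(0) = R1 * C_R(0)`.
#' @export
srtm_forward <- function(r1, k2ref, bp, reference, t_grid) {
  dt <- check_uniform_grid(t_grid)
  if (length(reference) != length(t_grid)) stop("reference/grid length mismatch")
  if (r1 <= 0 || k2ref <= 0) stop("R1 and k2REF must be positive")
  if (bp <= -1) stop("BP_ND must exceed -1 (k2a must be positive)")
  k2ref_s <- per_min(k2ref)
  k2a_s <- r1 * k2ref_s / (1 + bp)
  r1 * reference + r1 * (k2ref_s - k2a_s) * exp_conv(reference, dt, k2a_s)
}

#' Interval-average a dense curve over a frame schedule
#'
#' Each frame's value is the time average of the dense curve over the frame
#' interval (trapezoid rule on the fine grid), matching what a PET frame
#' measures.
#'
#' @param dense curve sampled on `t_grid`.
#' @param t_grid time grid in seconds (increasing, first point 0).
#' @param schedule a [frame_schedule()]; the grid must cover it.
#' @return one value per frame.
#' @export
frame_average <- function(dense, t_grid, schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  n <- length(t_grid)
  if (length(dense) != n) stop("dense/grid length mismatch")
  if (t_grid[1] > schedule$start[1] + 1e-9 ||
      t_grid[n] < frame_end(schedule) - 1e-9) {
    stop("grid does not cover the frame schedule")
  }
  ci <- c(0, cumsum(diff(t_grid) * (dense[-1] + dense[-n]) / 2))
  cif <- stats::approxfun(t_grid, ci, rule = 2)
  ends <- schedule$start + schedule$duration
  (cif(ends) - cif(schedule$start)) / schedule$duration
}

#' Reconstruct a dense reference curve from its frame-averaged TAC
#'
#' Frame values are interval averages, so plain interpolation through the
#' midpoints misrepresents a curved reference near its peak (frames there
#' are minutes long). Starting from midpoint interpolation (anchored at 0 at
#' injection), the curve is iteratively corrected so that its own frame
#' averages match the observed values.
#'
#' @param values per-frame reference TAC.
#' @param schedule the [frame_schedule()].
#' @param dt fine grid step in seconds (default 1).
#' @param max_iter,rtol iteration controls.
#' @return list with `t_grid` and `curve`.
#' @export
dense_reference <- function(values, schedule, dt = 1,
                            max_iter = 30L, rtol = 1e-10) {
  stopifnot(inherits(schedule, "frame_schedule"))
  end <- frame_end(schedule)
  t_grid <- seq(0, end, by = dt)
  if (t_grid[length(t_grid)] < end) t_grid <- c(t_grid, end)
  mid <- frame_midpoints(schedule)
  cur <- stats::approx(c(0, mid), c(0, values), xout = t_grid, rule = 2)$y
  scale <- max(abs(values))
  if (scale == 0) return(list(t_grid = t_grid, curve = cur))
  for (it in seq_len(max_iter)) {
    resid <- values - frame_average(cur, t_grid, schedule)
    if (max(abs(resid)) < rtol * scale) break
    cur <- cur + stats::approx(c(0, mid), c(0, resid),
                               xout = t_grid, rule = 2)$y
  }
  list(t_grid = t_grid, curve = cur)
}

#' Convert binding potential to distribution volume ratio
#'
#' @param bp binding potential BP_ND (> -1).
#' @return DVR = BP_ND + 1.
#' @export
bpnd_to_dvr <- function(bp) {
  if (any(bp <= -1)) stop("BP_ND must exceed -1")
  bp + 1
}

# Given fixed k2REF and k2a (per second), the SRTM prediction is linear in
# R1: C_T = R1 * B with basis B = refF + (k2REF - k2a) * convF. Weighted
# least squares gives R1 in closed form; out-of-bounds R1 is clipped.
# Returns c(r1, wrss).
r1_wls <- function(basis, y, w, r1_bounds) {
  denom <- sum(w * basis^2)
  r1 <- if (denom > 0) sum(w * basis * y) / denom else r1_bounds[1]
  r1 <- min(max(r1, r1_bounds[1]), r1_bounds[2])
  c(r1, sum(w * (y - r1 * basis)^2))
}

#' Fit the SRTM simultaneously to all regional TACs with coupled k2REF
#'
#' Estimates per-region `(R1, BP_ND)` and a single reference efflux rate
#' `k2REF` shared by every region of the scan, by minimizing the summed
#' weighted residual sum of squares over all regions. The coupling is solved
#' by profiling: an outer bounded scalar search over k2REF and, for each
#' candidate, independent per-region fits (the regions are separable given
#' k2REF). Each inner fit profiles the apparent efflux rate k2a on a log
#' grid with the delivery ratio R1 obtained in closed form by weighted
#' linear least squares, then polishes k2a continuously at the selected
#' k2REF. The procedure is deterministic.
#'
#' @param tacs a [tac_set()].
#' @param weights per-frame weights (default those stored in `tacs`).
#' @param k2ref_bounds search interval for k2REF in per minute.
#' @param r1_bounds,bp_bounds parameter boxes for R1 and BP_ND.
#' @param dt fine grid step in seconds for the convolution (default 1).
#' @param n_k2a size of the inner log-spaced k2a profile grid.
#' @param tol convergence tolerance on the outer objective.
#' @param max_outer maximum outer iterations.
#' @param couple if `FALSE`, each region is fitted with its own k2REF
#'   (independent fits; used as the comparison arm for the coupling).
#' @return object of class `srtm_fit` with elements `pars` (data.frame:
#'   roi, R1, k2REF, BP_ND, DVR, WRSS, converged), `k2REF` (shared value,
#'   NA when uncoupled), `wrss` (total), `wrss_trace` (best-so-far outer
#'   trace, non-increasing), `iterations`, `converged`.
#' @export
fit_srtm_coupled <- function(tacs, weights = NULL,
                             k2ref_bounds = c(0.01, 1),
                             r1_bounds = c(0.1, 3),
                             bp_bounds = c(-0.5, 10),
                             dt = 1, n_k2a = 120L,
                             tol = 1e-8, max_outer = 200L,
                             couple = TRUE) {
  stopifnot(inherits(tacs, "tac_set"))
  if (is.null(weights)) weights <- tacs$weights
  if (!any(tacs$reference > 0)) stop("reference TAC is nonpositive everywhere")
  if (!couple) {
    fits <- lapply(seq_along(tacs$roi_ids), function(i) {
      fit_srtm_coupled(subset_tac_set(tacs, tacs$roi_ids[i]),
                       weights = weights, k2ref_bounds = k2ref_bounds,
                       r1_bounds = r1_bounds, bp_bounds = bp_bounds,
                       dt = dt, n_k2a = n_k2a, tol = tol,
                       max_outer = max_outer, couple = TRUE)
    })
    pars <- do.call(rbind, lapply(fits, `[[`, "pars"))
    return(structure(list(pars = pars, k2REF = NA_real_,
                          wrss = sum(pars$WRSS),
                          wrss_trace = NULL,
                          iterations = max(vapply(fits, `[[`, 0L,
                                                  "iterations")),
                          converged = all(pars$converged)),
                     class = "srtm_fit"))
  }

  sched <- tacs$schedule
  dr <- dense_reference(tacs$reference, sched, dt = dt)
  t_grid <- dr$t_grid
  ref_dense <- dr$curve
  ref_f <- frame_average(ref_dense, t_grid, sched)
  y <- tacs$values
  n_roi <- nrow(y)
  w <- weights
  sy2 <- as.numeric(y^2 %*% w)

  # inner profile grid over k2a (per second), shared by all k2REF probes
  k2a_lo <- per_min(r1_bounds[1] * k2ref_bounds[1] / (1 + bp_bounds[2]))
  k2a_hi <- per_min(r1_bounds[2] * k2ref_bounds[2] /
                      (1 + max(bp_bounds[1], -0.9)))
  k2a_grid <- exp(seq(log(k2a_lo), log(k2a_hi), length.out = n_k2a))
  conv_f <- vapply(k2a_grid, function(k) {
    frame_average(exp_conv(ref_dense, dt, k), t_grid, sched)
  }, numeric(length(sched)))            # frames x n_k2a

  # Profile objective: for one k2REF (per second), the best achievable
  # summed WRSS; inner minimum located on the k2a grid and sharpened by
  # parabolic interpolation in log k2a.
  inner_grid <- function(k2ref_s) {
    basis <- ref_f + t(t(conv_f) * (k2ref_s - k2a_grid))   # frames x J
    numer <- crossprod(basis * w, t(y))                    # J x n_roi
    denom <- colSums(basis^2 * w)                          # J
    r1 <- numer / denom
    r1[] <- pmin(pmax(r1, r1_bounds[1]), r1_bounds[2])
    wrss <- matrix(sy2, nrow(r1), n_roi, byrow = TRUE) -
      2 * r1 * numer + r1^2 * denom
    bp <- r1 * k2ref_s / k2a_grid - 1
    bad <- bp < bp_bounds[1] | bp > bp_bounds[2]
    wrss_m <- wrss
    wrss_m[bad] <- Inf
    total <- 0
    jstar <- integer(n_roi)
    for (r in seq_len(n_roi)) {
      col <- wrss_m[, r]
      if (!any(is.finite(col))) col <- wrss[, r]
      j <- which.min(col)
      jstar[r] <- j
      val <- col[j]
      if (j > 1L && j < length(k2a_grid) &&
          is.finite(col[j - 1]) && is.finite(col[j + 1])) {
        # parabola through the bracketing triple in log k2a
        d1 <- (col[j + 1] - col[j - 1]) / 2
        d2 <- col[j + 1] - 2 * col[j] + col[j - 1]
        if (d2 > 0) val <- col[j] - d1^2 / (2 * d2)
      }
      total <- total + val
    }
    list(total = total, jstar = jstar)
  }

  # outer search over k2REF: coarse log scan, then golden section
  obj <- function(k2ref_s) inner_grid(k2ref_s)$total
  scan <- exp(seq(log(per_min(k2ref_bounds[1])),
                  log(per_min(k2ref_bounds[2])), length.out = 25L))
  fscan <- vapply(scan, obj, numeric(1))
  ib <- which.min(fscan)
  lo <- scan[max(1L, ib - 1L)]
  hi <- scan[min(length(scan), ib + 1L)]
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- obj(x1); f2 <- obj(x2)
  best <- min(fscan)
  trace <- c(cummin(fscan), min(best, f1, f2))
  iterations <- length(scan) + 2L
  converged <- FALSE
  while (iterations < max_outer) {
    if (f1 < f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- obj(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- obj(x2)
    }
    iterations <- iterations + 1L
    new_best <- min(best, f1, f2)
    trace <- c(trace, new_best)
    rel <- (b - a) / max(b, 1e-12)
    if ((best - new_best) < tol * max(1, new_best) && rel < 1e-7) {
      converged <- TRUE
      best <- new_best
      break
    }
    best <- new_best
  }
  k2ref_s <- (a + b) / 2
  ig <- inner_grid(k2ref_s)

  # continuous per-region polish of k2a at the selected k2REF
  pars <- data.frame(roi = as.character(tacs$roi_ids),
                     R1 = NA_real_, k2REF = k2ref_s * 60,
                     BP_ND = NA_real_, DVR = NA_real_, WRSS = NA_real_,
                     converged = converged,
                     stringsAsFactors = FALSE)
  for (r in seq_len(n_roi)) {
    j <- ig$jstar[r]
    lo_k <- k2a_grid[max(1L, j - 1L)]
    hi_k <- k2a_grid[min(length(k2a_grid), j + 1L)]
    yr <- y[r, ]
    froi <- function(lk) {
      k2a_s <- exp(lk)
      b_vec <- ref_f + (k2ref_s - k2a_s) *
        frame_average(exp_conv(ref_dense, dt, k2a_s), t_grid, sched)
      r1_wls(b_vec, yr, w, r1_bounds)[2]
    }
    op <- stats::optimize(froi, lower = log(lo_k), upper = log(hi_k),
                          tol = 1e-10)
    k2a_s <- exp(op$minimum)
    b_vec <- ref_f + (k2ref_s - k2a_s) *
      frame_average(exp_conv(ref_dense, dt, k2a_s), t_grid, sched)
    sol <- r1_wls(b_vec, yr, w, r1_bounds)
    pars$R1[r] <- sol[1]
    pars$BP_ND[r] <- sol[1] * k2ref_s / k2a_s - 1
    pars$WRSS[r] <- sol[2]
  }
  pars$DVR <- pars$BP_ND + 1
  structure(list(pars = pars, k2REF = k2ref_s * 60, wrss = sum(pars$WRSS),
                 wrss_trace = trace, iterations = iterations,
                 converged = converged),
            class = "srtm_fit")
}

#' @export
print.srtm_fit <- function(x, ...) {
  cat(sprintf("<srtm_fit> %d ROIs, k2REF = %s /min, total WRSS = %.4g, %s\n",
              nrow(x$pars),
              ifelse(is.na(x$k2REF), "per-ROI", sprintf("%.4f", x$k2REF)),
              x$wrss,
              ifelse(x$converged, "converged", "NOT converged")))
  invisible(x)
}
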