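test_that("forward model degenerates to the reference when BP = 0, R1 = 1", {
  t_grid <- seq(0, 5400, by = 1)
  ref <- simulate_reference_curve(t_grid)
  for (k2ref in c(0.05, 0.14, 0.5)) {
    ct <- srtm_forward(1, k2ref, 0, ref, t_grid)
    expect_equal(ct, ref, tolerance = 1e-10)
  }
})

test_that("step reference reaches the DVR equilibrium ratio", {
  t_grid <- seq(0, 5400, by = 1)
  step <- rep(10, length(t_grid))
  # the transient decays as exp(-k2a t); k2a >= 0.06 /min puts it well
  # below 1% by 90 min
  for (bp in c(0.5, 1.5, 2.5)) {
    r1 <- 1.1
    k2ref <- 0.2
    k2a <- r1 * k2ref / (1 + bp)
    expect_gte(k2a, 0.06)
    ct <- srtm_forward(r1, k2ref, bp, step, t_grid)
    ratio <- ct[length(ct)] / step[1]
    expect_equal(ratio, 1 + bp, tolerance = 0.01)
  }
})

test_that("forward model validates its domain", {
  t_grid <- seq(0, 100, by = 1)
  ref <- simulate_reference_curve(t_grid)
  expect_error(srtm_forward(1, 0.1, -1.5, ref, t_grid), "BP_ND")
  expect_error(srtm_forward(-1, 0.1, 1, ref, t_grid), "positive")
  expect_error(srtm_forward(1, 0.1, 1, ref[c(1, 3, 10)], c(0, 2, 9)),
               "uniform")
})

test_that("frame averaging is exact on constants and linear curves", {
  sched <- default_frame_schedule()
  t_grid <- seq(0, 5400, by = 1)
  expect_equal(frame_average(rep(3.7, length(t_grid)), t_grid, sched),
               rep(3.7, 30))
  expect_equal(frame_average(t_grid, t_grid, sched),
               frame_midpoints(sched))
  expect_error(frame_average(t_grid[1:100], t_grid[1:100], sched), "cover")
})

test_that("frame averages are grid-converged", {
  sched <- default_frame_schedule()
  g1 <- seq(0, 5400, by = 1)
  g2 <- seq(0, 5400, by = 0.1)
  f1 <- frame_average(simulate_reference_curve(g1), g1, sched)
  f2 <- frame_average(simulate_reference_curve(g2), g2, sched)
  expect_lt(max(abs(f1 - f2) / max(f2)), 1e-4)
})

test_that("forward model matches an independent ODE-integrator oracle", {
  skip_if_not_installed("deSolve")
  sched <- default_frame_schedule()
  t_grid <- seq(0, 5400, by = 1)
  a <- 30; tf <- 60; ts <- 1800
  ref <- simulate_reference_curve(t_grid, "biexponential",
                                  list(A = a, tau_fast = tf, tau_slow = ts))
  mids <- frame_midpoints(sched)
  set.seed(14)
  pars <- cbind(r1 = runif(10, 0.7, 1.3), k2ref = runif(10, 0.05, 0.3),
                bp = runif(10, 0.2, 4))
  for (i in seq_len(10)) {
    r1 <- pars[i, "r1"]; k2ref_s <- pars[i, "k2ref"] / 60
    k2a_s <- r1 * k2ref_s / (1 + pars[i, "bp"])
    deriv <- function(t, y, p) {
      cr <- a * (exp(-t / ts) - exp(-t / tf))
      crp <- a * (-exp(-t / ts) / ts + exp(-t / tf) / tf)
      list(r1 * (crp + k2ref_s * cr) - k2a_s * y)
    }
    ode <- deSolve::ode(c(ct = 0), times = c(0, mids), deriv, parms = NULL,
                        method = "lsoda", rtol = 1e-10, atol = 1e-12)
    oracle <- ode[-1, "ct"]
    dense <- srtm_forward(r1, pars[i, "k2ref"], pars[i, "bp"], ref, t_grid)
    mine <- approx(t_grid, dense, xout = mids)$y
    expect_lt(max(abs(mine - oracle) / pmax(abs(oracle), 1e-8)), 1e-3)
  }
})

test_that("coupled fit recovers noiseless parameters within 0.5%", {
  sim <- noiseless_study()
  fit <- fit_srtm_coupled(sim$baseline)
  expect_true(fit$converged)
  expect_lt(abs(fit$k2REF - sim$truth$k2ref[1]) / sim$truth$k2ref[1], 0.005)
  expect_lt(max(abs(fit$pars$R1 - sim$truth$R1) / sim$truth$R1), 0.005)
  expect_lt(max(abs(fit$pars$BP_ND - sim$truth$bp_baseline) /
                  sim$truth$bp_baseline), 0.005)
  expect_equal(fit$pars$DVR, fit$pars$BP_ND + 1)
  expect_true(all(fit$pars$WRSS >= 0))
})

test_that("a null-binding region fits BP_ND within 0.01 of zero", {
  sim <- simulate_study(n_rois = 1L, bp_range = c(0, 0), occupancy = 0,
                        noise_cv = 0, seed = 5)
  fit <- fit_srtm_coupled(sim$baseline)
  expect_lt(abs(fit$pars$BP_ND), 0.01)
})

test_that("fit is equivariant under a common intensity rescaling", {
  sim <- noiseless_study(n_rois = 4L, seed = 8L)
  f1 <- fit_srtm_coupled(sim$baseline)
  scaled <- tac_set(sim$baseline$values * 37, sim$baseline$reference * 37,
                    sim$baseline$schedule, roi_ids = sim$baseline$roi_ids,
                    reference_id = sim$baseline$reference_id)
  f2 <- fit_srtm_coupled(scaled)
  expect_equal(f2$pars$R1, f1$pars$R1, tolerance = 1e-6)
  expect_equal(f2$pars$BP_ND, f1$pars$BP_ND, tolerance = 1e-6)
  expect_equal(f2$k2REF, f1$k2REF, tolerance = 1e-6)
})

test_that("outer objective trace never increases", {
  sim <- simulate_study(n_rois = 4L, noise_cv = 0.05, seed = 17)
  fit <- fit_srtm_coupled(sim$baseline)
  expect_true(all(diff(fit$wrss_trace) <= 1e-12))
})

test_that("uncoupled fits give per-ROI k2REF and reject bad input", {
  sim <- noiseless_study(n_rois = 3L, seed = 4L)
  fu <- fit_srtm_coupled(sim$baseline, couple = FALSE)
  expect_true(is.na(fu$k2REF))
  expect_equal(nrow(fu$pars), 3L)
  zero <- tac_set(sim$baseline$values, rep(0, 30), sim$baseline$schedule,
                  roi_ids = sim$baseline$roi_ids)
  expect_error(fit_srtm_coupled(zero), "reference")
})

test_that("BP_ND to DVR conversion is exact", {
  expect_equal(bpnd_to_dvr(0), 1)
  expect_equal(bpnd_to_dvr(0.2), 1.2)   # the twin discard thresholds
  expect_equal(bpnd_to_dvr(2.25), 3.25)
  expect_error(bpnd_to_dvr(-1), "exceed")
})

test_that("dense reference reconstruction matches observed frame averages", {
  sched <- default_frame_schedule()
  t_grid <- seq(0, 5400, by = 1)
  truth <- simulate_reference_curve(t_grid)
  obs <- frame_average(truth, t_grid, sched)
  rec <- dense_reference(obs, sched, dt = 1)
  expect_lt(max(abs(frame_average(rec$curve, rec$t_grid, sched) - obs)),
            1e-8 * max(obs))
  expect_lt(max(abs(rec$curve - truth)) / max(truth), 0.02)
})
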