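test_that("occupancy formula is exact and invertible", {
  expect_equal(compute_occupancy(1.7, 1.7), 0)
  expect_equal(compute_occupancy(2.0, 1.0), 50)
  # inverting the formula against a printed subject value:
  # baseline 0.79 at 85.34% occupancy implies blocking BP 0.79 * (1 - 0.8534)
  block <- 0.79 * (1 - 0.8534)
  expect_equal(compute_occupancy(0.79, block), 85.34, tolerance = 1e-10)
  expect_error(compute_occupancy(0, 1), "undefined")
  # invariant to rescaling both scans
  expect_equal(compute_occupancy(2.4 * 13, 0.6 * 13),
               compute_occupancy(2.4, 0.6))
})

test_that("discard rules use strict printed inequalities in order", {
  rec <- data.frame(roi = c("a", "b", "c", "d", "e"),
                    bp_baseline = c(0.19, 0.20, 1.0, 1.0, 0.15),
                    occupancy_percent = c(50, 100.0, -3, 101, 120))
  out <- apply_roi_filters(rec)
  expect_equal(out$discard_reason,
               c("low_bp", "none", "impossible_occupancy",
                 "impossible_occupancy", "low_bp"))
  expect_equal(out$retained, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  # explicit DVR column triggers the low_dvr rule independently
  rec2 <- data.frame(roi = "f", bp_baseline = 0.5,
                     occupancy_percent = 50, dvr = 1.1)
  expect_equal(apply_roi_filters(rec2)$discard_reason, "low_dvr")
  # boundary values retained: bp 0.2 -> dvr 1.2, occupancy 0 and 100
  rec3 <- data.frame(roi = c("g", "h"), bp_baseline = c(0.2, 1),
                     occupancy_percent = c(0, 100))
  expect_true(all(apply_roi_filters(rec3)$retained))
})

test_that("a clean study passes the refit loop unchanged in one pass", {
  sim <- simulate_study(n_rois = 6L, bp_range = c(0.5, 4),
                        occupancy = c(20, 75), noise_cv = 0, seed = 31)
  res <- filter_refit_loop(sim$baseline, sim$blocking)
  expect_equal(res$passes, 1L)
  expect_true(all(res$table$retained))
  single_b <- fit_srtm_coupled(sim$baseline)
  expect_equal(res$table$bp_baseline[match(single_b$pars$roi,
                                           res$table$roi)],
               single_b$pars$BP_ND)
  m <- merge(res$table, sim$truth, by = "roi")
  expect_lt(max(abs(m$occupancy_percent - m$occupancy)), 2)
})

test_that("planted low-binding regions are discarded with the right reason", {
  set.seed(41)
  bp <- c(0.1, 0.1, runif(8, 0.8, 3))
  # scans rebuilt below with the planted BP vector
  sim <- simulate_study(n_rois = 10L, bp_range = c(1, 1),
                        occupancy = rep(40, 10), noise_cv = 0, seed = 41)
  t_grid <- sim$t_grid
  mk <- function(bps) {
    vals <- t(vapply(seq_along(bps), function(i) {
      frame_average(srtm_forward(sim$truth$R1[i], 0.14, bps[i],
                                 sim$ref_dense, t_grid),
                    t_grid, sim$baseline$schedule)
    }, numeric(30)))
    tac_set(vals, sim$baseline$reference, sim$baseline$schedule,
            roi_ids = sim$truth$roi, reference_id = "cerebellum")
  }
  base <- mk(bp)
  block <- mk(bp * (1 - 0.4))
  res <- filter_refit_loop(base, block)
  dropped <- res$table[!res$table$retained, ]
  expect_setequal(dropped$roi, c("roi01", "roi02"))
  expect_true(all(dropped$discard_reason == "low_bp"))
  kept <- res$table[res$table$retained, ]
  expect_lt(max(abs(kept$occupancy_percent - 40)), 2)
})

test_that("blocking BP above baseline is discarded as impossible occupancy", {
  sim <- simulate_study(n_rois = 5L, bp_range = c(1, 3),
                        occupancy = rep(40, 5), noise_cv = 0, seed = 43)
  base <- sim$baseline
  block <- sim$blocking
  # swap the scans for one region: its occupancy becomes negative
  tmp <- base$values[2, ]
  base$values[2, ] <- block$values[2, ]
  block$values[2, ] <- tmp
  res <- filter_refit_loop(base, block)
  bad <- res$table[res$table$roi == "roi02", ]
  expect_false(bad$retained)
  expect_equal(bad$discard_reason, "impossible_occupancy")
})

test_that("the refit loop is idempotent on its retained output", {
  set.seed(47)
  bp <- c(0.1, runif(5, 0.8, 3))
  sim <- simulate_study(n_rois = 6L, bp_range = c(1, 1),
                        occupancy = rep(40, 6), noise_cv = 0, seed = 47)
  t_grid <- sim$t_grid
  mk <- function(bps) {
    vals <- t(vapply(seq_along(bps), function(i) {
      frame_average(srtm_forward(sim$truth$R1[i], 0.14, bps[i],
                                 sim$ref_dense, t_grid),
                    t_grid, sim$baseline$schedule)
    }, numeric(30)))
    tac_set(vals, sim$baseline$reference, sim$baseline$schedule,
            roi_ids = sim$truth$roi, reference_id = "cerebellum")
  }
  base <- mk(bp); block <- mk(bp * 0.6)
  res1 <- filter_refit_loop(base, block)
  kept <- res1$table$roi[res1$table$retained]
  res2 <- filter_refit_loop(subset_tac_set(base, kept),
                            subset_tac_set(block, kept))
  expect_equal(res2$passes, 1L)
  expect_setequal(res2$table$roi[res2$table$retained], kept)
  expect_equal(res2$table$bp_baseline[match(kept, res2$table$roi)],
               res1$table$bp_baseline[match(kept, res1$table$roi)],
               tolerance = 1e-8)
})

test_that("all regions discarded raises an informative error", {
  sim <- simulate_study(n_rois = 2L, bp_range = c(0.05, 0.1),
                        occupancy = 40, noise_cv = 0, seed = 49)
  expect_error(filter_refit_loop(sim$baseline, sim$blocking),
               "all ROIs discarded")
})

test_that("study summary reproduces the packaged table statistics", {
  df <- load_table1_fixture()
  s <- summarize_occupancy(df, top_k = 7)
  expect_equal(s$n, 137L)
  expect_equal(round(s$bp_mean, 2), 1.44)
  expect_equal(round(s$bp_sd, 2), 0.33)
  expect_equal(round(s$occ_mean, 1), 39.5)
  expect_equal(round(s$occ_sd, 1), 10.9)
  expect_equal(s$occ_min, 19.84)
  expect_equal(s$occ_max, 74.72)
  expect_equal(s$top$occupancy[7], 63.12)
  expect_equal(s$top$roi[7], "sgACC")
  expect_true(all(c("l angular gyrus", "r angular gyrus",
                    "l intraparietal sulcus", "r intraparietal sulcus",
                    "sgACC") %in% s$top$roi))
  # recomputing means from subject cells changes nothing beyond rounding
  s2 <- summarize_occupancy(df, top_k = 7, use_printed_means = FALSE)
  expect_equal(s2$occ_mean, s$occ_mean, tolerance = 1e-3)
  expect_error(summarize_occupancy(df[0, ]), "empty")
})

test_that("summary works on single-subject pipeline output", {
  tab <- data.frame(roi = c("a", "b", "c"),
                    bp_baseline = c(1, 2, 3),
                    occupancy_percent = c(30, 40, 50),
                    retained = c(TRUE, TRUE, FALSE),
                    discard_reason = c("none", "none", "low_bp"))
  s <- summarize_occupancy(tab, top_k = 2)
  expect_equal(s$n, 2L)
  expect_equal(s$occ_mean, 35)
  expect_equal(s$bp_mean, 1.5)
  expect_equal(s$top$roi, c("b", "a"))
})
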