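#' Percent receptor occupancy from baseline and blocking binding potentials
#'
#' `Occ(%) = 100 * (BP_baseline - BP_blocking) / BP_baseline`. The value may
#' fall outside 0--100% (e.g. with noisy fits); such values are handled by
#' the discard rules in [apply_roi_filters()], not here.
#'
#' @param bp_baseline baseline BP_ND (nonzero).
#' @param bp_blocking blocking-scan BP_ND.
#' @return percent occupancy (vectorized).
#' @export
compute_occupancy <- function(bp_baseline, bp_blocking) {
  if (any(bp_baseline == 0)) stop("occupancy undefined for baseline BP_ND = 0")
  100 * (bp_baseline - bp_blocking) / bp_baseline
}

#' Apply the ROI discard rules
#'
#' Regions are discarded when the baseline binding potential is below
#' `bp_min` (default 0.2), the baseline distribution volume ratio is below
#' `dvr_min` (default 1.2), or the occupancy is impossible (below 0% or
#' above 100%). Comparisons are strict, so boundary values are retained.
#' The recorded reason is the first failing rule in the order
#' low_bp, low_dvr, impossible_occupancy.
#'
#' @param records data.frame with columns `bp_baseline` and
#'   `occupancy_percent`; an optional `dvr` column overrides the default
#'   `bp_baseline + 1`.
#' @param bp_min,dvr_min,occupancy_bounds thresholds (see [study_config()]).
#' @return `records` with added `retained` (logical) and `discard_reason`
#'   (`"none"`, `"low_bp"`, `"low_dvr"` or `"impossible_occupancy"`).
#' @export
apply_roi_filters <- function(records, bp_min = 0.2, dvr_min = 1.2,
                              occupancy_bounds = c(0, 100)) {
  stopifnot(all(c("bp_baseline", "occupancy_percent") %in% names(records)))
  dvr <- if ("dvr" %in% names(records)) records$dvr else
    records$bp_baseline + 1
  reason <- rep("none", nrow(records))
  occ <- records$occupancy_percent
  bad_occ <- occ < occupancy_bounds[1] | occ > occupancy_bounds[2]
  reason[bad_occ] <- "impossible_occupancy"
  reason[dvr < dvr_min] <- "low_dvr"
  reason[records$bp_baseline < bp_min] <- "low_bp"
  records$retained <- reason == "none"
  records$discard_reason <- reason
  records
}

#' Fit, filter and refit a baseline/blocking scan pair
#'
#' Runs the full occupancy analysis on one subject's scan pair: both scans
#' are fitted with [fit_srtm_coupled()] (k2REF coupled within each scan),
#' per-region occupancy is computed, the discard rules are applied, the
#' discarded regions are removed and the remaining regions refitted;
#' this repeats until the retained set is stable or `max_pass` passes.
#' Discarded regions keep the estimates and reason from the pass in which
#' they were dropped.
#'
#' @param tacs_baseline,tacs_blocking [tac_set()]s over the same ROI ids.
#' @param config a [study_config()] (thresholds and weighting scheme).
#' @param max_pass maximum filter/refit passes (default 5).
#' @param ... further arguments passed to [fit_srtm_coupled()].
#' @return list of class `occupancy_result`: `table` (data.frame with roi,
#'   bp_baseline, bp_blocking, occupancy_percent, retained, discard_reason,
#'   R1_baseline, R1_blocking), `k2REF_baseline`, `k2REF_blocking`,
#'   `passes`, `history` (retained ROI ids per pass), and the final fits.
#' @export
filter_refit_loop <- function(tacs_baseline, tacs_blocking,
                              config = study_config(), max_pass = 5L, ...) {
  stopifnot(inherits(tacs_baseline, "tac_set"),
            inherits(tacs_blocking, "tac_set"))
  ids <- as.character(tacs_baseline$roi_ids)
  if (!setequal(ids, as.character(tacs_blocking$roi_ids))) {
    stop("baseline and blocking scans must share ROI ids")
  }
  active <- ids
  dropped <- NULL
  history <- list()
  pass <- 0L
  repeat {
    pass <- pass + 1L
    fb <- fit_srtm_coupled(subset_tac_set(tacs_baseline, active), ...)
    fx <- fit_srtm_coupled(subset_tac_set(tacs_blocking, active), ...)
    tab <- data.frame(roi = fb$pars$roi,
                      bp_baseline = fb$pars$BP_ND,
                      bp_blocking = fx$pars$BP_ND[match(fb$pars$roi,
                                                        fx$pars$roi)],
                      R1_baseline = fb$pars$R1,
                      R1_blocking = fx$pars$R1[match(fb$pars$roi,
                                                     fx$pars$roi)],
                      stringsAsFactors = FALSE)
    tab$occupancy_percent <- compute_occupancy(tab$bp_baseline,
                                               tab$bp_blocking)
    tab <- apply_roi_filters(tab, bp_min = config$bp_min,
                             dvr_min = config$dvr_min,
                             occupancy_bounds = config$occupancy_bounds)
    history[[pass]] <- tab$roi[tab$retained]
    new_active <- tab$roi[tab$retained]
    dropped <- rbind(dropped, tab[!tab$retained, , drop = FALSE])
    if (length(new_active) == 0L) {
      stop("all ROIs discarded; reasons: ",
           paste(sprintf("%s=%s", dropped$roi, dropped$discard_reason),
                 collapse = ", "))
    }
    if (setequal(new_active, active) || pass >= max_pass) {
      active <- new_active
      break
    }
    active <- new_active
  }
  out <- rbind(tab[tab$retained, , drop = FALSE], dropped)
  out <- out[match(ids[ids %in% out$roi], out$roi), , drop = FALSE]
  rownames(out) <- NULL
  structure(list(table = out,
                 k2REF_baseline = fb$k2REF, k2REF_blocking = fx$k2REF,
                 passes = pass, history = history,
                 fit_baseline = fb, fit_blocking = fx),
            class = "occupancy_result")
}

#' @export
print.occupancy_result <- function(x, ...) {
  cat(sprintf(
    "<occupancy_result> %d/%d ROIs retained after %d pass(es); k2REF %.4f (baseline) / %.4f (blocking) /min\n",
    sum(x$table$retained), nrow(x$table), x$passes,
    x$k2REF_baseline, x$k2REF_blocking))
  invisible(x)
}

#' Study-level summary of regional binding potential and occupancy
#'
#' Per-region values are first averaged across subjects (arithmetic mean),
#' then summarized across regions: mean and sample standard deviation
#' (n - 1) of the per-region mean baseline BP_ND and occupancy, the range of
#' per-region mean occupancy, and the `top_k` regions by mean occupancy.
#'
#' Accepts either the packaged study table layout (columns `roi`,
#' `bp_s*`/`bp_mean`, `occ_s*`/`occ_mean`) or any data.frame with `roi` plus
#' matrices/columns of per-subject values named `bp_*` and `occ_*`; a
#' single-subject occupancy table from [filter_refit_loop()] (columns
#' `bp_baseline`, `occupancy_percent`) also works.
#'
#' @param table a data.frame as described above.
#' @param top_k number of top-occupancy regions to report (default 7).
#' @param use_printed_means if `TRUE` (default) and `bp_mean`/`occ_mean`
#'   columns are present, those are used as the per-region means; otherwise
#'   means are recomputed from the subject columns.
#' @return list of class `occupancy_summary`: `n`, `bp_mean`, `bp_sd`,
#'   `occ_mean`, `occ_sd`, `occ_min`, `occ_max`, `top` (data.frame roi,
#'   occupancy).
#' @export
summarize_occupancy <- function(table, top_k = 7L,
                                use_printed_means = TRUE) {
  if (nrow(table) == 0L) stop("empty table")
  if ("retained" %in% names(table)) table <- table[table$retained, ]
  if (nrow(table) == 0L) stop("no retained ROIs")
  get_mean <- function(prefix, mean_col, fallback) {
    if (use_printed_means && mean_col %in% names(table)) {
      return(table[[mean_col]])
    }
    cols <- grep(paste0("^", prefix, "_s[0-9]+$"), names(table), value = TRUE)
    if (length(cols)) return(rowMeans(table[cols]))
    if (fallback %in% names(table)) return(table[[fallback]])
    stop("no ", prefix, " columns found")
  }
  bp <- get_mean("bp", "bp_mean", "bp_baseline")
  occ <- get_mean("occ", "occ_mean", "occupancy_percent")
  ord <- order(occ, decreasing = TRUE)
  top <- data.frame(roi = table$roi[ord][seq_len(min(top_k, length(ord)))],
                    occupancy = occ[ord][seq_len(min(top_k, length(ord)))],
                    stringsAsFactors = FALSE)
  structure(list(n = nrow(table),
                 bp_mean = mean(bp), bp_sd = stats::sd(bp),
                 occ_mean = mean(occ), occ_sd = stats::sd(occ),
                 occ_min = min(occ), occ_max = max(occ), top = top),
            class = "occupancy_summary")
}

#' @export
print.occupancy_summary <- function(x, ...) {
  cat(sprintf("<occupancy_summary> %d ROIs\n", x$n))
  cat(sprintf("  baseline BP_ND: %.2f (+/- %.2f SD)\n", x$bp_mean, x$bp_sd))
  cat(sprintf("  occupancy: %.1f%% (+/- %.1f%% SD), range %.2f-%.2f%%\n",
              x$occ_mean, x$occ_sd, x$occ_min, x$occ_max))
  cat(sprintf("  top %d regions by occupancy:\n", nrow(x$top)))
  for (i in seq_len(nrow(x$top))) {
    cat(sprintf("    %-28s %6.2f%%\n", x$top$roi[i], x$top$occupancy[i]))
  }
  invisible(x)
}
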