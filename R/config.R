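#' Study configuration
#'
#' Bundles the tunable settings of the occupancy pipeline: the frame
#' schedule, the reference-region label, the parcel count, the correlation
#' threshold of the parcellation graph, the ROI discard thresholds, the
#' frame weighting scheme and the random seed.
#'
#' Thresholds follow the standard discard rules: regions with baseline
#' binding potential below `bp_min` (default 0.2) or distribution volume
#' ratio below `dvr_min` (default 1.2), or with occupancy outside
#' `occupancy_bounds` (default 0--100%), are discarded and the model refit.
#'
#' @param schedule a [frame_schedule()]; default the 30-frame protocol.
#' @param reference_label integer label of the reference region (cerebellum).
#' @param k number of parcels (default 200).
#' @param correlation_threshold Pearson r below which graph edges are dropped
#'   (default 0.5).
#' @param bp_min minimum retained baseline binding potential (default 0.2).
#' @param dvr_min minimum retained distribution volume ratio (default 1.2).
#' @param occupancy_bounds retained occupancy range in percent,
#'   default `c(0, 100)`.
#' @param weighting frame weighting scheme, `"duration"` or `"uniform"`.
#' @param seed integer random seed used for all stochastic steps.
#' @return a list of class `study_config`.
#' @export
study_config <- function(schedule = default_frame_schedule(),
                         reference_label = 1L,
                         k = 200L,
                         correlation_threshold = 0.5,
                         bp_min = 0.2,
                         dvr_min = 1.2,
                         occupancy_bounds = c(0, 100),
                         weighting = c("duration", "uniform"),
                         seed = 1L) {
  stopifnot(inherits(schedule, "frame_schedule"))
  weighting <- match.arg(weighting)
  if (k < 1) stop("k must be >= 1")
  if (bp_min <= 0 || dvr_min <= 0) stop("thresholds must be positive")
  if (length(occupancy_bounds) != 2L ||
      occupancy_bounds[1] >= occupancy_bounds[2]) {
    stop("occupancy_bounds must be an ordered pair")
  }
  structure(list(schedule = schedule,
                 reference_label = as.integer(reference_label),
                 k = as.integer(k),
                 correlation_threshold = correlation_threshold,
                 bp_min = bp_min, dvr_min = dvr_min,
                 occupancy_bounds = occupancy_bounds,
                 weighting = weighting,
                 seed = as.integer(seed)),
            class = "study_config")
}

# Evaluate an expression with a temporary RNG state seeded by `seed`,
# restoring the caller's state afterwards. All stochastic package code
# funnels through this so seeds are local and reproducible.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
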