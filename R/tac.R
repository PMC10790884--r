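#' Time-activity curves
#'
#' A time-activity curve (TAC) holds the decay-corrected radioactivity
#' concentration of one region at each frame of a schedule, together with
#' nonnegative per-frame fit weights.
#'
#' @param roi_id region label (integer or character).
#' @param values numeric activity concentration per frame.
#' @param schedule the [frame_schedule()] the values are sampled on.
#' @param weights nonnegative per-frame weights; default from
#'   [default_weights()] with the duration scheme.
#' @return object of class `tac`.
#' @export
tac <- function(roi_id, values, schedule,
                weights = default_weights(schedule)) {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (length(values) != length(schedule) ||
      length(weights) != length(schedule)) {
    stop("values, weights and schedule must have equal length")
  }
  if (any(weights < 0) || !any(weights > 0)) {
    stop("weights must be nonnegative with at least one positive")
  }
  structure(list(roi_id = roi_id, values = as.numeric(values),
                 schedule = schedule, weights = as.numeric(weights)),
            class = "tac")
}

#' Per-frame fit weights
#'
#' `"uniform"` gives every frame weight 1; `"duration"` weights each frame by
#' its duration relative to the longest frame (longer frames average more
#' counts and so have lower variance).
#'
#' @param schedule a [frame_schedule()].
#' @param scheme `"duration"` (default) or `"uniform"`.
#' @return numeric weight per frame.
#' @export
default_weights <- function(schedule, scheme = c("duration", "uniform")) {
  stopifnot(inherits(schedule, "frame_schedule"))
  scheme <- match.arg(scheme)
  switch(scheme,
         uniform = rep(1, length(schedule)),
         duration = schedule$duration / max(schedule$duration))
}

#' A set of regional TACs plus the reference-region TAC
#'
#' @param values numeric matrix, one row per target region, one column per
#'   frame (row names are used as region ids when `roi_ids` is missing).
#' @param reference numeric vector, the reference-region curve per frame.
#' @param schedule shared [frame_schedule()].
#' @param roi_ids region identifiers, one per row of `values`.
#' @param reference_id identifier of the reference region; must not collide
#'   with a target id.
#' @param weights shared per-frame weights (see [default_weights()]).
#' @return object of class `tac_set`.
#' @export
tac_set <- function(values, reference, schedule,
                    roi_ids = rownames(values),
                    reference_id = "reference",
                    weights = default_weights(schedule)) {
  stopifnot(inherits(schedule, "frame_schedule"))
  values <- rbind(values)
  if (is.null(roi_ids)) roi_ids <- as.character(seq_len(nrow(values)))
  if (ncol(values) != length(schedule) ||
      length(reference) != length(schedule)) {
    stop("frame count mismatch between curves and schedule")
  }
  if (length(roi_ids) != nrow(values)) stop("one roi_id per row required")
  if (as.character(reference_id) %in% as.character(roi_ids)) {
    stop("reference region id must not be among target ids")
  }
  if (any(weights < 0) || !any(weights > 0)) {
    stop("weights must be nonnegative with at least one positive")
  }
  rownames(values) <- roi_ids
  structure(list(values = values, reference = as.numeric(reference),
                 schedule = schedule, roi_ids = roi_ids,
                 reference_id = reference_id, weights = as.numeric(weights)),
            class = "tac_set")
}

#' @export
print.tac_set <- function(x, ...) {
  cat(sprintf("<tac_set> %d target ROIs + reference '%s', %d frames\n",
              nrow(x$values), x$reference_id, length(x$schedule)))
  invisible(x)
}

#' Restrict a TAC set to a subset of target regions
#' @param x a [tac_set()].
#' @param roi_ids target ids to keep.
#' @return a `tac_set` with only the requested rows.
#' @export
subset_tac_set <- function(x, roi_ids) {
  stopifnot(inherits(x, "tac_set"))
  keep <- as.character(x$roi_ids) %in% as.character(roi_ids)
  if (!any(keep)) stop("no requested ROI present in the TAC set")
  tac_set(x$values[keep, , drop = FALSE], x$reference, x$schedule,
          roi_ids = x$roi_ids[keep], reference_id = x$reference_id,
          weights = x$weights)
}

#' Extract regional TACs from a dynamic image
#'
#' The TAC value of a region at frame f is the unweighted mean over the
#' region's voxels of the frame-f volume; the reference region is extracted
#' identically from its own label.
#'
#' @param dynamic 4D numeric array (x, y, z, frame).
#' @param labels 3D integer label array matching the first three dimensions
#'   of `dynamic`; 0 is background.
#' @param schedule [frame_schedule()] whose length matches the 4th dimension.
#' @param reference_id integer label of the reference region.
#' @param roi_ids integer labels of the target regions; default all nonzero
#'   labels except `reference_id`.
#' @param weights per-frame weights passed to [tac_set()].
#' @return a [tac_set()].
#' @export
extract_roi_tacs <- function(dynamic, labels, schedule, reference_id,
                             roi_ids = NULL,
                             weights = default_weights(schedule)) {
  stopifnot(inherits(schedule, "frame_schedule"))
  d <- dim(dynamic)
  if (length(d) != 4L) stop("dynamic image must be 4D")
  if (!identical(d[1:3], dim(labels))) {
    stop("geometry mismatch between dynamic and label image")
  }
  if (d[4] != length(schedule)) {
    stop(sprintf("dynamic image has %d volumes but schedule has %d frames",
                 d[4], length(schedule)))
  }
  lab <- as.integer(labels)
  present <- sort(unique(lab[lab > 0L]))
  if (is.null(roi_ids)) roi_ids <- setdiff(present, reference_id)
  wanted <- c(as.integer(roi_ids), as.integer(reference_id))
  missing_ids <- setdiff(wanted, present)
  if (length(missing_ids)) {
    stop("labels absent from label image: ",
         paste(missing_ids, collapse = ", "))
  }
  nvox <- prod(d[1:3])
  mat <- matrix(dynamic, nrow = nvox, ncol = d[4])
  sel <- lab %in% wanted
  sums <- rowsum(mat[sel, , drop = FALSE], group = lab[sel])
  counts <- as.vector(table(lab[sel]))
  means <- sums / counts
  ids <- as.integer(rownames(sums))
  ref <- means[match(as.integer(reference_id), ids), ]
  tgt <- means[match(as.integer(roi_ids), ids), , drop = FALSE]
  tac_set(tgt, ref, schedule, roi_ids = as.character(roi_ids),
          reference_id = as.character(reference_id), weights = weights)
}
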