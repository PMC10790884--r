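#' Read a dynamic (4D) NIfTI image
#'
#' @param path file path to a NIfTI-1 image.
#' @param schedule optional [frame_schedule()]; if given, the 4th dimension
#'   must equal its frame count.
#' @return list with `data` (4D array) and `affine` (4x4 voxel-to-world).
#' @export
read_dynamic_image <- function(path, schedule = NULL) {
  img <- RNifti::readNifti(path)
  arr <- array(as.vector(img), dim = dim(img))
  if (length(dim(arr)) != 4L) stop("expected a 4D dynamic image: ", path)
  if (!is.null(schedule) && dim(arr)[4] != length(schedule)) {
    stop(sprintf("dynamic image has %d volumes but schedule has %d frames",
                 dim(arr)[4], length(schedule)))
  }
  list(data = arr, affine = unclass(RNifti::xform(img)))
}

#' Read a 3D integer label image
#'
#' Labels must be nonnegative integers; 0 is background.
#'
#' @param path file path to a NIfTI-1 image.
#' @return list with `data` (3D integer array), `affine`, and `labels`
#'   (sorted nonzero label set).
#' @export
read_label_image <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.vector(img), dim = dim(img))
  if (length(dim(arr)) != 3L) stop("expected a 3D label image: ", path)
  if (max(abs(arr - round(arr))) > 1e-6 || min(arr) < 0) {
    stop("label image must contain nonnegative integers")
  }
  arr <- array(as.integer(round(arr)), dim = dim(arr))
  list(data = arr, affine = unclass(RNifti::xform(img)),
       labels = sort(unique(arr[arr > 0L])))
}

#' Write an array as NIfTI
#' @param data 3D or 4D numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_image <- function(data, path) {
  RNifti::writeNifti(RNifti::asNifti(data), path)
  invisible(path)
}

#' Write / read a TAC set as TSV
#'
#' One row per region (reference last), columns = frames; frame start and
#' duration are carried in the header rows so the file round-trips without a
#' side channel.
#'
#' @param x a [tac_set()].
#' @param path output TSV path.
#' @export
write_tacs <- function(x, path) {
  stopifnot(inherits(x, "tac_set"))
  m <- rbind(x$values, reference = x$reference)
  rownames(m)[nrow(m)] <- as.character(x$reference_id)
  df <- data.frame(roi = rownames(m), m, check.names = FALSE)
  colnames(df) <- c("roi", sprintf("f%02d", seq_len(ncol(m))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# start\t", paste(x$schedule$start, collapse = "\t")),
               paste0("# duration\t",
                      paste(x$schedule$duration, collapse = "\t")),
               paste0("# reference\t", x$reference_id)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tacs
#' @param weights per-frame weights for the reconstructed set.
#' @return `read_tacs` returns a [tac_set()].
#' @export
read_tacs <- function(path, weights = NULL) {
  hdr <- readLines(path, n = 3L)
  parse_num <- function(line) as.numeric(strsplit(line, "\t")[[1]][-1])
  sched <- frame_schedule(parse_num(hdr[1]), parse_num(hdr[2]))
  ref_id <- strsplit(hdr[3], "\t")[[1]][2]
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 3L,
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(df$roi, NULL)
  iref <- match(ref_id, df$roi)
  if (is.na(iref)) stop("reference row '", ref_id, "' missing from ", path)
  if (is.null(weights)) weights <- default_weights(sched)
  tac_set(m[-iref, , drop = FALSE], m[iref, ], sched,
          roi_ids = df$roi[-iref], reference_id = ref_id, weights = weights)
}

#' Load the packaged per-subject baseline binding-potential and occupancy
#' table
#'
#' The packaged fixture is a 137-region table of baseline binding potential
#' (BP_ND) and percent occupancy for four subjects plus the across-subject
#' mean, transcribed from the published study table. At load time every row
#' is checked for mean consistency: the printed mean column must equal the
#' arithmetic mean of the four subject cells to within 0.01 after 2-decimal
#' rounding; offending rows are reported by name with a warning.
#'
#' @return a data.frame with columns `roi`, `bp_s1..bp_s4`, `bp_mean`,
#'   `occ_s1..occ_s4`, `occ_mean` (137 rows).
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_baseline_occupancy.tsv",
                      package = "petoccupancy", mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, quote = "")
  stopifnot(nrow(df) == 137L)
  bp_cols <- paste0("bp_s", 1:4)
  occ_cols <- paste0("occ_s", 1:4)
  bad <- abs(round(rowMeans(df[bp_cols]), 2) - df$bp_mean) > 0.01 + 1e-9 |
    abs(round(rowMeans(df[occ_cols]), 2) - df$occ_mean) > 0.01 + 1e-9
  if (any(bad)) {
    warning("mean-consistency failure in fixture rows: ",
            paste(df$roi[bad], collapse = ", "))
  }
  df
}
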