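#' 26-connected neighbor pairs of a voxel mask
#'
#' The parcellation graph is spatially constrained: candidate edges join
#' only voxels that touch (face, edge or corner) inside the analysis mask.
#' Voxels are numbered 1..n in array order over `which(mask)`.
#'
#' @param mask 3D logical array.
#' @return integer matrix with two columns, one row per unordered in-mask
#'   neighbor pair (first index < second); no self pairs.
#' @export
build_adjacency <- function(mask) {
  stopifnot(length(dim(mask)) == 3L)
  if (!any(mask)) stop("empty mask")
  d <- dim(mask)
  vox <- array(0L, d)
  vox[mask] <- seq_len(sum(mask))
  offsets <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offsets <- offsets[offsets$dz > 0 |
                       (offsets$dz == 0 & offsets$dy > 0) |
                       (offsets$dz == 0 & offsets$dy == 0 & offsets$dx > 0), ]
  pairs <- vector("list", nrow(offsets))
  for (i in seq_len(nrow(offsets))) {
    dx <- offsets$dx[i]; dy <- offsets$dy[i]; dz <- offsets$dz[i]
    lo <- pmax(1, 1 - c(dx, dy, dz))
    hi <- pmin(d, d - c(dx, dy, dz))
    if (any(lo > hi)) next
    xr <- lo[1]:hi[1]; yr <- lo[2]:hi[2]; zr <- lo[3]:hi[3]
    a <- vox[xr, yr, zr, drop = FALSE]
    b <- vox[xr + dx, yr + dy, zr + dz, drop = FALSE]
    keep <- a > 0L & b > 0L
    pairs[[i]] <- cbind(a[keep], b[keep])
  }
  out <- do.call(rbind, pairs)
  flip <- out[, 1] > out[, 2]
  out[flip, ] <- out[flip, 2:1]
  colnames(out) <- c("i", "j")
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' Thresholded Pearson correlation weights on a neighbor graph
#'
#' For each listed voxel pair the edge weight is the Pearson correlation of
#' the two voxel time series; correlations below `threshold` are set to 0
#' (edge dropped). Zero-variance voxels get weight 0 on all their edges and
#' a warning.
#'
#' @param ts numeric matrix, voxels x timepoints (already preprocessed).
#' @param pairs pair matrix from [build_adjacency()].
#' @param threshold minimum retained correlation (default 0.5).
#' @return numeric edge weight vector aligned with the rows of `pairs`.
#' @export
correlation_graph <- function(ts, pairs, threshold = 0.5) {
  stopifnot(is.matrix(ts), ncol(ts) >= 2L)
  if (max(pairs) > nrow(ts)) stop("pair index exceeds voxel count")
  sds <- apply(ts, 1, stats::sd)
  flat <- sds == 0 | !is.finite(sds)
  if (any(flat)) {
    warning(sum(flat), " zero-variance voxel series; their edges get weight 0")
    sds[flat] <- 1
  }
  z <- (ts - rowMeans(ts)) / sds
  r <- unname(rowSums(z[pairs[, 1], , drop = FALSE] *
                        z[pairs[, 2], , drop = FALSE]) / (ncol(ts) - 1))
  r[flat[pairs[, 1]] | flat[pairs[, 2]]] <- 0
  r[r < threshold] <- 0
  r
}

#' Fisher-z average of per-subject edge weights
#'
#' Correlations are clipped to +/- (1 - 1e-7), transformed with atanh,
#' averaged across subjects, and mapped back with tanh.
#'
#' @param graphs list of per-subject edge weight vectors over one shared
#'   pair list.
#' @return group-level edge weight vector.
#' @export
fisher_average <- function(graphs) {
  if (length(graphs) == 0L) stop("no subjects")
  len <- unique(vapply(graphs, length, integer(1)))
  if (length(len) != 1L) stop("all graphs must share the same pair list")
  clip <- 1 - 1e-7
  zs <- vapply(graphs, function(g) atanh(pmin(pmax(g, -clip), clip)),
               numeric(len))
  if (is.null(dim(zs))) zs <- matrix(zs, nrow = 1L)
  unname(tanh(rowMeans(zs)))
}

# Exactly k nonempty labels: while clusters are missing, split the largest
# cluster in half (by member order) into a missing label.
ensure_k_labels <- function(labels, k) {
  repeat {
    sizes <- tabulate(labels, nbins = k)
    missing <- which(sizes == 0L)
    if (!length(missing)) return(labels)
    big <- which.max(sizes)
    members <- which(labels == big)
    labels[members[seq_len(floor(length(members) / 2))]] <- missing[1]
  }
}

# Apportion k clusters over graph components proportionally to size
# (largest remainder, at least 1 and at most size_c per component).
apportion_k <- function(sizes, k) {
  n_comp <- length(sizes)
  if (n_comp > k) {
    stop(sprintf("graph has %d components but only %d clusters requested",
                 n_comp, k))
  }
  ideal <- k * sizes / sum(sizes)
  alloc <- pmin(sizes, pmax(1L, floor(ideal)))
  while (sum(alloc) < k) {
    room <- alloc < sizes
    if (!any(room)) stop("requested more clusters than voxels")
    cand <- which(room)
    alloc[cand[which.max((ideal - alloc)[cand])]] <-
      alloc[cand[which.max((ideal - alloc)[cand])]] + 1L
  }
  while (sum(alloc) > k) {
    cand <- which(alloc > 1L)
    alloc[cand[which.min((ideal - alloc)[cand])]] <-
      alloc[cand[which.min((ideal - alloc)[cand])]] - 1L
  }
  alloc
}

# Normalized-cut spectral clustering of one connected component.
cluster_component <- function(w_mat, k, seed) {
  n <- nrow(w_mat)
  if (k == 1L || n == 1L) return(rep(1L, n))
  deg <- Matrix::rowSums(w_mat)
  deg[deg <= 0] <- 1e-12
  dis <- 1 / sqrt(deg)
  m <- as.matrix(w_mat * tcrossprod(dis))
  ev <- eigen(m, symmetric = TRUE)
  x <- ev$vectors[, seq_len(k), drop = FALSE]
  nrm <- sqrt(rowSums(x^2))
  nrm[nrm == 0] <- 1
  x <- x / nrm
  cl <- with_seed(seed, {
    n_uniq <- nrow(unique(round(x, 12)))
    if (n_uniq < k) {
      km <- stats::kmeans(x, centers = n_uniq, nstart = 10, iter.max = 100)
      km$cluster
    } else {
      stats::kmeans(x, centers = k, nstart = 10, iter.max = 100)$cluster
    }
  })
  ensure_k_labels(cl, k)
}

#' Normalized-cut spectral parcellation of a weighted voxel graph
#'
#' Clusters the group-level correlation graph into exactly `k` nonempty
#' parcels: negative weights are clipped to 0, the graph is split into
#' connected components (with `k` apportioned across components by size when
#' the thresholded graph is disconnected), and each component is clustered
#' by the symmetric-normalized Laplacian embedding (leading eigenvectors,
#' row-normalized) followed by seeded k-means with 10 restarts.
#'
#' @param weights group edge weights (e.g. from [fisher_average()]).
#' @param pairs pair matrix from [build_adjacency()].
#' @param n_voxels number of voxels in the mask.
#' @param k requested parcel count.
#' @param seed integer seed making the clustering deterministic.
#' @param mask optional 3D logical array; if given, a label volume is built.
#' @param threshold recorded in provenance only.
#' @return object of class `parcellation`: `labels` (integer 1..k per
#'   voxel), `k`, optional `volume`, and `provenance`.
#' @export
spectral_ncut <- function(weights, pairs, n_voxels, k, seed = 1L,
                          mask = NULL, threshold = NA_real_) {
  if (k < 1L) stop("k must be >= 1")
  if (k > n_voxels) stop("k exceeds the number of mask voxels")
  w <- pmax(weights, 0)
  keep <- w > 0
  g <- igraph::graph_from_edgelist(cbind(pairs[keep, 1], pairs[keep, 2]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n_voxels - igraph::vcount(g)))
  comp <- igraph::components(g)
  if (comp$no > 1L && k > 1L) {
    warning(sprintf("thresholded graph has %d components; apportioning %d clusters by size",
                    comp$no, k))
  }
  alloc <- apportion_k(as.integer(comp$csize), k)
  labels <- integer(n_voxels)
  offset <- 0L
  wm <- Matrix::sparseMatrix(i = pmin(pairs[keep, 1], pairs[keep, 2]),
                             j = pmax(pairs[keep, 1], pairs[keep, 2]),
                             x = w[keep], dims = c(n_voxels, n_voxels),
                             symmetric = TRUE)
  for (c_id in seq_len(comp$no)) {
    members <- which(comp$membership == c_id)
    sub <- wm[members, members, drop = FALSE]
    cl <- cluster_component(sub, alloc[c_id], seed + c_id)
    labels[members] <- cl + offset
    offset <- offset + alloc[c_id]
  }
  volume <- NULL
  if (!is.null(mask)) {
    volume <- array(0L, dim(mask))
    volume[mask] <- labels
  }
  structure(list(labels = labels, k = as.integer(k), volume = volume,
                 provenance = list(threshold = threshold, seed = seed,
                                   eigen_dim = max(alloc))),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> %d voxels in %d parcels (seed %s)\n",
              length(x$labels), x$k, x$provenance$seed))
  invisible(x)
}

#' Full parcellation pipeline from preprocessed voxel time series
#'
#' Convenience wrapper: spatial adjacency, per-subject thresholded
#' correlation graphs, Fisher-z group averaging, then [spectral_ncut()].
#'
#' @param subjects list of voxels x timepoints matrices (one per subject),
#'   all over the same mask in `which(mask)` voxel order.
#' @param mask shared 3D logical analysis mask.
#' @param k parcel count (the study used 200).
#' @param threshold correlation threshold (default 0.5).
#' @param seed integer seed.
#' @return a `parcellation` with label volume.
#' @export
build_parcellation <- function(subjects, mask, k, threshold = 0.5,
                               seed = 1L) {
  pairs <- build_adjacency(mask)
  graphs <- lapply(subjects, correlation_graph, pairs = pairs,
                   threshold = threshold)
  w <- fisher_average(graphs)
  spectral_ncut(w, pairs, n_voxels = sum(mask), k = k, seed = seed,
                mask = mask, threshold = threshold)
}
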