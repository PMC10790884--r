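# Shared test fixtures, all built in code.

# small contiguous schedule for cheap tests: 2x10s + 1x20s
toy_schedule <- function() load_frame_schedule(list(c(2, 10), c(1, 20)))

# adjusted Rand index between two labelings
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# a small noiseless study reused by several SRTM tests
noiseless_study <- function(n_rois = 8L, seed = 11L) {
  simulate_study(n_rois = n_rois, noise_cv = 0, seed = seed)
}

# brute-force 26-connectivity pair count over a mask (independent oracle)
brute_adjacency_count <- function(mask) {
  coords <- which(mask, arr.ind = TRUE)
  n <- nrow(coords)
  cnt <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (max(abs(coords[i, ] - coords[j, ])) == 1L) cnt <- cnt + 1L
    }
  }
  cnt
}
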