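# Fixtures built in code: sinusoid epoch sets, toy recordings, canonical
# trees, and the Pruefer-sequence spanning-tree enumerator used as the MST
# brute-force oracle.

# epochs holding two cosines with a constant phase lag
lagged_epochs <- function(lag, n_ep = 40, rate = 250, dur = 2, f = 10) {
  tt <- seq(0, dur - 1 / rate, by = 1 / rate)
  ep <- array(0, c(n_ep, 2, length(tt)))
  for (e in seq_len(n_ep)) {
    ep[e, 1, ] <- cos(2 * pi * f * tt)
    ep[e, 2, ] <- cos(2 * pi * f * tt - lag)
  }
  eeg_epochs(ep, rate, dur, c("A", "B"))
}

# a hand-built eeg_phases object with a prescribed phase-difference stream
phases_from_diff <- function(dphi, n_ep = 1) {
  n_t <- length(dphi)
  ph <- array(0, c(n_ep, 2, n_t))
  for (e in seq_len(n_ep)) ph[e, 2, ] <- -dphi   # phi1 - phi2 = dphi
  structure(list(phases = ph, retain = rep(TRUE, n_t),
                 degenerate = matrix(FALSE, n_ep, 2),
                 channel_labels = c("A", "B"), subject_id = "fixture"),
            class = "eeg_phases")
}

# multichannel white-noise recording
noise_recording <- function(n_ch = 4, rate = 200, dur = 5, seed = 1,
                            kinds = rep("EEG", n_ch),
                            labels = paste0("C", seq_len(n_ch))) {
  set.seed(seed)
  eeg_recording(matrix(rnorm(n_ch * rate * dur, 0, 20), n_ch),
                rate = rate, channel_labels = labels, channel_kinds = kinds)
}

# dissimilarity matrices whose MST is a chain / star on n nodes
chain_weights <- function(n) {
  w <- matrix(1, n, n)
  for (i in seq_len(n - 1)) w[i, i + 1] <- w[i + 1, i] <- 0.1
  diag(w) <- 0
  w
}
star_weights <- function(n, centre = 1) {
  w <- matrix(1, n, n)
  w[centre, ] <- w[, centre] <- 0.1
  diag(w) <- 0
  w
}

# decode a Pruefer sequence into the tree's edge list (n-1 x 2)
prufer_decode <- function(seq, n) {
  degree <- rep(1L, n)
  for (s in seq) degree[s] <- degree[s] + 1L
  edges <- matrix(0L, n - 1L, 2L)
  ptr <- 0L
  for (k in seq_along(seq)) {
    leaf <- which(degree == 1L)[1L]
    edges[k, ] <- c(leaf, seq[k])
    degree[leaf] <- 0L
    degree[seq[k]] <- degree[seq[k]] - 1L
  }
  last <- which(degree == 1L)
  edges[n - 1L, ] <- last
  edges
}

# all labelled spanning trees on n nodes as a (n-1) x n^(n-2) matrix of
# linear indices into an n x n weight matrix (upper-triangle edges)
all_trees_edge_index <- function(n) {
  n_seq <- n^(n - 2L)
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  idx <- matrix(0L, n - 1L, n_seq)
  for (k in seq_len(n_seq)) {
    e <- prufer_decode(grid[k, ], n)
    lo <- pmin(e[, 1], e[, 2]); hi <- pmax(e[, 1], e[, 2])
    idx[, k] <- (hi - 1L) * n + lo
  }
  idx
}

# minimum spanning-tree weight by exhaustive enumeration
enumerate_mst_weight <- function(w, tree_index = all_trees_edge_index(nrow(w))) {
  totals <- colSums(matrix(w[tree_index], nrow(tree_index)))
  min(totals)
}

# tiny cohort spec for I/O round-trips and schema tests
tiny_spec <- function(...) {
  cohort_spec(group_sizes = c(HC = 2, `MCI-AD` = 2, AD = 2),
              n_channels = 4, n_eog = 2, rate = 500, duration = 10, ...)
}
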