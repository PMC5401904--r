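# Shared fixtures built in code.

# Raster with onsets at given (neuron, frame) positions.
make_raster <- function(n_neurons, n_frames, onsets = NULL, dt_s = 0.1) {
  m <- matrix(0L, n_neurons, n_frames)
  if (!is.null(onsets)) m[onsets] <- 1L
  event_raster(m, dt_s = dt_s)
}

# Independent oracle for synchronous_groups: connected components of the
# onset co-occurrence graph (onsets are vertices, edges join onsets whose
# frames differ by at most the window), by breadth-first search.
brute_force_groups <- function(m, window_frames = 1L) {
  on <- which(m == 1L, arr.ind = TRUE)
  k <- nrow(on)
  if (k == 0L) return(integer(0))
  unvisited <- rep(TRUE, k)
  sizes <- integer(0)
  while (any(unvisited)) {
    queue <- which(unvisited)[1]
    unvisited[queue] <- FALSE
    members <- queue
    while (length(queue) > 0L) {
      cur <- queue[1]
      queue <- queue[-1]
      nb <- which(unvisited &
                    abs(on[, 2] - on[cur, 2]) <= window_frames)
      unvisited[nb] <- FALSE
      queue <- c(queue, nb)
      members <- c(members, nb)
    }
    sizes <- c(sizes, length(unique(on[members, 1])))
  }
  sort(sizes)
}

# Rayleigh critical resultant length at level alpha (large-sample form).
rayleigh_r_crit <- function(n, alpha = 0.05) sqrt(-log(alpha) / n)

# Compare a detected raster against ground truth with +/- 1 frame slack:
# TRUE iff counts match per neuron and each true onset has a detected onset
# within one frame (and vice versa).
rasters_agree <- function(truth, detected, slack = 1L) {
  tm <- truth$onsets
  dm <- detected$onsets
  if (!identical(dim(tm), dim(dm))) return(FALSE)
  if (!identical(rowSums(tm), rowSums(dm))) return(FALSE)
  for (i in seq_len(nrow(tm))) {
    tf <- which(tm[i, ] == 1L)
    df <- which(dm[i, ] == 1L)
    if (length(tf) != length(df)) return(FALSE)
    if (length(tf) > 0 && any(abs(tf - df) > slack)) return(FALSE)
  }
  TRUE
}
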