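#' Parameters for the discrete-time cascade simulator
#'
#' The activity model is a branching cascade on the cluster graph: each neuron
#' initiates an event spontaneously and every event recruits graph neighbours
#' on the next frame with a fixed per-edge probability, subject to a
#' refractory period. This minimal model produces both solo events and
#' whole-cluster synchronisation as wiring density and transmission increase.
#'
#' @param spontaneous_rate Spontaneous initiation rate, events / s / neuron.
#' @param transmission_prob Per-edge, per-event recruitment probability.
#' @param refractory_frames Frames after an event during which a neuron
#'   cannot fire again (>= 1).
#' @param duration_s Recording duration in seconds (default 120 s: the
#'   standard 2-min session).
#' @param dt_s Frame interval in seconds (default 0.1 s: 100 ms imaging
#'   interval). `duration_s / dt_s` must be a whole number of frames.
#'
#' @return A `cascade_params` list.
#' @export
cascade_params <- function(spontaneous_rate = 0.01,
                           transmission_prob = 0.2,
                           refractory_frames = 10L,
                           duration_s = 120,
                           dt_s = 0.1) {
  assert_scalar_number(spontaneous_rate, "spontaneous_rate", lower = 0)
  assert_probability(transmission_prob, "transmission_prob")
  assert_scalar_number(refractory_frames, "refractory_frames", lower = 1,
                       integer = TRUE)
  assert_scalar_number(duration_s, "duration_s", lower = 1e-12)
  assert_scalar_number(dt_s, "dt_s", lower = 1e-12)
  n_frames <- duration_s / dt_s
  if (abs(n_frames - round(n_frames)) > 1e-8) {
    abort("`duration_s / dt_s` must be an integer frame count.")
  }
  structure(
    list(spontaneous_rate = spontaneous_rate,
         transmission_prob = transmission_prob,
         refractory_frames = as.integer(refractory_frames),
         duration_s = duration_s, dt_s = dt_s,
         n_frames = as.integer(round(n_frames))),
    class = "cascade_params"
  )
}

#' Simulate branching cascades of activity on a cluster graph
#'
#' Per frame, every non-refractory neuron initiates spontaneously with
#' probability `1 - exp(-spontaneous_rate * dt_s)`; every event at frame
#' `t - 1` recruits each graph neighbour at frame `t` independently with
#' `transmission_prob`. A neuron within `refractory_frames` of its last event
#' cannot fire. Every event is therefore attributable to spontaneous
#' initiation or to a neighbour's event one frame earlier.
#'
#' @param adjacency Symmetric binary adjacency matrix (see
#'   [build_topology()]).
#' @param params A [cascade_params()].
#' @param seed Integer seed; identical inputs give a bit-identical raster.
#' @param init_spikes Optional integer vector of neurons forced to fire at
#'   frame 1 (useful for probing propagation).
#'
#' @return An [event_raster()] holding the simulated ground-truth onsets.
#' @examples
#' adj <- build_topology(topology_spec(10, "complete"))
#' r <- simulate_cascades(adj, cascade_params(transmission_prob = 1),
#'                        seed = 1, init_spikes = 1)
#' sum(r$onsets[, 2])  # every neighbour recruited on the next frame
#' @export
simulate_cascades <- function(adjacency, params = cascade_params(), seed = 1L,
                              init_spikes = NULL) {
  assert_adjacency(adjacency)
  if (!inherits(params, "cascade_params")) {
    abort("`params` must be created by `cascade_params()`.")
  }
  n <- nrow(adjacency)
  n_frames <- params$n_frames
  p_spont <- 1 - exp(-params$spontaneous_rate * params$dt_s)
  q <- 1 - params$transmission_prob
  raster <- matrix(0L, n, n_frames)
  if (!is.null(init_spikes)) {
    init_spikes <- as.integer(init_spikes)
    if (any(init_spikes < 1L | init_spikes > n)) {
      abort("`init_spikes` must index neurons of the cluster.")
    }
  }
  withr::with_seed(seed, {
    last_spike <- rep(-Inf, n)
    for (t in seq_len(n_frames)) {
      eligible <- (t - last_spike) > params$refractory_frames
      if (t > 1L) {
        k <- as.vector(adjacency %*% raster[, t - 1L])
        p_fire <- 1 - (1 - p_spont) * q^k
      } else {
        p_fire <- rep(p_spont, n)
      }
      fire <- eligible & (runif(n) < p_fire)
      if (t == 1L && !is.null(init_spikes)) fire[init_spikes] <- TRUE
      if (any(fire)) {
        raster[fire, t] <- 1L
        last_spike[fire] <- t
      }
    }
  })
  event_raster(raster, dt_s = params$dt_s)
}
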