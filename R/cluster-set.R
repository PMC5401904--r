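#' Generate a set of simulated cluster recordings with ground truth
#'
#' Produces `n_clusters` complete synthetic recordings, each with its wiring,
#' ground-truth event raster and fluorescence traces. Two presets encode the
#' contrast under study: `control_like` clusters use sparse selective wiring
#' (small-world ring, degree 4, rewiring 0.1) with weak transmission (0.2), so
#' activity stays mostly confined to solo events and small groups;
#' `mutant_like` clusters use dense unselective wiring (random graph, edge
#' probability 0.8) with strong transmission (0.6), so most initiations
#' recruit the entire cluster. Every preset value can be overridden.
#'
#' @param n_clusters Number of clusters (>= 1). Typical study sizes are 40
#'   control and 35 mutant clusters.
#' @param mode `"control_like"` or `"mutant_like"`.
#' @param size_range Two integers in `[2, 200]`; cluster sizes are drawn
#'   uniformly from this range (default `c(9, 25)`, medium-sized clusters).
#' @param seed Master seed, expanded deterministically into per-cluster child
#'   seeds (see [child_seed rule][generate_cluster_set] details).
#' @param topology_args,cascade_args,indicator_args Named lists overriding
#'   the preset [topology_spec()], [cascade_params()] and
#'   [indicator_params()] arguments.
#'
#' @details The master seed is expanded by the documented rule
#'   `child = (1009 * seed + 7919 * index) mod (2^31 - 1)` so individual
#'   clusters can be regenerated in isolation.
#'
#' @return A tibble with one row per cluster and columns `cluster_id`,
#'   `mode`, `n_neurons`, `seed`, plus list-columns `adjacency`,
#'   `truth_raster` ([event_raster()]) and `recording`
#'   ([fluorescence_recording()]).
#' @examples
#' set <- generate_cluster_set(3, "control_like", seed = 1)
#' set$n_neurons
#' @export
generate_cluster_set <- function(n_clusters,
                                 mode = c("control_like", "mutant_like"),
                                 size_range = c(9L, 25L),
                                 seed = 1L,
                                 topology_args = list(),
                                 cascade_args = list(),
                                 indicator_args = list()) {
  mode <- match.arg(mode)
  assert_scalar_number(n_clusters, "n_clusters", lower = 1, integer = TRUE)
  if (length(size_range) != 2L || size_range[1] > size_range[2] ||
      size_range[1] < 2 || size_range[2] > 200) {
    abort("`size_range` must be two increasing integers within [2, 200].")
  }
  preset_topo <- if (mode == "control_like") {
    list(kind = "small_world", ring_degree = 4L, rewire_beta = 0.1)
  } else {
    list(kind = "random", edge_prob = 0.8)
  }
  preset_casc <- list(
    transmission_prob = if (mode == "control_like") 0.2 else 0.6
  )
  rows <- purrr::map(seq_len(n_clusters), function(i) {
    cs <- child_seed(seed, i)
    n <- withr::with_seed(cs, sample(size_range[1]:size_range[2], 1L))
    topo_args <- utils::modifyList(
      c(list(n_neurons = n, seed = child_seed(cs, 1L)), preset_topo),
      topology_args)
    adjacency <- build_topology(do.call(topology_spec, topo_args))
    casc <- do.call(cascade_params,
                    utils::modifyList(preset_casc, cascade_args))
    raster <- simulate_cascades(adjacency, casc, seed = child_seed(cs, 2L))
    raster$cluster_id <- i
    ind <- do.call(indicator_params, indicator_args)
    rec <- spikes_to_fluorescence(raster, ind, seed = child_seed(cs, 3L))
    tibble(cluster_id = i, mode = mode, n_neurons = n, seed = cs,
           adjacency = list(adjacency), truth_raster = list(raster),
           recording = list(rec))
  })
  dplyr::bind_rows(rows)
}

#' Construct a benchmark cluster set with known full-synchronisation truth
#'
#' Builds `n_clusters` clusters of which exactly `n_full_sync` contain at
#' least one frame where every neuron emits an onset (complete
#' synchronisation), while the remainder keep one permanently silent neuron
#' so their largest co-active group is at most `n - 1`. Background events are
#' placed sparsely with a minimum separation so that detection at default
#' parameters recovers the raster exactly on noiseless traces. This is the
#' ground-truth fixture for validating the full-synchronisation classifier
#' end-to-end (fluorescence synthesis, dF/F, onset detection,
#' classification).
#'
#' @param n_clusters Total clusters (default 35).
#' @param n_full_sync Clusters constructed to fully synchronise (default 21,
#'   i.e. 60 percent of 35).
#' @param size_range Uniform range of cluster sizes (default `c(9, 25)`).
#' @param seed Master seed (expanded with the documented child-seed rule).
#' @param events_per_neuron Range of background event counts per neuron.
#' @param n_frames Frames per recording (default 1200 = 2 min at 100 ms).
#' @param indicator An [indicator_params()]; defaults to noiseless traces.
#'
#' @return A tibble like [generate_cluster_set()] with an extra logical
#'   column `full_sync_truth`.
#' @export
generate_sync_benchmark <- function(n_clusters = 35L,
                                    n_full_sync = 21L,
                                    size_range = c(9L, 25L),
                                    seed = 1L,
                                    events_per_neuron = c(2L, 5L),
                                    n_frames = 1200L,
                                    indicator = indicator_params(noise_sd = 0)) {
  assert_scalar_number(n_clusters, "n_clusters", lower = 1, integer = TRUE)
  assert_scalar_number(n_full_sync, "n_full_sync", lower = 0,
                       upper = n_clusters, integer = TRUE)
  gap <- 15L  # > refractory and > default min_separation_frames
  is_full <- rep(c(TRUE, FALSE), c(n_full_sync, n_clusters - n_full_sync))
  is_full <- withr::with_seed(seed, sample(is_full))
  rows <- purrr::map(seq_len(n_clusters), function(i) {
    cs <- child_seed(seed, i)
    withr::with_seed(cs, {
      n <- sample(size_range[1]:size_range[2], 1L)
      m <- matrix(0L, n, n_frames)
      sync_frame <- if (is_full[i]) sample(100:(n_frames - 100), 1L) else NA
      silent <- if (is_full[i]) integer(0) else sample(n, 1L)
      for (j in seq_len(n)) {
        if (j %in% silent) next
        k <- sample(events_per_neuron[1]:events_per_neuron[2], 1L)
        # rejection-sample sparse event times with pairwise gaps > `gap`,
        # keeping clear of the common synchronisation frame
        times <- integer(0)
        tries <- 0L
        while (length(times) < k && tries < 200L) {
          cand <- sample(seq_len(n_frames - 1L), 1L)
          ok <- all(abs(cand - times) > gap) &&
            (is.na(sync_frame) || abs(cand - sync_frame) > gap)
          if (ok) times <- c(times, cand)
          tries <- tries + 1L
        }
        m[j, times] <- 1L
        if (!is.na(sync_frame)) m[j, sync_frame] <- 1L
      }
      raster <- event_raster(m, dt_s = 0.1, cluster_id = i)
      rec <- spikes_to_fluorescence(raster, indicator,
                                    seed = child_seed(cs, 1L))
      tibble(cluster_id = i, n_neurons = n, seed = cs,
             full_sync_truth = is_full[i],
             truth_raster = list(raster), recording = list(rec))
    })
  })
  dplyr::bind_rows(rows)
}
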