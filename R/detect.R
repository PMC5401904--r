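#' Detect transient onsets in a dF/F matrix
#'
#' Per neuron, two robust noise scales are estimated: the median absolute
#' deviation (Gaussian-consistent) of the dF/F trace and of its first
#' difference. An onset is marked at frames where dF/F exceeds the trace
#' median by `z_threshold` level-noise units *and* the single-frame
#' increment exceeds `z_threshold` jump-noise units. Requiring the
#' suprathreshold rise as well as the suprathreshold level keeps the
#' false-positive rate on pure-noise traces well below one onset per
#' recording and recovers events that initiate while a previous transient is
#' still decaying (rise is fast relative to decay). Subsequent candidates
#' within `min_separation_frames` of an accepted onset are suppressed.
#'
#' @param dff dF/F matrix from [compute_dff()] (finite values).
#' @param params A [detection_params()].
#' @param dt_s Frame interval; defaults to the matrix attribute set by
#'   [compute_dff()].
#' @param cluster_id Optional label; defaults to the matrix attribute.
#'
#' @return An [event_raster()] of detected onsets, same shape as `dff`.
#' @export
detect_events <- function(dff, params = detection_params(), dt_s = NULL,
                          cluster_id = NULL) {
  if (!is.matrix(dff) || !all(is.finite(dff))) {
    abort("`dff` must be a finite numeric matrix.")
  }
  dt_s <- dt_s %||% attr(dff, "dt_s") %||% 0.1
  cluster_id <- cluster_id %||% attr(dff, "cluster_id")
  n_frames <- ncol(dff)
  onsets <- matrix(0L, nrow(dff), n_frames)
  for (i in seq_len(nrow(dff))) {
    v <- dff[i, ]
    centre <- median(v)
    sigma <- max(mad(v), 1e-9)         # floors keep noiseless traces usable
    sigma_jump <- max(mad(diff(v)), 1e-9)
    above <- v >= centre + params$z_threshold * sigma
    rise <- c(v[1] - centre, diff(v)) >= params$z_threshold * sigma_jump
    cand <- which(above & rise)
    last <- -Inf
    for (t in cand) {
      if (t - last > params$min_separation_frames) {
        onsets[i, t] <- 1L
        last <- t
      }
    }
  }
  event_raster(onsets, dt_s = dt_s, cluster_id = cluster_id)
}

#' Per-neuron activity mask
#'
#' A neuron counts as active if it has at least one detected onset within the
#' recording.
#'
#' @param raster An [event_raster()] or binary matrix.
#'
#' @return A logical vector, one entry per neuron.
#' @export
active_mask <- function(raster) {
  m <- as_raster_matrix(raster)
  rowSums(m) > 0
}
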