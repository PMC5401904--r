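#' Fluorescence recording of a neuronal cluster
#'
#' Container for a raw multi-neuron fluorescence recording: a neurons x frames
#' matrix sampled at a fixed interval. This is the unit of all calcium
#' analysis; a standard recording is 2 min at a 100 ms imaging interval
#' (1200 frames).
#'
#' @param values Numeric matrix, neurons in rows, frames in columns. At least
#'   2 neurons and 10 frames, no missing values.
#' @param dt_s Sampling interval in seconds (default 0.1).
#' @param cluster_id Optional label for the imaged cluster.
#'
#' @return An object of class `fluorescence_recording` with fields `values`,
#'   `dt_s` and `cluster_id`.
#' @seealso [compute_dff()], [spikes_to_fluorescence()]
#' @export
fluorescence_recording <- function(values, dt_s = 0.1, cluster_id = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (neurons x frames).")
  }
  if (nrow(values) < 2L) abort("A recording needs at least 2 neurons.")
  if (ncol(values) < 10L) abort("A recording needs at least 10 frames.")
  if (anyNA(values)) abort("A recording must not contain missing values.")
  assert_scalar_number(dt_s, "dt_s", lower = 1e-12)
  structure(
    list(values = values, dt_s = dt_s, cluster_id = cluster_id),
    class = "fluorescence_recording"
  )
}

#' @export
print.fluorescence_recording <- function(x, ...) {
  cat(sprintf(
    "<fluorescence_recording> %d neurons x %d frames, dt = %g s%s\n",
    nrow(x$values), ncol(x$values), x$dt_s,
    if (is.null(x$cluster_id)) "" else paste0(", cluster ", x$cluster_id)
  ))
  invisible(x)
}

#' @export
dim.fluorescence_recording <- function(x) dim(x$values)

#' Binary event raster of detected transient onsets
#'
#' The bridge from fluorescence traces to synchrony statistics: a binary
#' neurons x frames matrix with a 1 at every detected (or simulated)
#' calcium-transient onset.
#'
#' @param onsets Binary (0/1) matrix, same shape as the source recording.
#' @param dt_s Sampling interval in seconds.
#' @param cluster_id Optional cluster label.
#'
#' @return An object of class `event_raster` with fields `onsets`, `dt_s` and
#'   `cluster_id`.
#' @seealso [detect_events()], [synchronous_groups()]
#' @export
event_raster <- function(onsets, dt_s = 0.1, cluster_id = NULL) {
  if (!is.matrix(onsets)) abort("`onsets` must be a matrix.")
  if (!all(onsets %in% c(0, 1))) abort("`onsets` entries must be 0 or 1.")
  assert_scalar_number(dt_s, "dt_s", lower = 1e-12)
  storage.mode(onsets) <- "integer"
  structure(
    list(onsets = onsets, dt_s = dt_s, cluster_id = cluster_id),
    class = "event_raster"
  )
}

#' @export
print.event_raster <- function(x, ...) {
  cat(sprintf(
    "<event_raster> %d neurons x %d frames, %d onsets, dt = %g s%s\n",
    nrow(x$onsets), ncol(x$onsets), sum(x$onsets), x$dt_s,
    if (is.null(x$cluster_id)) "" else paste0(", cluster ", x$cluster_id)
  ))
  invisible(x)
}

#' @export
dim.event_raster <- function(x) dim(x$onsets)

#' @describeIn event_raster Long-format view: one row per onset with columns
#'   `neuron`, `frame`, `time_s`.
#' @param x An `event_raster`.
#' @param ... Unused.
#' @export
as_tibble.event_raster <- function(x, ...) {
  idx <- which(x$onsets == 1L, arr.ind = TRUE)
  tibble(
    neuron = as.integer(idx[, 1]),
    frame = as.integer(idx[, 2]),
    time_s = (as.integer(idx[, 2]) - 1L) * x$dt_s
  )
}

as_raster_matrix <- function(x) {
  if (inherits(x, "event_raster")) x$onsets else x
}
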