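#' Decompose an event raster into synchronous groups
#'
#' Onsets are merged into one synchronous group whenever each onset lies
#' within `window_frames` of another onset in the group (transitive closure
#' over frames), i.e. connected components of the temporal co-occurrence
#' graph. Chain merging is used instead of a fixed frame lattice so that
#' events straddling a bin edge are not split. A group's size is the number
#' of distinct neurons contributing at least one onset to it; every onset
#' belongs to exactly one group.
#'
#' @param raster An [event_raster()] or binary matrix.
#' @param window_frames Synchrony window in frames (default 1 = one 100 ms
#'   imaging interval).
#'
#' @return Integer vector of group sizes in temporal order, with attribute
#'   `"window_frames"`.
#' @examples
#' m <- matrix(0L, 3, 20); m[1, 5] <- m[2, 5] <- m[3, 6] <- 1L; m[1, 15] <- 1L
#' synchronous_groups(m)  # one group of 3, one of 1
#' @export
synchronous_groups <- function(raster, window_frames = 1L) {
  assert_scalar_number(window_frames, "window_frames", lower = 1,
                       integer = TRUE)
  m <- as_raster_matrix(raster)
  frames <- sort(unique(which(m == 1L, arr.ind = TRUE)[, 2]))
  if (length(frames) == 0L) {
    return(structure(integer(0), window_frames = as.integer(window_frames)))
  }
  new_group <- c(TRUE, diff(frames) > window_frames)
  group_of_frame <- cumsum(new_group)
  sizes <- vapply(seq_len(max(group_of_frame)), function(g) {
    f <- frames[group_of_frame == g]
    sum(rowSums(m[, f, drop = FALSE]) > 0)
  }, integer(1))
  structure(sizes, window_frames = as.integer(window_frames))
}

#' Synchrony-size histogram with a distinguished "all" bin
#'
#' Counts synchronous groups by size, routing groups that contain every
#' neuron of the cluster (complete synchronisation) to a separate `"all"`
#' bin, as in the classic presentation of cluster synchrony histograms.
#'
#' @param group_sizes Integer group sizes (from [synchronous_groups()]).
#' @param cluster_size Number of neurons `n` in the cluster.
#'
#' @return A tibble of class `synchrony_histogram` with columns `bin`
#'   (`"1" ... "n-1"`, `"all"`), `size` and `count`, plus attribute
#'   `cluster_size`.
#' @export
synchrony_histogram <- function(group_sizes, cluster_size) {
  assert_scalar_number(cluster_size, "cluster_size", lower = 2,
                       integer = TRUE)
  group_sizes <- as.integer(group_sizes)
  if (any(group_sizes < 1L | group_sizes > cluster_size)) {
    abort("Group sizes must lie in [1, cluster_size].")
  }
  sizes <- seq_len(cluster_size)
  counts <- vapply(sizes, function(s) sum(group_sizes == s), integer(1))
  out <- tibble(
    bin = c(as.character(seq_len(cluster_size - 1L)), "all"),
    size = sizes,
    count = counts
  )
  class(out) <- c("synchrony_histogram", class(out))
  attr(out, "cluster_size") <- as.integer(cluster_size)
  attr(out, "window_frames") <- attr(group_sizes, "window_frames")
  out
}

#' Percentage of active neurons in a cluster
#'
#' @param raster An [event_raster()] or binary matrix.
#'
#' @return `100 * (neurons with >= 1 onset) / n`, a percentage in `[0, 100]`.
#' @export
active_fraction <- function(raster) {
  m <- as_raster_matrix(raster)
  100 * sum(rowSums(m) > 0) / nrow(m)
}

#' Bin per-cluster active-neuron percentages
#'
#' Exactly-0 and exactly-100 percent clusters get their own bins; the
#' interior is divided into ten equal half-open bins `[0,10), [10,20), ...,
#' [90,100)` applied to values strictly between 0 and 100.
#'
#' @param values Percentages in `[0, 100]`, one per cluster.
#'
#' @return A tibble of class `active_fraction_histogram` with 12 rows and
#'   columns `bin`, `lower`, `upper`, `count`.
#' @export
bin_active_fractions <- function(values) {
  if (any(!is.finite(values)) || any(values < 0 | values > 100)) {
    abort("`values` must be percentages in [0, 100].")
  }
  interior <- values[values > 0 & values < 100]
  idx <- pmin(floor(interior / 10), 9) + 1L
  out <- tibble(
    bin = c("0", sprintf("[%d,%d)", seq(0, 90, 10), seq(10, 100, 10)),
            "100"),
    lower = c(0, seq(0, 90, 10), 100),
    upper = c(0, seq(10, 100, 10), 100),
    count = c(sum(values == 0),
              vapply(1:10, function(b) sum(idx == b), integer(1)),
              sum(values == 100))
  )
  class(out) <- c("active_fraction_histogram", class(out))
  out
}

#' Per-neuron response counts and unit-width frequency histogram
#'
#' `response_frequencies()` counts the onsets of each neuron over the
#' recording (events per 2-min session at the default frame rate);
#' `frequency_histogram()` tabulates how many neurons show each response
#' frequency at unit bin width.
#'
#' @param raster An [event_raster()], binary matrix, or list of either
#'   (counts are pooled over the list).
#'
#' @return `response_frequencies()`: a tibble with columns `cluster_id`,
#'   `neuron`, `n_events`. `frequency_histogram()`: a tibble of class
#'   `frequency_distribution` with columns `frequency` (1 ... max observed)
#'   and `n_neurons`.
#' @export
response_frequencies <- function(raster) {
  if (is.list(raster) && !inherits(raster, "event_raster")) {
    return(dplyr::bind_rows(purrr::imap(raster, function(r, i) {
      out <- response_frequencies(r)
      if (all(is.na(out$cluster_id))) out$cluster_id <- i
      out
    })))
  }
  m <- as_raster_matrix(raster)
  id <- if (inherits(raster, "event_raster")) raster$cluster_id else NULL
  tibble(
    cluster_id = id %||% NA_integer_,
    neuron = seq_len(nrow(m)),
    n_events = as.integer(rowSums(m))
  )
}

#' @rdname response_frequencies
#' @param frequencies Integer response counts, or the tibble returned by
#'   `response_frequencies()`.
#' @export
frequency_histogram <- function(frequencies) {
  if (is.data.frame(frequencies)) frequencies <- frequencies$n_events
  frequencies <- as.integer(frequencies)
  if (any(frequencies < 0)) abort("Response counts must be non-negative.")
  maxf <- max(frequencies, 1L)
  out <- tibble(
    frequency = seq_len(maxf),
    n_neurons = vapply(seq_len(maxf), function(f) sum(frequencies == f),
                       integer(1))
  )
  class(out) <- c("frequency_distribution", class(out))
  attr(out, "n_zero") <- sum(frequencies == 0L)
  out
}

#' Classify a cluster as completely synchronising
#'
#' TRUE iff at least one synchronous group contains every neuron of the
#' cluster.
#'
#' @param raster An [event_raster()] or binary matrix.
#' @param window_frames Synchrony window in frames (default 1).
#'
#' @return Logical scalar.
#' @export
classify_full_sync <- function(raster, window_frames = 1L) {
  m <- as_raster_matrix(raster)
  sizes <- synchronous_groups(m, window_frames)
  length(sizes) > 0 && max(sizes) == nrow(m)
}
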