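#' Rectified, integrated envelope of a ventral-root trace
#'
#' Moving average of the absolute deviation from the trace median — the
#' standard treatment that turns a noisy electroneurogram into a smooth
#' burst envelope.
#'
#' @param trace Numeric vector.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param smooth_window_s Smoothing window in seconds (default 0.1; must
#'   span at least 2 samples and at most the trace).
#'
#' @return Numeric envelope, same length as `trace`, attribute
#'   `sample_rate_hz`.
#' @export
vr_envelope <- function(trace, sample_rate_hz, smooth_window_s = 0.1) {
  assert_scalar_number(sample_rate_hz, "sample_rate_hz", lower = 1e-9)
  w <- round(smooth_window_s * sample_rate_hz)
  if (w < 2) abort("`smooth_window_s` must span at least 2 samples.")
  if (w > length(trace)) abort("Smoothing window longer than the trace.")
  env <- moving_average(abs(trace - median(trace)), w)
  attr(env, "sample_rate_hz") <- sample_rate_hz
  env
}

#' Detect motor bursts in an envelope
#'
#' Two-pass thresholding so that bursts do not inflate the noise estimate: a
#' provisional threshold (median + `k_threshold` robust SD of the whole
#' envelope, or the mid-range when the envelope is noise-free) selects
#' baseline samples, and the final threshold is the baseline median plus
#' `k_threshold` times the baseline's robust SD. Runs above the final
#' threshold are merged across sub-threshold gaps shorter than
#' `merge_gap_s`, runs shorter than `min_duration_s` are discarded, and each
#' burst's onset/offset is refined to the half-height crossing of its peak
#' (exact to one sample for clean square bursts).
#'
#' @param envelope Envelope from [vr_envelope()] (non-negative).
#' @param sample_rate_hz Sampling rate; defaults to the envelope attribute.
#' @param k_threshold Threshold in baseline robust-SD units (default 3).
#' @param min_duration_s Minimal burst duration in seconds (default 0.2).
#' @param merge_gap_s Sub-threshold gaps shorter than this are fused
#'   (default 0.1).
#'
#' @return A tibble of class `burst_train` with columns `onset_s`,
#'   `offset_s` (non-overlapping, ordered). If no baseline can be estimated
#'   (trace saturated above threshold) the attribute `no_rhythm` is TRUE.
#' @export
detect_bursts <- function(envelope, sample_rate_hz = NULL, k_threshold = 3,
                          min_duration_s = 0.2, merge_gap_s = 0.1) {
  sr <- sample_rate_hz %||% attr(envelope, "sample_rate_hz")
  if (is.null(sr)) abort("`sample_rate_hz` is required.")
  if (any(envelope < 0)) abort("`envelope` must be non-negative.")
  n <- length(envelope)
  empty <- structure(
    tibble(onset_s = numeric(0), offset_s = numeric(0)),
    class = c("burst_train", class(tibble())), no_rhythm = FALSE)
  s0 <- mad(envelope)
  thr1 <- if (s0 > 0) median(envelope) + k_threshold * s0 else
    (min(envelope) + max(envelope)) / 2
  base <- envelope[envelope < thr1]
  if (length(base) == 0L) {
    attr(empty, "no_rhythm") <- TRUE
    return(empty)
  }
  base_med <- median(base)
  thr <- base_med + k_threshold * max(mad(base), 1e-9 * max(envelope, 1e-12))
  above <- envelope > thr
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  # fuse runs separated by short sub-threshold gaps
  if (nrow(runs) > 1L) {
    gap <- (runs[-1, 1] - runs[-nrow(runs), 2] - 1L) / sr
    keep_sep <- gap >= merge_gap_s
    grp <- cumsum(c(TRUE, keep_sep))
    runs <- do.call(rbind, lapply(split(seq_len(nrow(runs)), grp), function(i)
      c(runs[min(i), 1], runs[max(i), 2])))
  }
  # drop short runs, then refine edges at half height
  keep <- (runs[, 2] - runs[, 1] + 1L) / sr >= min_duration_s
  runs <- runs[keep, , drop = FALSE]
  if (nrow(runs) == 0L) return(empty)
  refined <- t(apply(runs, 1, function(rn) {
    half <- (base_med + max(envelope[rn[1]:rn[2]])) / 2
    i <- rn[1]
    if (envelope[i] >= half) {
      while (i > 1L && envelope[i - 1L] >= half) i <- i - 1L
    } else {
      while (i < rn[2] && envelope[i] < half) i <- i + 1L
    }
    j <- rn[2]
    if (envelope[j] >= half) {
      while (j < n && envelope[j + 1L] >= half) j <- j + 1L
    } else {
      while (j > rn[1] && envelope[j] < half) j <- j - 1L
    }
    c(i, j)
  }))
  # refinement must keep bursts ordered and disjoint
  ok <- c(TRUE, refined[-1, 1] > refined[-nrow(refined), 2])
  refined <- unname(refined[ok, , drop = FALSE])
  out <- tibble(onset_s = (refined[, 1] - 1L) / sr,
                offset_s = (refined[, 2] - 1L) / sr)
  structure(out, class = c("burst_train", class(out)), no_rhythm = FALSE)
}

#' Right-onset phases within left burst cycles
#'
#' For each left cycle `[onset_i, onset_{i+1})`, every right-burst onset in
#' the cycle is expressed as a phase
#' `(t - onset_i) / (onset_{i+1} - onset_i)` in `[0, 1)`. Phase 0.5 means
#' strict left-right alternation, phase 0 left-right synchrony.
#'
#' @param left,right `burst_train` tibbles from [detect_bursts()] (or any
#'   data frame with an `onset_s` column).
#'
#' @return Numeric phase vector. Fewer than 3 left bursts cannot define a
#'   rhythm: an empty vector with attribute `no_rhythm = TRUE` is returned.
#' @export
cycle_phases <- function(left, right) {
  lo <- left$onset_s
  ro <- right$onset_s
  if (length(lo) < 3L) {
    return(structure(numeric(0), no_rhythm = TRUE))
  }
  phases <- unlist(lapply(seq_len(length(lo) - 1L), function(i) {
    inside <- ro[ro >= lo[i] & ro < lo[i + 1L]]
    (inside - lo[i]) / (lo[i + 1L] - lo[i])
  }))
  unname(as.numeric(phases))
}

circular_distance <- function(a, b) {
  d <- abs(a - b) %% 1
  pmin(d, 1 - d)
}

#' Classify a left-right coordination pattern from cycle phases
#'
#' Computes the circular mean and resultant length R of the phase
#' distribution. Low concentration (`R < r_min`) means no consistent
#' phase relation: arrhythmic. Otherwise the circular mean is compared to
#' 0.5 (alternating) and 0.0 (synchronous) within `phase_tol` of a cycle;
#' means near neither are also labelled arrhythmic. The thresholds are
#' analysis choices (defaults `r_min = 0.6`, `phase_tol = 0.125`) and are
#' recorded in the result.
#'
#' @param phases Phases in `[0, 1)` from [cycle_phases()].
#' @param r_min Minimal resultant length for a rhythmic label.
#' @param phase_tol Tolerance (cycle fraction) around 0.5 / 0.0.
#'
#' @return An object of class `rhythm_classification`: `label` (one of
#'   `"alternating"`, `"synchronous"`, `"arrhythmic"`, `"no_rhythm"`),
#'   `circular_mean`, `resultant_length`, `n_phases`, `phases`, and the
#'   thresholds used. `glance()` gives a one-row tibble.
#' @export
classify_rhythm <- function(phases, r_min = 0.6, phase_tol = 0.125) {
  assert_probability(r_min, "r_min")
  assert_scalar_number(phase_tol, "phase_tol", lower = 0, upper = 0.25)
  if (length(phases) == 0L || isTRUE(attr(phases, "no_rhythm"))) {
    return(structure(
      list(label = "no_rhythm", circular_mean = NA_real_,
           resultant_length = NA_real_, n_phases = 0L,
           phases = numeric(0), r_min = r_min, phase_tol = phase_tol),
      class = "rhythm_classification"))
  }
  if (any(phases < 0 | phases >= 1)) abort("Phases must lie in [0, 1).")
  z <- mean(exp(2i * pi * phases))
  r <- Mod(z)
  mu <- (Arg(z) / (2 * pi)) %% 1
  label <- if (r < r_min) {
    "arrhythmic"
  } else if (circular_distance(mu, 0.5) <= phase_tol) {
    "alternating"
  } else if (circular_distance(mu, 0) <= phase_tol) {
    "synchronous"
  } else {
    "arrhythmic"
  }
  structure(
    list(label = label, circular_mean = mu, resultant_length = r,
         n_phases = length(phases), phases = as.numeric(phases),
         r_min = r_min, phase_tol = phase_tol),
    class = "rhythm_classification")
}

#' @export
print.rhythm_classification <- function(x, ...) {
  cat(sprintf(
    "<rhythm_classification> %s (n = %d phases, mean = %s, R = %s)\n",
    x$label, x$n_phases,
    if (is.na(x$circular_mean)) "NA" else sprintf("%.3f", x$circular_mean),
    if (is.na(x$resultant_length)) "NA" else
      sprintf("%.3f", x$resultant_length)))
  invisible(x)
}

#' @rdname classify_rhythm
#' @param x A `rhythm_classification`.
#' @param ... Unused.
#' @export
glance.rhythm_classification <- function(x, ...) {
  tibble(label = x$label, circular_mean = x$circular_mean,
         resultant_length = x$resultant_length, n_phases = x$n_phases,
         r_min = x$r_min, phase_tol = x$phase_tol)
}

#' End-to-end classification of a ventral-root trace pair
#'
#' Convenience wrapper: envelopes both traces, detects bursts, computes
#' right-onset phases within left cycles and classifies the coordination
#' pattern.
#'
#' @param pair A `vr_trace_pair` (see [generate_vr_traces()]) or a list
#'   with `left`, `right`, `sample_rate_hz`.
#' @param smooth_window_s,k_threshold,min_duration_s,merge_gap_s Passed to
#'   [vr_envelope()] / [detect_bursts()].
#' @param r_min,phase_tol Passed to [classify_rhythm()].
#'
#' @return A `rhythm_classification` with the detected burst trains attached
#'   as attributes `left_bursts` and `right_bursts`.
#' @export
classify_vr_pair <- function(pair, smooth_window_s = 0.1, k_threshold = 3,
                             min_duration_s = 0.2, merge_gap_s = 0.1,
                             r_min = 0.6, phase_tol = 0.125) {
  sr <- pair$sample_rate_hz
  lb <- detect_bursts(vr_envelope(pair$left, sr, smooth_window_s),
                      sr, k_threshold, min_duration_s, merge_gap_s)
  rb <- detect_bursts(vr_envelope(pair$right, sr, smooth_window_s),
                      sr, k_threshold, min_duration_s, merge_gap_s)
  phases <- cycle_phases(lb, rb)
  out <- classify_rhythm(phases, r_min = r_min, phase_tol = phase_tol)
  attr(out, "left_bursts") <- lb
  attr(out, "right_bursts") <- rb
  out
}

#' Rayleigh test of circular uniformity
#'
#' Tests whether phases (in cycle units) are uniformly distributed on the
#' circle, using the Rayleigh statistic `z = n R^2` with the standard
#' finite-sample correction to the p value.
#'
#' @param phases Phases in `[0, 1)`.
#'
#' @return A tibble with `n`, `resultant_length`, `z` and `p_value`.
#' @export
rayleigh_test <- function(phases) {
  n <- length(phases)
  if (n < 2L) abort("Need at least 2 phases.")
  r <- Mod(mean(exp(2i * pi * phases)))
  z <- n * r^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  tibble(n = n, resultant_length = r, z = z,
         p_value = max(min(p, 1), 0))
}
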