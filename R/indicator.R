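#' Calcium-indicator response parameters
#'
#' Generic kinetics of a fast synthetic calcium dye: instantaneous rise,
#' single-exponential decay, linear summation of transients, additive
#' Gaussian noise. Values are expressed in dF/F units so they are independent
#' of the baseline fluorescence level.
#'
#' @param baseline_f0 Baseline fluorescence, arbitrary units (> 0).
#' @param spike_amplitude Peak dF/F added by one event (default 0.3).
#' @param decay_tau_s Exponential decay time constant in seconds (default 1).
#' @param noise_sd Gaussian noise SD in dF/F units (default 0.02; 0 gives
#'   deterministic traces).
#'
#' @return An `indicator_params` list.
#' @export
indicator_params <- function(baseline_f0 = 100,
                             spike_amplitude = 0.3,
                             decay_tau_s = 1,
                             noise_sd = 0.02) {
  assert_scalar_number(baseline_f0, "baseline_f0", lower = 1e-12)
  assert_scalar_number(spike_amplitude, "spike_amplitude", lower = 0)
  assert_scalar_number(decay_tau_s, "decay_tau_s", lower = 1e-12)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  structure(
    list(baseline_f0 = baseline_f0, spike_amplitude = spike_amplitude,
         decay_tau_s = decay_tau_s, noise_sd = noise_sd),
    class = "indicator_params"
  )
}

#' Synthesise fluorescence traces from an event raster
#'
#' `F(t) = baseline_f0 * (1 + sum over events amplitude * exp(-(t - t_ev)/tau))`
#' plus Gaussian noise of SD `noise_sd * baseline_f0`. Transients rise within
#' one frame and sum linearly; the recursion `s[t] = A * spike[t] +
#' s[t-1] * exp(-dt/tau)` realises this exactly.
#'
#' @param raster An [event_raster()] or binary neurons x frames matrix.
#' @param params An [indicator_params()].
#' @param seed Integer seed for the noise draw.
#' @param dt_s Frame interval; defaults to the raster's `dt_s`.
#' @param cluster_id Optional label carried onto the recording.
#'
#' @return A [fluorescence_recording()].
#' @export
spikes_to_fluorescence <- function(raster, params = indicator_params(),
                                   seed = 1L, dt_s = NULL,
                                   cluster_id = NULL) {
  if (!inherits(params, "indicator_params")) {
    abort("`params` must be created by `indicator_params()`.")
  }
  if (inherits(raster, "event_raster")) {
    dt_s <- dt_s %||% raster$dt_s
    cluster_id <- cluster_id %||% raster$cluster_id
    m <- raster$onsets
  } else {
    dt_s <- dt_s %||% 0.1
    m <- raster
  }
  if (!all(m %in% c(0, 1))) abort("`raster` must be binary.")
  decay <- exp(-dt_s / params$decay_tau_s)
  signal <- t(apply(m * params$spike_amplitude, 1, function(x) {
    as.numeric(stats::filter(x, decay, method = "recursive"))
  }))
  values <- params$baseline_f0 * (1 + signal)
  if (params$noise_sd > 0) {
    noise <- withr::with_seed(seed, matrix(
      rnorm(length(values), sd = params$noise_sd * params$baseline_f0),
      nrow(values), ncol(values)))
    values <- values + noise
  }
  fluorescence_recording(values, dt_s = dt_s, cluster_id = cluster_id)
}
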