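#' Specify a synthetic ventral-root trace pair
#'
#' Paired left/right lumbar ventral-root output during drug-induced fictive
#' locomotion, modelled at the rectified-envelope level: bursts are rendered
#' as amplitude pedestals on a flat baseline with additive Gaussian noise.
#' The right-side burst onsets are placed at a mode-dependent phase of the
#' left cycle: 0.5 for `alternating` (normal locomotor pattern), 0.0 for
#' `synchronous` (the pattern evoked when crossed inhibition is blocked),
#' uniformly at random for `arrhythmic`; `silent` produces no bursts.
#'
#' @param mode One of `"alternating"`, `"synchronous"`, `"arrhythmic"`,
#'   `"silent"`.
#' @param cycle_period_s Left burst cycle period in seconds (default 2).
#' @param burst_duty Burst duration as a fraction of the cycle, in (0, 1).
#' @param burst_amplitude Burst pedestal amplitude in signal units.
#' @param sample_rate_hz Sampling rate (default 500 Hz).
#' @param noise_sd Additive Gaussian noise SD in signal units.
#' @param duration_s Recording length in seconds; must cover at least one
#'   full cycle.
#' @param seed Integer seed.
#'
#' @return A `vr_sim_spec` list.
#' @export
vr_sim_spec <- function(mode = c("alternating", "synchronous", "arrhythmic",
                                 "silent"),
                        cycle_period_s = 2,
                        burst_duty = 0.4,
                        burst_amplitude = 1,
                        sample_rate_hz = 500,
                        noise_sd = 0.1,
                        duration_s = 60,
                        seed = 1L) {
  mode <- match.arg(mode)
  assert_scalar_number(cycle_period_s, "cycle_period_s", lower = 1e-9)
  assert_scalar_number(burst_duty, "burst_duty", lower = 1e-9,
                       upper = 1 - 1e-9)
  assert_scalar_number(burst_amplitude, "burst_amplitude", lower = 0)
  assert_scalar_number(sample_rate_hz, "sample_rate_hz", lower = 1e-9)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  assert_scalar_number(duration_s, "duration_s", lower = 1e-9)
  if (mode != "silent" && duration_s < cycle_period_s) {
    abort("`duration_s` must cover at least one cycle.")
  }
  structure(
    list(mode = mode, cycle_period_s = cycle_period_s,
         burst_duty = burst_duty, burst_amplitude = burst_amplitude,
         sample_rate_hz = sample_rate_hz, noise_sd = noise_sd,
         duration_s = duration_s, seed = as.integer(seed)),
    class = "vr_sim_spec"
  )
}

#' Generate a paired left/right ventral-root trace with ground truth
#'
#' @param spec A [vr_sim_spec()].
#'
#' @return A list of class `vr_trace_pair`: `left`, `right` (numeric
#'   vectors), `sample_rate_hz`, `duration_s`, and a `truth` list holding the
#'   left/right burst interval tibbles (`onset_s`, `offset_s`) and the
#'   ground-truth right-onset `phases`.
#' @export
generate_vr_traces <- function(spec) {
  if (!inherits(spec, "vr_sim_spec")) {
    abort("`spec` must be created by `vr_sim_spec()`.")
  }
  sr <- spec$sample_rate_hz
  n <- round(spec$duration_s * sr)
  t_axis <- (seq_len(n) - 1) / sr
  period <- spec$cycle_period_s
  burst_len <- spec$burst_duty * period
  render <- function(onsets) {
    x <- numeric(n)
    for (o in onsets) {
      i0 <- max(1L, floor(o * sr) + 1L)
      i1 <- min(n, floor((o + burst_len) * sr))
      if (i1 >= i0) x[i0:i1] <- spec$burst_amplitude
    }
    x
  }
  withr::with_seed(spec$seed, {
    if (spec$mode == "silent") {
      left_on <- numeric(0)
      right_on <- numeric(0)
      phases <- numeric(0)
    } else {
      # leave one burst length of margin so the last cycle fits
      left_on <- seq(0.25 * period, spec$duration_s - burst_len,
                     by = period)
      phases <- switch(spec$mode,
        alternating = rep(0.5, length(left_on) - 1L),
        synchronous = rep(0, length(left_on) - 1L),
        arrhythmic = runif(length(left_on) - 1L)
      )
      right_on <- left_on[-length(left_on)] + phases * period
    }
    left <- render(left_on)
    right <- render(right_on)
    if (spec$noise_sd > 0) {
      left <- left + rnorm(n, sd = spec$noise_sd)
      right <- right + rnorm(n, sd = spec$noise_sd)
    }
  })
  structure(
    list(left = left, right = right, sample_rate_hz = sr,
         duration_s = spec$duration_s,
         truth = list(
           left_bursts = tibble(onset_s = left_on,
                                offset_s = left_on + burst_len),
           right_bursts = tibble(onset_s = right_on,
                                 offset_s = right_on + burst_len),
           phases = phases
         ),
         spec = spec),
    class = "vr_trace_pair"
  )
}

#' @export
print.vr_trace_pair <- function(x, ...) {
  cat(sprintf(
    "<vr_trace_pair> %.0f s at %g Hz, %d left / %d right bursts (%s)\n",
    x$duration_s, x$sample_rate_hz, nrow(x$truth$left_bursts),
    nrow(x$truth$right_bursts), x$spec$mode))
  invisible(x)
}
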