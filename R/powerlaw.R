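#' Fit a power law to a response-frequency histogram
#'
#' Ordinary least squares of `log10(n_neurons)` against `log10(frequency)`
#' over the non-empty bins of a unit-width frequency histogram — the straight
#' line of the histogram's log-log presentation. Zero-count bins are
#' excluded (their logarithm is undefined); the slope is returned signed. At
#' least three non-empty bins with frequency >= 1 are required, otherwise the
#' fit is flagged as undefined. A slope near -1 indicates the heavy-tailed
#' activity heterogeneity characteristic of scale-free-like cultured
#' networks; narrow bell-shaped distributions yield no usable fit or a slope
#' far from it.
#'
#' @param freq_histogram A `frequency_distribution` tibble from
#'   [frequency_histogram()], or any data frame with columns `frequency` and
#'   `n_neurons`.
#'
#' @return An object of class `power_law_fit` with fields `slope`,
#'   `intercept`, `r_squared`, `fitted` (logical), `n_bins` and `data`.
#' @examples
#' h <- tibble::tibble(frequency = 1:10, n_neurons = round(1000 * (1:10)^-2))
#' fit_power_law(h)$slope
#' @export
fit_power_law <- function(freq_histogram) {
  if (!is.data.frame(freq_histogram) ||
      !all(c("frequency", "n_neurons") %in% names(freq_histogram))) {
    abort("`freq_histogram` needs columns `frequency` and `n_neurons`.")
  }
  keep <- freq_histogram$frequency >= 1 & freq_histogram$n_neurons > 0
  pts <- freq_histogram[keep, , drop = FALSE]
  out <- structure(
    list(slope = NA_real_, intercept = NA_real_, r_squared = NA_real_,
         fitted = FALSE, n_bins = nrow(pts), data = as_tibble(pts)),
    class = "power_law_fit"
  )
  if (nrow(pts) < 3L) {
    return(out)
  }
  lx <- log10(pts$frequency)
  ly <- log10(pts$n_neurons)
  fit <- lm(ly ~ lx)
  out$slope <- unname(coef(fit)[2])
  out$intercept <- unname(coef(fit)[1])
  sst <- sum((ly - mean(ly))^2)
  ssr <- sum(fit$residuals^2)
  out$r_squared <- if (sst == 0) 1 else 1 - ssr / sst
  out$fitted <- TRUE
  out
}

#' @export
print.power_law_fit <- function(x, ...) {
  if (x$fitted) {
    cat(sprintf(
      "<power_law_fit> slope = %.3f, intercept = %.3f, R^2 = %.3f (%d bins)\n",
      x$slope, x$intercept, x$r_squared, x$n_bins))
  } else {
    cat(sprintf(
      "<power_law_fit> not fitted (%d non-empty bins, need >= 3)\n",
      x$n_bins))
  }
  invisible(x)
}

#' Tidy a power-law fit
#'
#' @param x A `power_law_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per coefficient; `glance()`: a one-row summary
#'   with `slope`, `intercept`, `r_squared`, `n_bins`, `fitted`.
#' @export
tidy.power_law_fit <- function(x, ...) {
  tibble(
    term = c("log10_intercept", "log10_slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @rdname tidy.power_law_fit
#' @export
glance.power_law_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         r_squared = x$r_squared, n_bins = x$n_bins, fitted = x$fitted)
}

#' Sample per-neuron response frequencies from a discrete power law
#'
#' Draws `n` integer response frequencies from `p(f)` proportional to
#' `f^-exponent` on the support `f_range[1] ... f_range[2]`. Used to emulate
#' the heavy-tailed per-neuron response-frequency distribution of healthy
#' cultured networks with a known ground-truth exponent.
#'
#' @param n Number of neurons to sample.
#' @param exponent Positive power-law exponent (the log-log slope is its
#'   negative).
#' @param f_range Integer support, default `c(1, 64)` (responses per 2-min
#'   recording).
#' @param seed Integer seed.
#'
#' @return Integer vector of length `n`.
#' @export
sample_response_frequencies <- function(n, exponent = 0.981,
                                        f_range = c(1L, 64L), seed = 1L) {
  assert_scalar_number(n, "n", lower = 1, integer = TRUE)
  assert_scalar_number(exponent, "exponent", lower = 0)
  f <- f_range[1]:f_range[2]
  p <- f^(-exponent)
  withr::with_seed(seed, sample(f, n, replace = TRUE, prob = p / sum(p)))
}
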