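#' Plot a synchrony-size histogram
#'
#' Bar chart of synchronous-group counts by size with the distinguished
#' `"all"` bin on the right, mirroring the standard presentation of cluster
#' synchrony histograms.
#'
#' @param object A [synchrony_histogram()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.synchrony_histogram <- function(object, ...) {
  object$bin <- factor(object$bin, levels = object$bin)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin, y = .data$count)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "neurons responding in synchrony",
                  y = "number of events") +
    ggplot2::theme_classic()
}

#' Plot an active-fraction histogram
#'
#' @param object An [bin_active_fractions()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.active_fraction_histogram <- function(object, ...) {
  object$bin <- factor(object$bin, levels = object$bin)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin, y = .data$count)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "active neurons per cluster (%)",
                  y = "number of clusters") +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a response-frequency distribution with its power-law fit
#'
#' Log-log scatter of neuron counts against response frequency; when a
#' [fit_power_law()] result is supplied (or computable) the fitted line is
#' overlaid.
#'
#' @param object A `frequency_distribution` tibble from
#'   [frequency_histogram()].
#' @param fit Optional `power_law_fit`; defaults to fitting `object`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.frequency_distribution <- function(object, fit = NULL, ...) {
  fit <- fit %||% fit_power_law(object)
  pts <- object[object$n_neurons > 0, , drop = FALSE]
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$frequency,
                                         y = .data$n_neurons)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "responses per recording", y = "number of neurons") +
    ggplot2::theme_classic()
  if (isTRUE(fit$fitted)) {
    p <- p + ggplot2::geom_abline(slope = fit$slope,
                                  intercept = fit$intercept,
                                  linetype = "dashed")
  }
  p
}

#' Plot the phase distribution of a rhythm classification
#'
#' Circular histogram of right-onset phases; 0.5 marks strict alternation,
#' 0 marks synchrony.
#'
#' @param object A [classify_rhythm()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rhythm_classification <- function(object, ...) {
  d <- tibble(phase = object$phases)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$phase)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, 0.05), fill = "grey30") +
    ggplot2::coord_polar() +
    ggplot2::scale_x_continuous(limits = c(0, 1),
                                breaks = c(0, 0.25, 0.5, 0.75)) +
    ggplot2::labs(x = sprintf("right-onset phase (%s, R = %.2f)",
                              object$label, object$resultant_length),
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a two-channel puncta scene
#'
#' Neurite polylines and puncta of both channels in field coordinates; true
#' colocalized partners are ringed.
#'
#' @param scene A `puncta_scene` from [generate_puncta_scene()].
#' @return A ggplot object.
#' @export
plot_puncta_scene <- function(scene) {
  poly_df <- function(polys, ch) {
    dplyr::bind_rows(purrr::imap(polys, function(p, i) {
      tibble(x_um = p[, 1], y_um = p[, 2], id = paste0(ch, i),
             channel = ch)
    }))
  }
  lines <- dplyr::bind_rows(poly_df(scene$polylines_a, "A"),
                            poly_df(scene$polylines_b, "B"))
  spots <- dplyr::bind_rows(scene$spots_a, scene$spots_b)
  ggplot2::ggplot() +
    ggplot2::geom_path(data = lines,
                       ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                    group = .data$id,
                                    colour = .data$channel),
                       alpha = 0.4) +
    ggplot2::geom_point(data = spots,
                        ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                     colour = .data$channel),
                        size = 0.8) +
    ggplot2::geom_point(data = spots[spots$truth, , drop = FALSE],
                        ggplot2::aes(x = .data$x_um, y = .data$y_um),
                        shape = 1, size = 2) +
    ggplot2::scale_colour_manual(values = c(A = "#1b9e77",
                                            B = "#d95f02")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
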