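#' One-way ANOVA with post-hoc Tukey HSD across conditions
#'
#' The standard decomposition for per-field counts (puncta or cells per
#' microscope field) compared across two or more conditions, followed by
#' Tukey honest-significant-difference tests on all condition pairs.
#'
#' @param data A data frame with one row per field/observation.
#' @param value Column of measured values (tidy-eval).
#' @param group Column of condition labels (tidy-eval).
#'
#' @return An object of class `group_test` with elements `anova` (tibble:
#'   `f_statistic`, `df_between`, `df_within`, `p_value`), `tukey` (tibble:
#'   `comparison`, `estimate`, `conf_low`, `conf_high`, `p_adj`) and the
#'   underlying `aov` fit. `tidy()` returns the Tukey table, `glance()` the
#'   ANOVA row.
#' @examples
#' d <- data.frame(n = c(10, 12, 11, 20, 22, 21), g = rep(c("a", "b"), each = 3))
#' glance(group_test(d, n, g))
#' @export
group_test <- function(data, value, group) {
  v <- eval_tidy(enquo(value), data)
  g <- as.factor(eval_tidy(enquo(group), data))
  if (nlevels(g) < 2L) abort("`group` must have at least 2 conditions.")
  if (any(table(g) < 2L)) {
    abort("Every condition needs at least 2 values.")
  }
  fit <- aov(v ~ g)
  s <- summary(fit)[[1]]
  anova_tbl <- tibble(
    f_statistic = s[1, "F value"],
    df_between = s[1, "Df"],
    df_within = s[2, "Df"],
    p_value = s[1, "Pr(>F)"]
  )
  tk <- TukeyHSD(fit)$g
  tukey_tbl <- tibble(
    comparison = rownames(tk),
    estimate = tk[, "diff"],
    conf_low = tk[, "lwr"],
    conf_high = tk[, "upr"],
    p_adj = tk[, "p adj"]
  )
  structure(list(anova = anova_tbl, tukey = tukey_tbl, fit = fit),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("<group_test> one-way ANOVA F(%d, %d) = %.3f, p = %.3g\n",
              x$anova$df_between, x$anova$df_within, x$anova$f_statistic,
              x$anova$p_value))
  print(x$tukey)
  invisible(x)
}

#' @rdname group_test
#' @param x A `group_test`.
#' @param ... Unused.
#' @export
tidy.group_test <- function(x, ...) x$tukey

#' @rdname group_test
#' @export
glance.group_test <- function(x, ...) x$anova

#' Survival ratio of a double-labelled population
#'
#' The percentage of marker-positive cells that are also neuron-positive,
#' e.g. `(GFP+NeuN+) / GFP+`, rounded to one decimal. Vectorised.
#'
#' @param double_positive Count of double-positive cells (`0 <=
#'   double_positive <= total`).
#' @param total Count of all marker-positive cells (> 0).
#'
#' @return Percentage(s) rounded to 1 decimal place.
#' @examples
#' survival_ratio(29, 78)  # 37.2
#' @export
survival_ratio <- function(double_positive, total) {
  if (any(total <= 0)) abort("`total` must be positive.")
  if (any(double_positive < 0 | double_positive > total)) {
    abort("`double_positive` must lie in [0, total].")
  }
  round(100 * double_positive / total, 1)
}

#' Survival-ratio table with optional consistency check
#'
#' Computes pooled survival percentages for a table of regions and, when a
#' `reported` column of previously published percentages is present, flags
#' rows whose pooled ratio disagrees with the reported value by more than
#' half a rounding unit — a sign that the reported number was averaged over
#' sections rather than pooled.
#'
#' @param counts Data frame with columns `region`, `double_positive`,
#'   `total`, and optionally `reported`.
#'
#' @return The input as a tibble with added `percent` and (if applicable)
#'   `matches_reported` columns.
#' @export
survival_table <- function(counts) {
  if (!all(c("region", "double_positive", "total") %in% names(counts))) {
    abort("`counts` needs columns region, double_positive, total.")
  }
  out <- as_tibble(counts)
  out$percent <- survival_ratio(out$double_positive, out$total)
  if ("reported" %in% names(out)) {
    out$matches_reported <- abs(out$percent - out$reported) <= 0.05
  }
  out
}
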