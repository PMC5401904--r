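#' Align per-cluster synchrony histograms into a bin matrix
#'
#' Binds a list of [synchrony_histogram()] tibbles (possibly from clusters of
#' different sizes) into one clusters x bins count matrix. Numeric bins are
#' aligned by group size up to `max_size - 1`; the `"all"` bin is shared by
#' all clusters regardless of their size; clusters too small to populate a
#' bin contribute a zero. Sizes between `max_size` and the cluster size are
#' pooled into the last numeric bin so no group is dropped.
#'
#' @param histograms List of `synchrony_histogram` tibbles.
#' @param max_size Largest distinct size bin (default 12); numeric bins run
#'   `1 ... max_size - 1` followed by a pooled `>=max_size` bin and `"all"`.
#'
#' @return A numeric matrix, rows = clusters, columns = bins.
#' @export
bind_synchrony_histograms <- function(histograms, max_size = 12L) {
  assert_scalar_number(max_size, "max_size", lower = 2, integer = TRUE)
  bins <- c(as.character(seq_len(max_size - 1L)),
            sprintf(">=%d", max_size), "all")
  rows <- purrr::map(histograms, function(h) {
    n <- attr(h, "cluster_size")
    full <- h$count[h$bin == "all"]
    partial <- h[h$bin != "all", , drop = FALSE]
    small <- vapply(seq_len(max_size - 1L), function(s) {
      if (s <= n - 1L) partial$count[partial$size == s] else 0L
    }, integer(1))
    pooled <- sum(partial$count[partial$size >= max_size])
    c(small, pooled, full)
  })
  m <- do.call(rbind, rows)
  colnames(m) <- bins
  m
}

signif_stars <- function(p) {
  dplyr::case_when(
    p < 1e-4 ~ "***",
    p < 0.005 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Per-bin Mann-Whitney comparison of two cluster groups
#'
#' For each bin (column), compares the per-cluster values of group A against
#' group B with a two-sided Mann-Whitney U test: exact enumeration when both
#' groups have at most 8 clusters and no ties, the tie-corrected normal
#' approximation otherwise. Bins in which every value of both groups is
#' identical carry no information and are reported as `U = n1*n2/2, p = 1`.
#' Significance tiers follow the three-star convention (0.05, 0.005, 1e-4).
#' Per-bin p values are reported uncorrected, matching the usual per-bin
#' histogram annotation; a Bonferroni-adjusted column is emitted alongside as
#' an extension.
#'
#' @param values_a,values_b Numeric matrices or data frames, rows = clusters,
#'   columns = bins (same columns in both; see
#'   [bind_synchrony_histograms()]).
#'
#' @return A tibble of class `group_comparison` with columns `bin`, `n_a`,
#'   `n_b`, `u_statistic`, `p_value`, `p_bonferroni`, `signif`.
#' @export
compare_groups <- function(values_a, values_b) {
  a <- as.matrix(values_a)
  b <- as.matrix(values_b)
  if (nrow(a) < 2L || nrow(b) < 2L) {
    abort("Each group needs at least 2 clusters.")
  }
  if (ncol(a) != ncol(b)) abort("Both groups must have the same bins.")
  bins <- colnames(a) %||% as.character(seq_len(ncol(a)))
  res <- purrr::map(seq_len(ncol(a)), function(j) {
    x <- a[, j]
    y <- b[, j]
    if (max(c(x, y)) == min(c(x, y))) {
      u <- length(x) * length(y) / 2
      p <- 1
    } else {
      exact <- length(x) <= 8L && length(y) <= 8L &&
        !any(duplicated(c(x, y)))
      wt <- suppressWarnings(
        wilcox.test(x, y, exact = exact, correct = !exact))
      u <- unname(wt$statistic)
      p <- wt$p.value
    }
    tibble(bin = bins[j], n_a = nrow(a), n_b = nrow(b),
           u_statistic = u, p_value = p)
  })
  out <- dplyr::bind_rows(res)
  out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  out$signif <- signif_stars(out$p_value)
  class(out) <- c("group_comparison", class(out))
  out
}
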