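# Minimum distance from each query point to a polyline (min over segments).
dist_to_polyline <- function(px, py, poly) {
  n <- nrow(poly)
  x1 <- poly[-n, 1]; y1 <- poly[-n, 2]
  x2 <- poly[-1, 1]; y2 <- poly[-1, 2]
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  len2[len2 == 0] <- 1e-300
  vapply(seq_along(px), function(i) {
    t <- ((px[i] - x1) * dx + (py[i] - y1) * dy) / len2
    t <- pmin(pmax(t, 0), 1)
    min(sqrt((px[i] - (x1 + t * dx))^2 + (py[i] - (y1 + t * dy))^2))
  }, numeric(1))
}

#' Pair up neurites running side by side
#'
#' A channel-A / channel-B polyline pair is accepted when a contiguous
#' stretch of at least `min_parallel_um` exists along the A polyline over
#' which the point-to-curve distance to the B polyline stays below
#' `max_sep_um` (default 0.5 um, the standard side-by-side criterion). Each
#' accepted pair is reported with its mean separation and parallel length
#' over that stretch.
#'
#' @param polylines_a,polylines_b Lists of two-column (x, y) matrices in
#'   common micrometre coordinates; polylines must have at least two points.
#' @param max_sep_um Maximal separation counted as side-by-side (default
#'   0.5).
#' @param min_parallel_um Minimal contiguous parallel stretch (default 5).
#' @param step_um Sampling step along the A polyline (default 0.05).
#'
#' @return A tibble with columns `id_a`, `id_b`, `mean_separation_um`,
#'   `parallel_length_um`, one row per accepted pair.
#' @export
pair_neurites <- function(polylines_a, polylines_b, max_sep_um = 0.5,
                          min_parallel_um = 5, step_um = 0.05) {
  if (!is.list(polylines_a)) polylines_a <- list(polylines_a)
  if (!is.list(polylines_b)) polylines_b <- list(polylines_b)
  for (p in c(polylines_a, polylines_b)) {
    if (!is.matrix(p) || nrow(p) < 2L) {
      abort("Polylines must be matrices with at least two points.")
    }
  }
  resample <- function(poly, step) {
    seg <- sqrt(diff(poly[, 1])^2 + diff(poly[, 2])^2)
    total <- sum(seg)
    s <- seq(0, total, by = step)
    cum <- c(0, cumsum(seg))
    i <- pmin(findInterval(s, cum, rightmost.closed = TRUE), nrow(poly) - 1L)
    frac <- (s - cum[i]) / seg[i]
    cbind(poly[i, 1] + frac * (poly[i + 1, 1] - poly[i, 1]),
          poly[i, 2] + frac * (poly[i + 1, 2] - poly[i, 2]))
  }
  rows <- list()
  for (ia in seq_along(polylines_a)) {
    pa <- resample(polylines_a[[ia]], step_um)
    for (ib in seq_along(polylines_b)) {
      d <- dist_to_polyline(pa[, 1], pa[, 2], polylines_b[[ib]])
      close <- d < max_sep_um
      r <- rle(close)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      runs <- which(r$values & r$lengths * step_um >= min_parallel_um)
      if (length(runs) == 0L) next
      best <- runs[which.max(r$lengths[runs])]
      span <- starts[best]:ends[best]
      rows[[length(rows) + 1L]] <- tibble(
        id_a = ia, id_b = ib,
        mean_separation_um = mean(d[span]),
        parallel_length_um = (length(span) - 1L) * step_um
      )
    }
  }
  if (length(rows) == 0L) {
    return(tibble(id_a = integer(0), id_b = integer(0),
                  mean_separation_um = numeric(0),
                  parallel_length_um = numeric(0)))
  }
  dplyr::bind_rows(rows)
}

#' Count colocalized puncta by one-to-one matching
#'
#' Matches channel-A to channel-B puncta within `radius_um` by greedy
#' nearest-first one-to-one assignment (ties broken deterministically by
#' coordinate order), so a dense clump cannot be double counted. When a
#' `corridor` is supplied, both spot sets are first restricted to points
#' within `corridor$max_sep_um` of either corridor polyline, giving per-pair
#' counts along side-by-side neurite stretches.
#'
#' @param spots_a,spots_b Tibbles or data frames with `x_um`, `y_um`
#'   columns, in common coordinates.
#' @param radius_um Maximal centroid distance counted as colocalized
#'   (default 0.5 um, the side-by-side separation criterion reused as the
#'   overlap radius).
#' @param corridor Optional list with elements `polyline_a`, `polyline_b`
#'   (two-column matrices) and optionally `max_sep_um` (default 0.5).
#'
#' @return Integer count of matched pairs, with the matching stored in
#'   attribute `"matches"` (tibble `index_a`, `index_b`, `distance_um`).
#' @export
count_colocalized <- function(spots_a, spots_b, radius_um = 0.5,
                              corridor = NULL) {
  if (radius_um < 0) abort("`radius_um` must be non-negative.")
  ax <- spots_a$x_um; ay <- spots_a$y_um
  bx <- spots_b$x_um; by <- spots_b$y_um
  ia <- seq_along(ax); ib <- seq_along(bx)
  if (!is.null(corridor)) {
    ms <- corridor$max_sep_um %||% 0.5
    near <- function(x, y) {
      if (length(x) == 0L) return(logical(0))
      pmin(dist_to_polyline(x, y, corridor$polyline_a),
           dist_to_polyline(x, y, corridor$polyline_b)) < ms
    }
    ka <- near(ax, ay); kb <- near(bx, by)
    ax <- ax[ka]; ay <- ay[ka]; ia <- ia[ka]
    bx <- bx[kb]; by <- by[kb]; ib <- ib[kb]
  }
  empty <- tibble(index_a = integer(0), index_b = integer(0),
                  distance_um = numeric(0))
  if (length(ax) == 0L || length(bx) == 0L) {
    return(structure(0L, matches = empty))
  }
  d <- sqrt(outer(ax, bx, `-`)^2 + outer(ay, by, `-`)^2)
  cand <- which(d <= radius_um, arr.ind = TRUE)
  if (nrow(cand) == 0L) {
    return(structure(0L, matches = empty))
  }
  dist <- d[cand]
  ord <- order(dist, ax[cand[, 1]], ay[cand[, 1]], bx[cand[, 2]],
               by[cand[, 2]])
  cand <- cand[ord, , drop = FALSE]
  dist <- dist[ord]
  used_a <- rep(FALSE, length(ax))
  used_b <- rep(FALSE, length(bx))
  ma <- mb <- integer(0)
  md <- numeric(0)
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE
      used_b[j] <- TRUE
      ma <- c(ma, ia[i]); mb <- c(mb, ib[j]); md <- c(md, dist[k])
    }
  }
  structure(length(ma),
            matches = tibble(index_a = ma, index_b = mb, distance_um = md))
}

#' Count puncta within a microscope field
#'
#' @param spots Tibble with `x_um`, `y_um` columns.
#' @param field_um Field side in micrometres, or a length-4 vector
#'   `c(xmin, xmax, ymin, ymax)`.
#'
#' @return Integer count of spots inside the field bounds.
#' @export
density_per_field <- function(spots, field_um) {
  if (length(field_um) == 1L) {
    bounds <- c(0, field_um, 0, field_um)
  } else if (length(field_um) == 4L) {
    bounds <- field_um
  } else {
    abort("`field_um` must be a side length or c(xmin, xmax, ymin, ymax).")
  }
  sum(spots$x_um >= bounds[1] & spots$x_um <= bounds[2] &
        spots$y_um >= bounds[3] & spots$y_um <= bounds[4])
}
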