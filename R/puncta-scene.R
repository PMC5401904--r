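#' Specify a synthetic two-channel puncta scene
#'
#' A scene contains `n_pairs` pairs of near-parallel neurite polylines (one
#' per channel) crossing a square field, with diffraction-limited puncta
#' placed along each polyline at a fixed linear density. A controllable
#' fraction of channel-A puncta receives a channel-B partner within a small
#' jitter radius — the ground truth for colocalization recovery.
#'
#' @param n_pairs Number of neurite pairs.
#' @param pair_separation_um Perpendicular distance between the two
#'   polylines of a pair, micrometres (> 0; pairs closer than 0.5 um count
#'   as side-by-side).
#' @param field_um Side of the square field in micrometres (default 105.9,
#'   a standard confocal field).
#' @param pixel_size_um Pixel size used when rendering, micrometres.
#' @param puncta_per_um Linear puncta density along each polyline.
#' @param coloc_fraction Fraction of channel-A puncta given a true
#'   channel-B partner.
#' @param coloc_jitter_um SD-free maximal offset of a true partner from its
#'   A punctum (default 0.1 um, well inside the 0.5 um matching radius).
#' @param psf_sigma_um Gaussian PSF sigma used when rendering.
#' @param seed Integer seed.
#'
#' @return A `puncta_scene_spec` list.
#' @export
puncta_scene_spec <- function(n_pairs = 16L,
                              pair_separation_um = 0.3,
                              field_um = 105.9,
                              pixel_size_um = 0.105,
                              puncta_per_um = 0.3,
                              coloc_fraction = 0.5,
                              coloc_jitter_um = 0.1,
                              psf_sigma_um = 0.15,
                              seed = 1L) {
  assert_scalar_number(n_pairs, "n_pairs", lower = 1, integer = TRUE)
  assert_scalar_number(pair_separation_um, "pair_separation_um",
                       lower = 1e-9)
  assert_scalar_number(field_um, "field_um", lower = 1)
  assert_scalar_number(pixel_size_um, "pixel_size_um", lower = 1e-6)
  assert_scalar_number(puncta_per_um, "puncta_per_um", lower = 0)
  assert_probability(coloc_fraction, "coloc_fraction")
  assert_scalar_number(coloc_jitter_um, "coloc_jitter_um", lower = 0)
  assert_scalar_number(psf_sigma_um, "psf_sigma_um", lower = 1e-6)
  if (field_um < 4 * pair_separation_um + 2) {
    abort("`field_um` is too small for the requested pair separation.")
  }
  structure(
    list(n_pairs = as.integer(n_pairs),
         pair_separation_um = pair_separation_um, field_um = field_um,
         pixel_size_um = pixel_size_um, puncta_per_um = puncta_per_um,
         coloc_fraction = coloc_fraction,
         coloc_jitter_um = coloc_jitter_um, psf_sigma_um = psf_sigma_um,
         seed = as.integer(seed)),
    class = "puncta_scene_spec"
  )
}

# A gently curved polyline crossing the field, sampled every ~0.5 um.
random_polyline <- function(field, margin = 1) {
  theta <- runif(1, 0, pi)
  cx <- runif(1, 0.25 * field, 0.75 * field)
  cy <- runif(1, 0.25 * field, 0.75 * field)
  half <- field  # long enough to cross, later clipped to the field
  s <- seq(-half, half, by = 0.5)
  amp <- runif(1, 0, 2)
  period <- runif(1, 30, 80)
  wig <- amp * sin(2 * pi * s / period)
  x <- cx + s * cos(theta) - wig * sin(theta)
  y <- cy + s * sin(theta) + wig * cos(theta)
  keep <- x > margin & x < field - margin & y > margin & y < field - margin
  # keep the longest contiguous in-field stretch
  r <- rle(keep)
  if (!any(r$values)) return(NULL)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- which.max(ifelse(r$values, r$lengths, 0))
  idx <- starts[i]:ends[i]
  cbind(x = x[idx], y = y[idx])
}

offset_polyline <- function(poly, d) {
  n <- nrow(poly)
  dx <- c(poly[2, 1] - poly[1, 1], poly[-1, 1] - poly[-n, 1])
  dy <- c(poly[2, 2] - poly[1, 2], poly[-1, 2] - poly[-n, 2])
  len <- sqrt(dx^2 + dy^2)
  cbind(x = poly[, 1] - d * dy / len, y = poly[, 2] + d * dx / len)
}

polyline_length <- function(poly) {
  sum(sqrt(diff(poly[, 1])^2 + diff(poly[, 2])^2))
}

# Poisson-distributed points along a polyline at linear density lambda.
points_along <- function(poly, lambda) {
  seg <- sqrt(diff(poly[, 1])^2 + diff(poly[, 2])^2)
  total <- sum(seg)
  k <- rpois(1, lambda * total)
  if (k == 0) return(cbind(x = numeric(0), y = numeric(0)))
  s <- sort(runif(k, 0, total))
  cum <- c(0, cumsum(seg))
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  frac <- (s - cum[i]) / seg[i]
  cbind(x = poly[i, 1] + frac * (poly[i + 1, 1] - poly[i, 1]),
        y = poly[i, 2] + frac * (poly[i + 1, 2] - poly[i, 2]))
}

#' Generate a synthetic two-channel puncta scene with ground truth
#'
#' Places `n_pairs` near-parallel polyline pairs in the field, puncta along
#' each polyline at `puncta_per_um`, and gives a `coloc_fraction` share of
#' channel-A puncta a channel-B partner within `coloc_jitter_um`. The
#' remaining channel-B puncta are placed independently, so any further
#' overlap is chance-level.
#'
#' @param spec A [puncta_scene_spec()].
#'
#' @return A list of class `puncta_scene`: `spots_a`, `spots_b` (tibbles
#'   `x_um`, `y_um`, `truth` — `truth` marks true partners), `polylines_a`,
#'   `polylines_b` (lists of matrices), `pairs` (tibble of ground-truth
#'   neurite pairs), and the `spec`.
#' @export
generate_puncta_scene <- function(spec) {
  if (!inherits(spec, "puncta_scene_spec")) {
    abort("`spec` must be created by `puncta_scene_spec()`.")
  }
  withr::with_seed(spec$seed, {
    polys_a <- list()
    polys_b <- list()
    tries <- 0L
    while (length(polys_a) < spec$n_pairs && tries < 50L * spec$n_pairs) {
      tries <- tries + 1L
      pa <- random_polyline(spec$field_um)
      if (is.null(pa) || nrow(pa) < 5L) next
      pb <- offset_polyline(pa, spec$pair_separation_um)
      inside <- pb[, 1] > 0 & pb[, 1] < spec$field_um &
        pb[, 2] > 0 & pb[, 2] < spec$field_um
      if (!all(inside)) next
      polys_a[[length(polys_a) + 1L]] <- pa
      polys_b[[length(polys_b) + 1L]] <- pb
    }
    if (length(polys_a) < spec$n_pairs) {
      abort("Field too small to place the requested neurite pairs.")
    }
    sa <- do.call(rbind, lapply(polys_a, points_along,
                                lambda = spec$puncta_per_um))
    sb_free <- do.call(rbind, lapply(polys_b, points_along,
                                     lambda = spec$puncta_per_um))
    n_a <- nrow(sa)
    is_partnered <- runif(n_a) < spec$coloc_fraction
    ang <- runif(sum(is_partnered), 0, 2 * pi)
    rad <- spec$coloc_jitter_um * sqrt(runif(sum(is_partnered)))
    sb_true <- cbind(x = sa[is_partnered, 1] + rad * cos(ang),
                     y = sa[is_partnered, 2] + rad * sin(ang))
    spots_a <- tibble(x_um = sa[, 1], y_um = sa[, 2],
                      truth = is_partnered, channel = "A")
    spots_b <- tibble(
      x_um = c(sb_true[, 1], sb_free[, 1]),
      y_um = c(sb_true[, 2], sb_free[, 2]),
      truth = rep(c(TRUE, FALSE), c(nrow(sb_true), nrow(sb_free))),
      channel = "B"
    )
    pairs <- tibble(
      pair_id = seq_len(spec$n_pairs),
      separation_um = spec$pair_separation_um,
      length_um = vapply(polys_a, polyline_length, numeric(1))
    )
  })
  structure(
    list(spots_a = spots_a, spots_b = spots_b, polylines_a = polys_a,
         polylines_b = polys_b, pairs = pairs, spec = spec),
    class = "puncta_scene"
  )
}

#' @export
print.puncta_scene <- function(x, ...) {
  cat(sprintf(
    "<puncta_scene> %d neurite pairs, %d A / %d B puncta in a %.1f um field\n",
    x$spec$n_pairs, nrow(x$spots_a), nrow(x$spots_b), x$spec$field_um))
  invisible(x)
}

#' Render one channel of a puncta scene as a pixel image
#'
#' Each punctum is drawn as a unit-amplitude Gaussian of SD `psf_sigma_um`.
#' Pixel (row, col) covers `[(col-1), col) x [(row-1), row)` pixel units with
#' its centre at `(col - 0.5, row - 0.5) * pixel_size_um`.
#'
#' @param spots Tibble with `x_um`, `y_um` columns (e.g. `scene$spots_a`).
#' @param field_um Field side in micrometres.
#' @param pixel_size_um Pixel size in micrometres.
#' @param psf_sigma_um Gaussian PSF sigma in micrometres.
#'
#' @return Numeric matrix (rows = y, columns = x).
#' @export
render_puncta_image <- function(spots, field_um, pixel_size_um = 0.105,
                                psf_sigma_um = 0.15) {
  npx <- ceiling(field_um / pixel_size_um)
  img <- matrix(0, npx, npx)
  if (nrow(spots) == 0L) return(img)
  sig_px <- psf_sigma_um / pixel_size_um
  r <- ceiling(4 * sig_px)
  for (k in seq_len(nrow(spots))) {
    cx <- spots$x_um[k] / pixel_size_um + 0.5
    cy <- spots$y_um[k] / pixel_size_um + 0.5
    cols <- max(1, floor(cx - r)):min(npx, ceiling(cx + r))
    rows <- max(1, floor(cy - r)):min(npx, ceiling(cy + r))
    gx <- exp(-((cols - cx)^2) / (2 * sig_px^2))
    gy <- exp(-((rows - cy)^2) / (2 * sig_px^2))
    img[rows, cols] <- img[rows, cols] + outer(gy, gx)
  }
  img
}

#' Write a two-channel puncta scene as a TIFF stack
#'
#' Renders both channels and writes a two-plane 32-bit float TIFF.
#'
#' @param scene A `puncta_scene`.
#' @param path Output file path.
#' @return Invisibly, the normalised two-channel array written.
#' @export
write_puncta_tiff <- function(scene, path) {
  a <- render_puncta_image(scene$spots_a, scene$spec$field_um,
                           scene$spec$pixel_size_um, scene$spec$psf_sigma_um)
  b <- render_puncta_image(scene$spots_b, scene$spec$field_um,
                           scene$spec$pixel_size_um, scene$spec$psf_sigma_um)
  top <- max(a, b, 1)
  tiff::writeTIFF(list(a / top, b / top), path, bits.per.sample = 32L)
  invisible(array(c(a, b) / top, dim = c(dim(a), 2L)))
}

#' Read a two-channel puncta TIFF written by [write_puncta_tiff()]
#'
#' @param path TIFF file path.
#' @return A list of numeric matrices, one per channel.
#' @export
read_puncta_tiff <- function(path) {
  planes <- tiff::readTIFF(path, all = TRUE)
  lapply(planes, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
}
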