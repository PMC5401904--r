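#' Detect diffraction-limited spots in a single-channel image
#'
#' Scale-matched blob detection: the image is convolved with a
#' negated Laplacian-of-Gaussian kernel at the expected PSF scale, local
#' maxima of the response above a relative threshold are extracted, and each
#' detection is refined to sub-pixel precision by a response-weighted
#' centroid over its 3x3 neighbourhood. Two spots closer than about one PSF
#' sigma merge into a single response peak and are reported as one
#' detection.
#'
#' @param image Numeric matrix (rows = y, columns = x), e.g. from
#'   [render_puncta_image()] or [read_puncta_tiff()].
#' @param psf_sigma_um Expected spot scale (Gaussian sigma), micrometres.
#' @param pixel_size_um Pixel size in micrometres (required to place
#'   detections in physical coordinates).
#' @param threshold Relative threshold in (0, 1]: keep maxima whose LoG
#'   response exceeds `threshold * max(response)` (default 0.2).
#'
#' @return A tibble with columns `x_um`, `y_um`, `intensity` (LoG response
#'   at the peak), sorted by decreasing intensity.
#' @export
detect_spots <- function(image, psf_sigma_um, pixel_size_um,
                         threshold = 0.2) {
  if (!is.matrix(image) || length(image) == 0L) {
    abort("`image` must be a non-empty numeric matrix.")
  }
  assert_scalar_number(pixel_size_um, "pixel_size_um", lower = 1e-9)
  assert_scalar_number(psf_sigma_um, "psf_sigma_um", lower = 1e-9)
  assert_scalar_number(threshold, "threshold", lower = 1e-9, upper = 1)
  sig <- psf_sigma_um / pixel_size_um
  r <- max(2L, ceiling(4 * sig))
  ax <- (-r):r
  g2 <- outer(ax^2, ax^2, `+`)
  # negated LoG so bright blobs give positive peaks
  kern <- -(g2 - 2 * sig^2) / sig^4 * exp(-g2 / (2 * sig^2))
  kern <- kern - mean(kern)  # zero response on flat backgrounds
  resp <- EBImage::filter2(image, kern, boundary = "replicate")
  peak <- max(resp)
  if (!is.finite(peak) || peak <= 0) {
    return(tibble(x_um = numeric(0), y_um = numeric(0),
                  intensity = numeric(0)))
  }
  nr <- nrow(resp)
  nc <- ncol(resp)
  inner_r <- 2:(nr - 1)
  inner_c <- 2:(nc - 1)
  m <- resp[inner_r, inner_c]
  is_max <- m >= threshold * peak
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (m >= resp[inner_r + dr, inner_c + dc])
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(tibble(x_um = numeric(0), y_um = numeric(0),
                  intensity = numeric(0)))
  }
  rows <- idx[, 1] + 1L
  cols <- idx[, 2] + 1L
  # collapse plateau ties: keep one representative per 8-connected clump
  keep <- rep(TRUE, length(rows))
  if (length(rows) > 1L) {
    ord <- order(rows, cols)
    rows <- rows[ord]; cols <- cols[ord]
    for (k in 2:length(rows)) {
      close_prev <- abs(rows[1:(k - 1)] - rows[k]) <= 1 &
        abs(cols[1:(k - 1)] - cols[k]) <= 1 & keep[1:(k - 1)]
      if (any(close_prev)) keep[k] <- FALSE
    }
  }
  rows <- rows[keep]; cols <- cols[keep]
  refine <- function(rr, cc) {
    w <- pmax(resp[(rr - 1):(rr + 1), (cc - 1):(cc + 1)], 0)
    if (sum(w) == 0) w[2, 2] <- 1
    dr <- sum(w * ((-1):1)) / sum(w)        # row offset
    dc <- sum(t(w) * ((-1):1)) / sum(w)     # col offset
    c(rr + dr, cc + dc)
  }
  sub <- t(mapply(refine, rows, cols))
  out <- tibble(
    x_um = (sub[, 2] - 0.5) * pixel_size_um,
    y_um = (sub[, 1] - 0.5) * pixel_size_um,
    intensity = resp[cbind(rows, cols)]
  )
  dplyr::arrange(out, dplyr::desc(.data$intensity))
}
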