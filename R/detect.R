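#' @title Ridge enhancement and comet detection
#' @description Tools implementing the detection stage of the EB1 comet
#'   pipeline: Hessian tubeness enhancement of linear comet signals followed
#'   by local-maximum detection with subpixel refinement inside an optional
#'   region of interest.
#' @name comet_detection
NULL

# sampled Gaussian / Gaussian-derivative kernel, radius 4*sigma, normalised
# so the 0th-order kernel sums to 1 (derivative kernels inherit that scale)
gauss_kernel <- function(sigma, order = 0L) {
  r <- max(1L, ceiling(4 * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  switch(as.character(order),
         "0" = g,
         "1" = g * (-x / sigma^2),
         # re-centre so the truncated kernel sums to zero and constants map
         # to a zero response
         "2" = { k <- g * ((x^2 - sigma^2) / sigma^4); k - mean(k) },
         stop("order must be 0, 1 or 2"))
}

# reflect (mirror-with-edge-repeat) index map for padding
reflect_index <- function(i, n) {
  i[i < 1L] <- 1L - i[i < 1L]
  i[i > n] <- 2L * n + 1L - i[i > n]
  i
}

# 1-D convolution along matrix rows (dim 1) with reflect padding
conv_dim1 <- function(m, kernel) {
  n <- nrow(m)
  r <- (length(kernel) - 1L) %/% 2L
  out <- matrix(0, n, ncol(m))
  for (k in seq_along(kernel)) {
    off <- k - r - 1L
    idx <- reflect_index(seq_len(n) + off, n)
    out <- out + kernel[k] * m[idx, , drop = FALSE]
  }
  out
}

# separable convolution: kernel_row applied along rows (y), kernel_col along
# columns (x), both with reflect padding
conv_sep <- function(m, kernel_row, kernel_col) {
  t(conv_dim1(t(conv_dim1(m, kernel_row)), kernel_col))
}

#' Tubeness enhancement of linear comet signals
#'
#' Scale-space ridge filter: the image is convolved with Gaussian-derivative
#' kernels at scale `scale_px` to form the 2x2 Hessian per pixel; with
#' eigenvalues `lambda1 <= lambda2`, the bright-ridge response is
#' `scale_px^2 * max(-lambda1, 0)`. Linear comet streaks (and, more weakly,
#' isotropic spots) give positive response; flat background gives zero. The
#' operator is linear in the image up to the final clamp at zero. Reflect
#' padding is used at the borders.
#'
#' @param frame_image numeric matrix (one movie frame).
#' @param scale_px Gaussian scale sigma in pixels (> 0); match it to the PSF
#'   sigma of the comets.
#' @return Non-negative matrix of the same shape as the input.
#' @examples
#' img <- matrix(0, 32, 32); img[16, 8:24] <- 1
#' resp <- tubeness_enhance(img, 1.5)
#' @export
tubeness_enhance <- function(frame_image, scale_px) {
  if (!is.matrix(frame_image))
    stop_bad("tubeness_enhance expects a 2-D image matrix")
  stopifnot(scale_px > 0)
  g0 <- gauss_kernel(scale_px, 0L)
  g1 <- gauss_kernel(scale_px, 1L)
  g2 <- gauss_kernel(scale_px, 2L)
  m <- frame_image
  hyy <- conv_sep(m, g2, g0)   # d2/drow2
  hxx <- conv_sep(m, g0, g2)   # d2/dcol2
  hxy <- conv_sep(m, g1, g1)
  # eigenvalues of [[hxx, hxy], [hxy, hyy]]; lambda1 is the smaller
  half_tr <- (hxx + hyy) / 2
  disc <- sqrt(((hxx - hyy) / 2)^2 + hxy^2)
  lambda1 <- half_tr - disc
  scale_px^2 * pmax(-lambda1, 0)
}

#' Region-of-interest polygon
#'
#' A simple (non-self-intersecting) polygon in pixel coordinates used to
#' restrict detection to the cell interior, mirroring a manually drawn ROI.
#'
#' @param vertices two-column matrix or data frame of `(x_px, y_px)`
#'   vertices, >= 3 rows, in order.
#' @return An object of class `roi_polygon`.
#' @export
roi_polygon <- function(vertices) {
  v <- as.matrix(vertices)[, 1:2, drop = FALSE]
  storage.mode(v) <- "double"
  if (nrow(v) < 3L) stop_bad("an ROI polygon needs >= 3 vertices")
  if (polygon_self_intersects(v))
    stop_bad("ROI polygon is self-intersecting")
  structure(v, class = "roi_polygon")
}

# O(n^2) segment-pair test; adjacent edges share endpoints and are skipped
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1), ])
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      a <- seg[i, ]; b <- seg[j, ]
      d1 <- cross(a[1], a[2], a[3], a[4], b[1], b[2])
      d2 <- cross(a[1], a[2], a[3], a[4], b[3], b[4])
      d3 <- cross(b[1], b[2], b[3], b[4], a[1], a[2])
      d4 <- cross(b[1], b[2], b[3], b[4], a[3], a[4])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

roi_contains <- function(roi, x, y) {
  bnd <- rbind(unclass(roi), unclass(roi)[1, ])
  mgcv::in.out(bnd, cbind(x, y))
}

# cast an image to float in [0, 1]: integer-typed frames are divided by the
# dtype maximum, anything else by its own max when it exceeds 1
normalize_frame <- function(m, dtype = NULL) {
  m <- matrix(as.numeric(m), nrow(m), ncol(m))
  if (!is.null(dtype) && dtype == "uint8") return(m / 255)
  if (!is.null(dtype) && dtype == "uint16") return(m / 65535)
  mx <- max(m)
  if (mx > 1) m / mx else m
}

#' Detect comets in a single frame
#'
#' Pipeline: normalise intensities to `[0, 1]`, enhance with
#' [tubeness_enhance()], find 8-connected local maxima of the response above
#' `quality_threshold`, refine each to subpixel precision by an
#' intensity-weighted centroid (window minimum subtracted) in a
#' `(2*ceiling(scale_px) + 1)^2` window on the enhanced image, and drop
#' detections outside the ROI polygon. Maxima within `ceiling(scale_px)`
#' pixels of the border are suppressed. The default threshold is
#' `median(response) + 5 * mad(response)`.
#'
#' @param frame_image numeric matrix.
#' @param scale_px enhancement scale (match the comet PSF sigma).
#' @param quality_threshold minimum enhanced response at the peak; `NULL`
#'   for the median + 5 MAD default.
#' @param roi optional [roi_polygon()].
#' @param frame frame index stored in the output (default 1).
#' @return Tibble with columns `frame`, `x_px`, `y_px` (subpixel, 0-based),
#'   `quality` (response at the peak) and `raw_intensity` (original pixel
#'   value at the nearest pixel), sorted by descending quality with ties
#'   broken by (row, col).
#' @export
detect_comets <- function(frame_image, scale_px, quality_threshold = NULL,
                          roi = NULL, frame = 1L) {
  if (!is.matrix(frame_image))
    stop_bad("detect_comets expects a 2-D image matrix")
  stopifnot(is.null(quality_threshold) || quality_threshold >= 0)
  norm <- normalize_frame(frame_image)
  resp <- tubeness_enhance(norm, scale_px)
  if (is.null(quality_threshold))
    quality_threshold <- median(resp) + 5 * mad(resp)

  nr <- nrow(resp); nc <- ncol(resp)
  if (nr < 3L || nc < 3L)
    return(empty_detections())
  ctr <- resp[2:(nr - 1), 2:(nc - 1)]
  sh <- function(dr, dc) resp[2:(nr - 1) + dr, 2:(nc - 1) + dc]
  # strict > against the half-neighbourhood scanned earlier, >= against the
  # rest: picks exactly one pixel from a small plateau, deterministically
  is_max <- ctr > sh(-1, -1) & ctr > sh(-1, 0) & ctr > sh(-1, 1) &
    ctr > sh(0, -1) & ctr >= sh(0, 1) &
    ctr >= sh(1, -1) & ctr >= sh(1, 0) & ctr >= sh(1, 1) &
    ctr > quality_threshold
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty_detections())
  peak_r <- idx[, 1] + 1L  # back to full-image 1-based indices
  peak_c <- idx[, 2] + 1L

  b <- ceiling(scale_px)
  keep <- peak_r > b & peak_r <= nr - b & peak_c > b & peak_c <= nc - b
  peak_r <- peak_r[keep]; peak_c <- peak_c[keep]
  if (length(peak_r) == 0L) return(empty_detections())

  w <- ceiling(scale_px)
  off <- (-w):w
  sub <- vapply(seq_along(peak_r), function(i) {
    ri <- peak_r[i] + off; ci <- peak_c[i] + off
    win <- resp[ri, ci]
    win <- win - min(win)
    tot <- sum(win)
    if (tot <= 0) return(c(peak_c[i] - 1, peak_r[i] - 1))
    c(sum(rep(ci - 1, each = length(ri)) * win) / tot,
      sum(rep(ri - 1, times = length(ci)) * win) / tot)
  }, numeric(2))

  det <- tibble(
    frame = as.integer(frame),
    x_px = sub[1, ], y_px = sub[2, ],
    quality = resp[cbind(peak_r, peak_c)],
    raw_intensity = frame_image[cbind(peak_r, peak_c)],
    peak_row = peak_r, peak_col = peak_c)
  if (!is.null(roi)) {
    det <- det[roi_contains(roi, det$x_px, det$y_px), , drop = FALSE]
    if (nrow(det) == 0L) return(empty_detections())
  }
  det <- det[order(-det$quality, det$peak_row, det$peak_col), ]
  dplyr::select(det, -"peak_row", -"peak_col")
}

empty_detections <- function() {
  tibble(frame = integer(), x_px = numeric(), y_px = numeric(),
         quality = numeric(), raw_intensity = numeric())
}

#' Detect comets in every frame of a movie
#'
#' Applies [detect_comets()] frame by frame. When `quality_threshold` is
#' `NULL` the median + 5 MAD rule is evaluated per frame.
#'
#' @inheritParams detect_comets
#' @param movie a [movie_stack()].
#' @return Tibble of detections across frames (same columns as
#'   [detect_comets()]).
#' @export
detect_movie <- function(movie, scale_px, quality_threshold = NULL,
                         roi = NULL) {
  stopifnot(inherits(movie, "movie_stack"))
  dplyr::bind_rows(lapply(seq_len(n_frames(movie)), function(t) {
    detect_comets(movie_frame(movie, t), scale_px,
                  quality_threshold = quality_threshold,
                  roi = roi, frame = t)
  }))
}
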