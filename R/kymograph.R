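#' Reslice path for kymograph extraction
#'
#' A polyline drawn along a microtubule bundle, resampled at unit
#' arc-length steps; at each sample the intensity is averaged over
#' `width_px` bilinear samples along the local normal (the "wide" reslice
#' convention).
#'
#' @param vertices two-column matrix or data frame of `(x_px, y_px)`
#'   vertices, >= 2 rows.
#' @param width_px odd integer >= 1, lateral averaging width.
#' @param step_px arc-length sampling step in pixels (default 1).
#' @return A `reslice_path` object.
#' @export
reslice_path <- function(vertices, width_px = 3L, step_px = 1) {
  v <- as.matrix(vertices)[, 1:2, drop = FALSE]
  storage.mode(v) <- "double"
  if (nrow(v) < 2L) stop_bad("a reslice path needs >= 2 vertices")
  width_px <- as.integer(width_px)
  if (width_px < 1L || width_px %% 2L == 0L)
    stop_bad("width_px must be an odd integer >= 1")
  stopifnot(step_px > 0)
  structure(list(vertices = v, width_px = width_px, step_px = step_px),
            class = "reslice_path")
}

# bilinear interpolation of matrix m at 0-based (x=col, y=row) positions
bilinear_sample <- function(m, x, y) {
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  nr <- nrow(m); nc <- ncol(m)
  cl <- function(v, n) pmin(pmax(v, 0L), n - 1L)
  x0c <- cl(x0, nc); x1c <- cl(x0 + 1, nc)
  y0c <- cl(y0, nr); y1c <- cl(y0 + 1, nr)
  m[cbind(y0c + 1, x0c + 1)] * (1 - fx) * (1 - fy) +
    m[cbind(y0c + 1, x1c + 1)] * fx * (1 - fy) +
    m[cbind(y1c + 1, x0c + 1)] * (1 - fx) * fy +
    m[cbind(y1c + 1, x1c + 1)] * fx * fy
}

#' Reslice a movie into a kymograph
#'
#' Resamples the path at `step_px` arc-length steps (so with the default
#' step the kymograph has `floor(arc_length) + 1` columns), averages
#' `width_px` bilinear samples along the local normal at each position, and
#' stacks one row per frame: rows = time, columns = position along the
#' path. Optionally applies [tubeness_enhance()] to each frame first, the
#' background-removal order used before wide-reslice analysis.
#'
#' @param movie a [movie_stack()].
#' @param path a [reslice_path()].
#' @param stat `"mean"` (wide-reslice convention) or `"max"` across the
#'   width.
#' @param tubeness_scale if non-`NULL`, tubeness-filter every frame at this
#'   scale before reslicing.
#' @return `n_frames x n_positions` matrix of class `kymograph` with
#'   attributes `arc_length_px`, `frame_interval_s`, `pixel_size_um`.
#' @export
reslice_kymograph <- function(movie, path, stat = c("mean", "max"),
                              tubeness_scale = NULL) {
  stopifnot(inherits(movie, "movie_stack"), inherits(path, "reslice_path"))
  stat <- match.arg(stat)
  geom <- polyline_geometry(path$vertices)
  s <- seq(0, geom$total, by = path$step_px)
  at <- polyline_at(geom, s)
  ang <- deg2rad(at$ang)
  # normal in image coordinates: tangent (cos, -sin) rotated 90 degrees
  nxv <- sin(ang); nyv <- cos(ang)
  half <- (path$width_px - 1L) / 2L
  offs <- (-half):half
  X <- matrix(at$x, length(s), length(offs)) + outer(nxv, offs)
  Y <- matrix(at$y, length(s), length(offs)) + outer(nyv, offs)
  rows <- dim(movie)[1]; cols <- dim(movie)[2]
  bad <- X < 0 | X > cols - 1 | Y < 0 | Y > rows - 1
  if (any(bad)) {
    idx <- which(rowSums(bad) > 0)
    stop_bad("reslice path exits the image at arc positions: %s",
             paste(utils::head(round(s[idx], 2), 10), collapse = ", "))
  }
  nt <- n_frames(movie)
  out <- matrix(0, nt, length(s))
  for (t in seq_len(nt)) {
    fr <- movie_frame(movie, t)
    if (!is.null(tubeness_scale)) fr <- tubeness_enhance(fr, tubeness_scale)
    vals <- matrix(bilinear_sample(fr, as.vector(X), as.vector(Y)),
                   nrow = length(s))
    out[t, ] <- if (stat == "mean") rowMeans(vals) else
      apply(vals, 1, max)
  }
  structure(out,
            arc_length_px = geom$total,
            frame_interval_s = frame_interval_s(movie),
            pixel_size_um = pixel_size_um(movie),
            class = c("kymograph", "matrix"))
}

#' Fit the speed of the brightest trace in a kymograph
#'
#' Takes the per-row (per-frame) argmax position and fits position against
#' frame by least squares; the slope is the speed in pixels/frame (a
#' kymograph line of slope `1/v` frames per position unit).
#'
#' @param kymo a `kymograph`.
#' @return List with `speed_px_per_frame` and the fitted `lm` object.
#' @export
kymograph_trace_speed <- function(kymo) {
  stopifnot(inherits(kymo, "kymograph"))
  pos <- apply(unclass(kymo), 1, which.max) - 1
  t <- seq_len(nrow(kymo)) - 1
  fit <- stats::lm(pos ~ t)
  list(speed_px_per_frame = unname(stats::coef(fit)[2]), fit = fit)
}

#' Plot a kymograph
#'
#' @param object a `kymograph`.
#' @param ... unused.
#' @return A ggplot: position (px along path) on x, time (s) downward on y.
#' @export
autoplot.kymograph <- function(object, ...) {
  df <- tidyr::expand_grid(
    t = (seq_len(nrow(object)) - 1) * attr(object, "frame_interval_s"),
    s = seq_len(ncol(object)) - 1)
  df$intensity <- as.vector(t(unclass(object)))
  ggplot2::ggplot(df, ggplot2::aes(.data$s, .data$t,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "position along path (px)", y = "time (s)",
                  fill = "intensity") +
    ggplot2::theme_minimal()
}
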