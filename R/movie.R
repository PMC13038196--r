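#' Calibrated time-lapse movie stack
#'
#' Light container for a fluorescence time-lapse: a numeric `H x W x T` array
#' of pixel intensities plus the two calibration constants every downstream
#' statistic needs, the imaging scale (micrometres per pixel) and the frame
#' interval (seconds per frame).
#'
#' @param pixels numeric array with dim `c(rows, cols, frames)`, or a matrix
#'   (interpreted as a single frame).
#' @param pixel_size_um imaging scale, micrometres per pixel (> 0).
#' @param frame_interval_s frame interval, seconds per frame (> 0).
#' @param dtype storage descriptor, e.g. `"float"`, `"uint8"`, `"uint16"`;
#'   informational only, pixel values are kept as numeric.
#'
#' @return An object of class `movie_stack`: the pixel array with calibration
#'   attached as attributes.
#' @examples
#' m <- movie_stack(array(0, dim = c(16, 16, 4)),
#'                  pixel_size_um = 0.16, frame_interval_s = 1.5)
#' n_frames(m)
#' @export
movie_stack <- function(pixels, pixel_size_um, frame_interval_s,
                        dtype = "float") {
  if (is.matrix(pixels)) pixels <- array(pixels, dim = c(dim(pixels), 1L))
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    stop("`pixels` must be an H x W x T array (or a single-frame matrix)")
  if (dim(pixels)[3] < 1L) stop("a movie needs at least one frame")
  stopifnot(is.numeric(pixel_size_um), length(pixel_size_um) == 1L,
            pixel_size_um > 0,
            is.numeric(frame_interval_s), length(frame_interval_s) == 1L,
            frame_interval_s > 0)
  structure(pixels,
            pixel_size_um = pixel_size_um,
            frame_interval_s = frame_interval_s,
            dtype = dtype,
            class = "movie_stack")
}

#' @rdname movie_stack
#' @param x a `movie_stack`.
#' @export
n_frames <- function(x) dim(x)[3]

#' @rdname movie_stack
#' @export
pixel_size_um <- function(x) attr(x, "pixel_size_um")

#' @rdname movie_stack
#' @export
frame_interval_s <- function(x) attr(x, "frame_interval_s")

#' Extract one frame of a movie as a plain matrix
#' @param movie a `movie_stack`.
#' @param t frame index (1-based).
#' @return numeric matrix `rows x cols`.
#' @export
movie_frame <- function(movie, t) {
  stopifnot(t >= 1, t <= dim(movie)[3])
  unclass(movie)[, , t]
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<movie_stack> %d x %d px, %d frame(s), %.4g um/px, %.4g s/frame [%s]\n",
    d[1], d[2], d[3], attr(x, "pixel_size_um"), attr(x, "frame_interval_s"),
    attr(x, "dtype")))
  invisible(x)
}

#' Read / write a movie as a multi-page TIFF
#'
#' `write_movie_tiff()` stores one page per frame (page order is time; each
#' page is rows x cols). Pixel values are rescaled to `[0, 1]` by the stack
#' maximum before writing (16-bit output), so absolute intensity scale is not
#' preserved on disk -- downstream detection normalises intensities anyway.
#' `read_movie_tiff()` re-attaches calibration, which TIFF does not carry.
#'
#' @param movie a `movie_stack`.
#' @param path file path.
#' @param bits_per_sample 8 or 16.
#' @return `write_movie_tiff()` returns `path` invisibly; `read_movie_tiff()`
#'   returns a `movie_stack`.
#' @export
write_movie_tiff <- function(movie, path, bits_per_sample = 16L) {
  px <- unclass(movie)
  mx <- max(px)
  if (mx > 0) px <- px / mx
  px[px < 0] <- 0
  pages <- lapply(seq_len(dim(px)[3]), function(t) px[, , t])
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits_per_sample))
  invisible(path)
}

#' @rdname write_movie_tiff
#' @param pixel_size_um,frame_interval_s calibration to attach on read.
#' @export
read_movie_tiff <- function(path, pixel_size_um, frame_interval_s) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  px <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  movie_stack(px, pixel_size_um, frame_interval_s, dtype = "float")
}
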