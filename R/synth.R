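#' Simulation configuration for synthetic EB1 comet movies
#'
#' Defines the ground-truth comet process and the forward imaging model used
#' to emulate the two microtubule growth regimes seen in differentiating
#' alveolar epithelial cultures: early cells show unidirectional plus-end
#' growth along radial spokes from the cell centre to the cortex
#' (`"unidirectional_radial"`), late cells show bidirectional growth along
#' bundled tracks with 50/50 polarity (`"bidirectional_bundled"`).
#'
#' Comets are born by a Poisson process (`birth_rate_per_frame`), live for a
#' geometric (memoryless) number of frames with the stated mean, and advance
#' a fixed step of `comet_speed_um_s * frame_interval_s / pixel_size_um`
#' pixels per frame. Heading noise is a wrapped Gaussian applied to the step
#' direction only; speed is never rescaled. Comets leaving the field of view
#' (or, in bundled mode, running off their polyline) terminate.
#'
#' @param image_shape `c(rows, cols)` in pixels.
#' @param n_frames number of frames (>= 2).
#' @param frame_interval_s seconds per frame; default 1.5 s, a typical
#'   EB1-EGFP live-imaging interval.
#' @param pixel_size_um micrometres per pixel. Required: no default.
#' @param mode `"unidirectional_radial"` or `"bidirectional_bundled"`.
#' @param bundle_skeleton bundled mode only: list of polylines, each a
#'   two-column matrix of `(x_px, y_px)` vertices.
#' @param comet_speed_um_s comet growth speed, um/s.
#' @param angular_noise_deg SD of the wrapped-Gaussian per-step heading
#'   noise, degrees.
#' @param birth_rate_per_frame expected new comets per frame.
#' @param mean_lifetime_frames mean comet lifetime in frames.
#' @param psf_sigma_px SD of the isotropic Gaussian PSF, pixels.
#' @param amplitude peak intensity of one comet (photon counts).
#' @param background constant background offset.
#' @param noise_model `"none"`, `"gaussian"` or `"poisson"`.
#' @param noise_sd Gaussian read-noise SD (required for `"gaussian"`).
#' @param seed integer RNG seed; a fixed seed fixes trajectories and rendered
#'   movie bit-for-bit.
#' @return A `sim_config` list.
#' @examples
#' cfg <- sim_config(pixel_size_um = 0.16, seed = 1)
#' @export
sim_config <- function(image_shape = c(128L, 128L),
                       n_frames = 60L,
                       frame_interval_s = 1.5,
                       pixel_size_um,
                       mode = c("unidirectional_radial",
                                "bidirectional_bundled"),
                       bundle_skeleton = NULL,
                       comet_speed_um_s = 0.15,
                       angular_noise_deg = 10,
                       birth_rate_per_frame = 2,
                       mean_lifetime_frames = 12,
                       psf_sigma_px = 1.5,
                       amplitude = 100,
                       background = 10,
                       noise_model = c("poisson", "gaussian", "none"),
                       noise_sd = NULL,
                       seed = 1L) {
  mode <- match.arg(mode)
  noise_model <- match.arg(noise_model)
  if (missing(pixel_size_um)) stop_bad("`pixel_size_um` is required")
  stopifnot(length(image_shape) == 2L, all(image_shape >= 8),
            n_frames >= 2L,
            frame_interval_s > 0, pixel_size_um > 0,
            comet_speed_um_s > 0, angular_noise_deg >= 0,
            birth_rate_per_frame >= 0, mean_lifetime_frames >= 1,
            psf_sigma_px > 0, amplitude > 0, background >= 0)
  if (mode == "bidirectional_bundled") {
    if (is.null(bundle_skeleton) || length(bundle_skeleton) < 1L)
      stop_bad("bidirectional_bundled mode requires a bundle_skeleton with >= 1 polyline")
    for (p in bundle_skeleton)
      if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 2L)
        stop_bad("each bundle polyline must be a matrix of >= 2 (x, y) vertices")
  }
  if (noise_model == "gaussian" &&
      (is.null(noise_sd) || noise_sd <= 0))
    stop_bad("gaussian noise_model requires noise_sd > 0")
  structure(list(
    image_shape = as.integer(image_shape), n_frames = as.integer(n_frames),
    frame_interval_s = frame_interval_s, pixel_size_um = pixel_size_um,
    mode = mode, bundle_skeleton = bundle_skeleton,
    comet_speed_um_s = comet_speed_um_s,
    angular_noise_deg = angular_noise_deg,
    birth_rate_per_frame = birth_rate_per_frame,
    mean_lifetime_frames = mean_lifetime_frames,
    psf_sigma_px = psf_sigma_px, amplitude = amplitude,
    background = background, noise_model = noise_model, noise_sd = noise_sd,
    seed = as.integer(seed)), class = "sim_config")
}

#' Nominal per-frame step length of a configuration, in pixels
#' @param config a `sim_config`.
#' @export
step_length_px <- function(config) {
  config$comet_speed_um_s * config$frame_interval_s / config$pixel_size_um
}

#' Gently curved near-parallel bundle polylines spanning the field
#'
#' Convenience skeleton for the bidirectional-bundled regime: `n_bundles`
#' left-to-right polylines with a shallow sinusoidal bow, evenly spaced in
#' the row direction with a margin.
#'
#' @param image_shape `c(rows, cols)`.
#' @param n_bundles number of polylines.
#' @param bow peak vertical deflection in pixels.
#' @param margin_frac fraction of the image kept clear at each edge.
#' @return list of two-column `(x, y)` vertex matrices.
#' @export
default_bundle_skeleton <- function(image_shape, n_bundles = 4,
                                    bow = 4, margin_frac = 0.12) {
  rows <- image_shape[1]; cols <- image_shape[2]
  margin <- margin_frac * min(rows, cols)
  ys <- seq(margin, rows - 1 - margin, length.out = n_bundles)
  xs <- seq(margin, cols - 1 - margin, length.out = 24)
  lapply(seq_along(ys), function(i) {
    phase <- 2 * pi * (i - 1) / max(1, n_bundles)
    cbind(x = xs,
          y = ys[i] + bow * sin(2 * pi * (xs - xs[1]) /
                                  (xs[length(xs)] - xs[1]) + phase))
  })
}

# cumulative arc-length parameterisation of one polyline
polyline_geometry <- function(p) {
  seg <- diff(p)
  len <- sqrt(rowSums(seg^2))
  if (any(len == 0)) {
    keep <- len > 0
    seg <- seg[keep, , drop = FALSE]; len <- len[keep]
  }
  list(verts = p, seg = seg, len = len,
       cum = c(0, cumsum(len)), total = sum(len),
       ang = rad2deg(atan2(-seg[, 2], seg[, 1])))
}

# point and tangent angle (deg, math convention) at arc position s
polyline_at <- function(geom, s) {
  s <- pmin(pmax(s, 0), geom$total)
  i <- findInterval(s, geom$cum, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(geom$len))
  f <- (s - geom$cum[i]) / geom$len[i]
  list(x = geom$verts[i, 1] + f * geom$seg[i, 1],
       y = geom$verts[i, 2] + f * geom$seg[i, 2],
       ang = geom$ang[i])
}

in_bounds <- function(x, y, image_shape) {
  x >= 0 & x <= image_shape[2] - 1 & y >= 0 & y <= image_shape[1] - 1
}

#' Simulate ground-truth comet trajectories
#'
#' Draws comet births, lifetimes and stepwise motion under the configured
#' growth regime. In the radial regime each comet's base heading points from
#' the image centre outward along its spawn spoke; in the bundled regime each
#' comet follows its assigned polyline with polarity +1 or -1 chosen with
#' equal probability. Per-step headings are the base/tangent heading plus
#' independent wrapped-Gaussian noise.
#'
#' @param config a [sim_config()].
#' @return A tibble of class `comet_trajectories` with one row per comet per
#'   frame: `track_id`, `frame` (1-based), `x_px`, `y_px` (0-based pixel
#'   coordinates, x = column), `polarity` (+1/-1; NA in radial mode) and
#'   `base_angle_deg` (spawn spoke / local tangent heading). The generating
#'   `sim_config` is attached as attribute `config`.
#' @examples
#' tr <- simulate_trajectories(sim_config(pixel_size_um = 0.16, seed = 7))
#' dplyr::count(tr, track_id)
#' @export
simulate_trajectories <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  shape <- config$image_shape
  step <- step_length_px(config)
  sigma <- deg2rad(config$angular_noise_deg)
  bundled <- config$mode == "bidirectional_bundled"
  geoms <- if (bundled) lapply(config$bundle_skeleton, polyline_geometry)
  glens <- if (bundled) vapply(geoms, `[[`, numeric(1), "total")

  births <- rpois(config$n_frames, config$birth_rate_per_frame)
  out <- vector("list", sum(births))
  id <- 0L
  cx <- (shape[2] - 1) / 2; cy <- (shape[1] - 1) / 2
  for (f0 in seq_len(config$n_frames)) {
    for (b in seq_len(births[f0])) {
      id <- id + 1L
      life <- rgeom(1, 1 / config$mean_lifetime_frames) + 1L
      n_pos <- min(life, config$n_frames - f0 + 1L)
      noise <- if (n_pos > 1L) rnorm(n_pos - 1L, 0, sigma) else numeric(0)
      if (!bundled) {
        spoke <- runif(1, 0, 360)
        r0 <- runif(1, 2, 0.35 * min(shape))
        x <- cx + r0 * cos(deg2rad(spoke))
        y <- cy - r0 * sin(deg2rad(spoke))
        ang <- deg2rad(spoke) + noise
        xs <- x + c(0, cumsum(step * cos(ang)))
        ys <- y - c(0, cumsum(step * sin(ang)))
        polarity <- NA_integer_
        base <- rep(spoke, n_pos)
      } else {
        gi <- sample.int(length(geoms), 1, prob = glens)
        g <- geoms[[gi]]
        polarity <- if (runif(1) < 0.5) 1L else -1L
        s0 <- runif(1, 0, g$total)
        ss <- s0 + polarity * step * (0:(n_pos - 1L))
        ok_arc <- ss >= 0 & ss <= g$total
        n_arc <- if (all(ok_arc)) n_pos else which(!ok_arc)[1] - 1L
        if (n_arc < 1L) next
        ss <- ss[seq_len(n_arc)]
        at <- polyline_at(g, ss)
        tang <- deg2rad((at$ang + if (polarity > 0) 0 else 180) %% 360)
        # step directions: local tangent heading plus noise, free 2-D motion
        ang <- if (n_arc > 1L) tang[seq_len(n_arc - 1L)] + noise[seq_len(n_arc - 1L)]
               else numeric(0)
        xs <- at$x[1] + c(0, cumsum(step * cos(ang)))
        ys <- at$y[1] - c(0, cumsum(step * sin(ang)))
        base <- rad2deg(tang) %% 360
        n_pos <- n_arc
      }
      inb <- in_bounds(xs, ys, shape)
      n_keep <- if (all(inb)) n_pos else which(!inb)[1] - 1L
      if (n_keep < 1L) next
      out[[id]] <- tibble(
        track_id = id,
        frame = f0 + 0:(n_keep - 1L),
        x_px = xs[seq_len(n_keep)], y_px = ys[seq_len(n_keep)],
        polarity = rep(polarity, n_keep)[seq_len(n_keep)],
        base_angle_deg = rep(base, length.out = n_pos)[seq_len(n_keep)])
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  res <- if (length(out)) dplyr::bind_rows(out) else
    tibble(track_id = integer(), frame = integer(), x_px = numeric(),
           y_px = numeric(), polarity = integer(), base_angle_deg = numeric())
  # renumber so ids are dense and ordered by birth
  res$track_id <- match(res$track_id, unique(res$track_id))
  attr(res, "config") <- config
  class(res) <- c("comet_trajectories", class(res))
  res
}

#' Render trajectories into a noisy fluorescence movie
#'
#' Forward imaging model: each comet alive in a frame contributes an
#' isotropic 2-D Gaussian of SD `psf_sigma_px` with peak `amplitude` at its
#' subpixel position; a constant background is added, then shot/read noise
#' per `noise_model`. Rendering consumes its own RNG stream derived from the
#' config seed, so trajectories and rendering are jointly reproducible.
#'
#' @param traj a `comet_trajectories` tibble (or any tibble with columns
#'   `frame`, `x_px`, `y_px`).
#' @param config the [sim_config()] used (defaults to the one attached to
#'   `traj`).
#' @return A [movie_stack()].
#' @export
render_movie <- function(traj, config = attr(traj, "config")) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 1L))
  rows <- config$image_shape[1]; cols <- config$image_shape[2]
  px <- array(config$background,
              dim = c(rows, cols, config$n_frames))
  s <- config$psf_sigma_px
  r <- ceiling(4 * s)
  if (nrow(traj) > 0) {
    for (k in seq_len(nrow(traj))) {
      t <- traj$frame[k]
      x0 <- traj$x_px[k]; y0 <- traj$y_px[k]
      ci <- max(0, floor(x0) - r):min(cols - 1, ceiling(x0) + r)
      ri <- max(0, floor(y0) - r):min(rows - 1, ceiling(y0) + r)
      g <- config$amplitude *
        outer(exp(-(ri - y0)^2 / (2 * s^2)), exp(-(ci - x0)^2 / (2 * s^2)))
      px[ri + 1, ci + 1, t] <- px[ri + 1, ci + 1, t] + g
    }
  }
  if (config$noise_model == "gaussian") {
    px <- px + array(rnorm(length(px), 0, config$noise_sd), dim = dim(px))
  } else if (config$noise_model == "poisson") {
    px <- array(rpois(length(px), pmax(px, 0)), dim = dim(px))
  }
  movie_stack(px, config$pixel_size_um, config$frame_interval_s)
}

#' Write ground-truth trajectories as CSV
#'
#' Columns: `track_id, frame, x_px, y_px, polarity`. Floating point values
#' are written with 6 significant digits.
#' @param traj a `comet_trajectories` tibble.
#' @param path output path.
#' @export
write_trajectories_csv <- function(traj, path) {
  out <- dplyr::mutate(
    dplyr::select(as_tibble(traj), "track_id", "frame", "x_px", "y_px",
                  "polarity"),
    dplyr::across(c("x_px", "y_px"), ~ signif(.x, 6)))
  readr::write_csv(out, path)
  invisible(path)
}
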