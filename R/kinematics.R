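#' Imaging calibration
#'
#' @param pixel_size_um micrometres per pixel (> 0).
#' @param frame_interval_s seconds per frame (> 0).
#' @return A `calibration` list.
#' @export
calibration <- function(pixel_size_um, frame_interval_s) {
  stopifnot(pixel_size_um > 0, frame_interval_s > 0)
  structure(list(pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s),
            class = "calibration")
}

one_track <- function(track) {
  tr <- as_tibble(track)
  if ("track_id" %in% names(tr) && dplyr::n_distinct(tr$track_id) > 1L)
    stop_bad("expected a single track; got %d track_ids",
             dplyr::n_distinct(tr$track_id))
  if (!all(c("frame", "x_px", "y_px") %in% names(tr)))
    stop_bad("a track needs columns frame, x_px, y_px")
  tr[order(tr$frame), ]
}

#' Comet track velocity (um/min)
#'
#' Velocity is the total XY path length divided by the track duration, with
#' both calibrated: path in micrometres via `pixel_size_um`, duration in
#' minutes via `frame_interval_s`. This is the mean instantaneous speed and
#' is robust to direction reversals; the net-displacement variant is
#' available from [track_kinematics()] as `velocity_net_um_min`.
#'
#' @param track tibble with `frame`, `x_px`, `y_px` for one track (>= 2
#'   detections).
#' @param calib a [calibration()].
#' @return velocity in um/min.
#' @examples
#' tr <- tibble::tibble(frame = 1:2, x_px = c(0, 3), y_px = c(0, -4))
#' track_velocity(tr, calibration(0.1, 1.5))  # 20 um/min
#' @export
track_velocity <- function(track, calib) {
  tr <- one_track(track)
  if (nrow(tr) < 2L) stop_bad("velocity is undefined for a single detection")
  path_um <- sum(sqrt(diff(tr$x_px)^2 + diff(tr$y_px)^2)) *
    calib$pixel_size_um
  dur_min <- (max(tr$frame) - min(tr$frame)) * calib$frame_interval_s / 60
  path_um / dur_min
}

#' Net movement angle of a track (degrees)
#'
#' Angle of the start-to-end displacement vector, counterclockwise from +x
#' with the image row axis negated (so "up" in the image is 90 degrees),
#' mapped to `[0, 360)`.
#'
#' @inheritParams track_velocity
#' @return angle in degrees; error if the net displacement is zero (such
#'   tracks are excluded from directionality concentration).
#' @export
movement_angle <- function(track) {
  tr <- one_track(track)
  if (nrow(tr) < 2L) stop_bad("movement angle needs >= 2 detections")
  dx <- tr$x_px[nrow(tr)] - tr$x_px[1]
  dy <- tr$y_px[nrow(tr)] - tr$y_px[1]
  if (dx == 0 && dy == 0)
    stop_bad("movement angle is undefined for zero net displacement")
  heading_deg(dx, dy)
}

step_headings_deg <- function(tr) {
  dx <- diff(tr$x_px); dy <- diff(tr$y_px)
  keep <- !(dx == 0 & dy == 0)
  heading_deg(dx[keep], dy[keep])
}

#' Angle fluctuation of a track (degrees)
#'
#' Standard deviation of the frame-to-frame directional changes along a
#' track. Each change is the difference between consecutive step headings
#' wrapped into `(-180, 180]` (so 170 degrees followed by -170 degrees is a
#' +20 degree change, not -340). The sample SD (denominator n-1) is the
#' default; `population = TRUE` uses n.
#'
#' @inheritParams track_velocity
#' @param population use the population (n) denominator.
#' @return SD of direction changes in degrees; `NA` if the track has fewer
#'   than 3 steps (fewer than 2 direction changes).
#' @export
angle_fluctuation <- function(track, population = FALSE) {
  tr <- one_track(track)
  h <- step_headings_deg(tr)
  if (length(h) < 3L) return(NA_real_)
  d <- wrap_angle_deg(diff(h))
  if (population) sqrt(mean((d - mean(d))^2)) else sd(d)
}

#' Track straightness
#'
#' Net start-to-end displacement divided by total path length; 1 for
#' perfectly straight co-directed motion, 0 for a track returning to its
#' start. Dimensionless and invariant to uniform spatial scaling.
#'
#' @inheritParams track_velocity
#' @return straightness in `[0, 1]`.
#' @export
track_straightness <- function(track) {
  tr <- one_track(track)
  if (nrow(tr) < 2L) stop_bad("straightness needs >= 2 detections")
  path <- sum(sqrt(diff(tr$x_px)^2 + diff(tr$y_px)^2))
  if (path == 0) stop_bad("straightness is undefined for zero path length")
  net <- sqrt((tr$x_px[nrow(tr)] - tr$x_px[1])^2 +
                (tr$y_px[nrow(tr)] - tr$y_px[1])^2)
  net / path
}

#' Directionality concentration (mean resultant length)
#'
#' Circular-statistics measure of how coherently a set of movement angles
#' points in one direction: the length of the mean unit vector,
#' `R = ||(1/n) * sum(cos, sin)||`, in `[0, 1]`. All angles equal gives 1;
#' a balanced bidirectional set (angles theta and theta + 180 in equal
#' measure) gives 0.
#'
#' @param angles_deg numeric vector of angles in degrees (>= 1).
#' @return `R` in `[0, 1]`.
#' @examples
#' directionality_concentration(c(0, 90))  # sqrt(2)/2
#' @export
directionality_concentration <- function(angles_deg) {
  if (length(angles_deg) < 1L || !is.numeric(angles_deg))
    stop_bad("directionality concentration needs >= 1 angle")
  th <- deg2rad(angles_deg)
  sqrt(mean(cos(th))^2 + mean(sin(th))^2)
}

#' Per-track kinematics table
#'
#' Computes the four calibrated statistics for every track in a tidy track
#' table: velocity (um/min, path-based, with the net-displacement variant as
#' an auxiliary column), net movement angle (degrees), angle fluctuation
#' (degrees; `NA` below 3 steps) and straightness.
#'
#' @param tracks tibble with `track_id`, `frame`, `x_px`, `y_px`.
#' @param calib a [calibration()].
#' @param population_sd use the population denominator for angle
#'   fluctuation.
#' @return Tibble with one row per track: `track_id`, `n_steps`,
#'   `velocity_um_min`, `velocity_net_um_min`, `movement_angle_deg` (`NA`
#'   for zero net displacement), `angle_fluctuation_deg`, `straightness`,
#'   and `track_dc`, the per-track directionality concentration (mean
#'   resultant length of the track's own step headings) -- the
#'   track-level coherence measure used when contrasting conditions, since
#'   the movie-level DC pools net angles that are uniform by construction
#'   in a radial growth field.
#' @export
track_kinematics <- function(tracks, calib, population_sd = FALSE) {
  stopifnot(inherits(calib, "calibration"))
  tr <- as_tibble(tracks)
  if (!all(c("track_id", "frame", "x_px", "y_px") %in% names(tr)))
    stop_bad("tracks need columns track_id, frame, x_px, y_px")
  tr <- tr[order(tr$track_id, tr$frame), ]
  px <- calib$pixel_size_um
  dt_min <- calib$frame_interval_s / 60
  dplyr::reframe(dplyr::group_by(tr, .data$track_id), {
    n <- dplyr::n()
    if (n < 2L) {
      tibble(n_steps = 0L, velocity_um_min = NA_real_,
             velocity_net_um_min = NA_real_,
             movement_angle_deg = NA_real_,
             angle_fluctuation_deg = NA_real_, straightness = NA_real_,
             track_dc = NA_real_)
    } else {
      dx <- diff(.data$x_px); dy <- diff(.data$y_px)
      steps <- sqrt(dx^2 + dy^2)
      path <- sum(steps)
      netx <- sum(dx); nety <- sum(dy)
      net <- sqrt(netx^2 + nety^2)
      dur <- (max(.data$frame) - min(.data$frame)) * dt_min
      keep <- steps > 0
      h <- heading_deg(dx[keep], dy[keep])
      fluct <- if (length(h) >= 3L) {
        d <- wrap_angle_deg(diff(h))
        if (population_sd) sqrt(mean((d - mean(d))^2)) else sd(d)
      } else NA_real_
      tibble(n_steps = n - 1L,
             velocity_um_min = path * px / dur,
             velocity_net_um_min = net * px / dur,
             movement_angle_deg =
               if (net > 0) heading_deg(netx, nety) else NA_real_,
             angle_fluctuation_deg = fluct,
             straightness = if (path > 0) net / path else NA_real_,
             track_dc = if (length(h) >= 2L)
               directionality_concentration(h) else NA_real_)
    }
  })
}

#' Per-movie summary of comet kinematics
#'
#' Computes [track_kinematics()] per track, excludes tracks with fewer than
#' `min_steps` steps (counting them), then aggregates: mean velocity, angle
#' fluctuation and straightness over usable tracks, and directionality
#' concentration over the per-track net movement angles (or over all step
#' headings pooled, with `per_step = TRUE`).
#'
#' @inheritParams track_kinematics
#' @param min_steps minimum steps for a track to enter the summary
#'   (default 3, the minimum for angle fluctuation).
#' @param per_step compute DC over pooled step headings instead of
#'   per-track net movement angles.
#' @return One-row tibble of class `movie_summary` with columns
#'   `n_tracks_used`, `n_tracks_excluded`, `mean_velocity_um_min`,
#'   `directionality_concentration` (over pooled net movement angles, or
#'   pooled step headings with `per_step = TRUE`), `mean_track_dc` (mean of
#'   the per-track step-heading resultant lengths),
#'   `mean_angle_fluctuation_deg`, `mean_straightness`; the per-track table
#'   is attached as attribute `per_track` (see [tidy.movie_summary()]).
#' @export
summarize_movie <- function(tracks, calib, min_steps = 3L,
                            per_step = FALSE, population_sd = FALSE) {
  kin <- track_kinematics(tracks, calib, population_sd = population_sd)
  usable <- kin[!is.na(kin$n_steps) & kin$n_steps >= min_steps, ]
  if (nrow(usable) == 0L)
    stop_bad("zero usable tracks (all %d below min_steps = %d)",
             nrow(kin), min_steps)
  dc <- if (per_step) {
    tr <- as_tibble(tracks)
    tr <- tr[tr$track_id %in% usable$track_id, ]
    tr <- tr[order(tr$track_id, tr$frame), ]
    h <- unlist(lapply(split(tr, tr$track_id), step_headings_deg),
                use.names = FALSE)
    directionality_concentration(h)
  } else {
    ang <- usable$movement_angle_deg[!is.na(usable$movement_angle_deg)]
    directionality_concentration(ang)
  }
  out <- tibble(
    n_tracks_used = nrow(usable),
    n_tracks_excluded = nrow(kin) - nrow(usable),
    mean_velocity_um_min = mean(usable$velocity_um_min),
    directionality_concentration = dc,
    mean_track_dc = mean(usable$track_dc, na.rm = TRUE),
    mean_angle_fluctuation_deg =
      mean(usable$angle_fluctuation_deg, na.rm = TRUE),
    mean_straightness = mean(usable$straightness))
  attr(out, "per_track") <- usable
  class(out) <- c("movie_summary", class(out))
  out
}

#' Tidy / glance methods for movie summaries
#'
#' `tidy()` returns the per-track kinematics behind a summary; `glance()`
#' returns the one-row movie-level summary as a plain tibble.
#'
#' @param x a `movie_summary`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.movie_summary <- function(x, ...) as_tibble(attr(x, "per_track"))

#' @rdname tidy.movie_summary
#' @export
glance.movie_summary <- function(x, ...) {
  out <- x
  attr(out, "per_track") <- NULL
  class(out) <- setdiff(class(out), "movie_summary")
  as_tibble(out)
}
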