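#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median mad quantile rnorm rpois rgeom runif sd
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# wrap angle differences (degrees) into (-180, 180], boundary mapped to +180
wrap_angle_deg <- function(d) {
  w <- d %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

# movement angles follow the counterclockwise-from-+x math convention with
# image row axis negated (x = column, y = row, origin top-left)
heading_deg <- function(dx, drow) rad2deg(atan2(-drow, dx)) %% 360

# deterministic child-stream seed; keeps derived seeds inside 32-bit range
child_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647
}

stop_bad <- function(...) stop(sprintf(...), call. = FALSE)
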