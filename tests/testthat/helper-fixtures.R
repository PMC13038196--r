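# Fixture builders shared across test files. All data are generated in
# code; nothing is read from disk. The default acquisition mirrors the
# study conditions: 1.5 s frame interval; 0.16 um/px stands in for the
# unreported pixel size.

fixture_calib <- function() calibration(pixel_size_um = 0.16,
                                        frame_interval_s = 1.5)

radial_config <- function(seed = 1, ...) {
  args <- list(
    image_shape = c(96L, 96L), n_frames = 40L, frame_interval_s = 1.5,
    pixel_size_um = 0.16, mode = "unidirectional_radial",
    comet_speed_um_s = 0.15, angular_noise_deg = 10,
    birth_rate_per_frame = 1.5, mean_lifetime_frames = 12,
    psf_sigma_px = 1.5, amplitude = 100, background = 10,
    noise_model = "gaussian", noise_sd = 3, seed = seed)
  over <- list(...)
  args[names(over)] <- over   # plain replacement, no recursive list merge
  do.call(sim_config, args)
}

bundled_config <- function(seed = 2, shape = c(96L, 96L), ...) {
  args <- list(
    image_shape = shape, n_frames = 40L, frame_interval_s = 1.5,
    pixel_size_um = 0.16, mode = "bidirectional_bundled",
    bundle_skeleton = default_bundle_skeleton(shape, n_bundles = 3),
    comet_speed_um_s = 0.20, angular_noise_deg = 25,
    birth_rate_per_frame = 1.5, mean_lifetime_frames = 12,
    psf_sigma_px = 1.5, amplitude = 100, background = 10,
    noise_model = "gaussian", noise_sd = 3, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# render a single frame holding isolated Gaussian spots at given subpixel
# positions; peak-amplitude-to-noise-SD ratio `snr` (0 = noiseless)
render_spots_frame <- function(positions, shape = c(64L, 64L),
                               sigma = 1.5, amplitude = 100,
                               background = 10, snr = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  img <- matrix(background, shape[1], shape[2])
  for (k in seq_len(nrow(positions))) {
    x0 <- positions[k, 1]; y0 <- positions[k, 2]
    cs <- 0:(shape[2] - 1); rs <- 0:(shape[1] - 1)
    img <- img + amplitude *
      outer(exp(-(rs - y0)^2 / (2 * sigma^2)),
            exp(-(cs - x0)^2 / (2 * sigma^2)))
  }
  if (snr > 0)
    img <- img + matrix(rnorm(length(img), 0, amplitude / snr),
                        shape[1], shape[2])
  img
}

# straight-line synthetic track table
straight_track <- function(n = 6, step = 2, angle_deg = 0, id = 1L) {
  th <- angle_deg * pi / 180
  tibble::tibble(track_id = id, frame = seq_len(n),
                 x_px = 10 + (seq_len(n) - 1) * step * cos(th),
                 y_px = 10 - (seq_len(n) - 1) * step * sin(th))
}

# minimal bedGraph / BED writers for parser tests
write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

random_signal_tibble <- function(n, chroms = c("chr1", "chr2"),
                                 max_pos = 5000) {
  start <- sample.int(max_pos, n, replace = TRUE)
  width <- sample.int(80, n, replace = TRUE)
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = start, end = start + width,
                 value = round(rexp(n, 1 / 3), 3))
}
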