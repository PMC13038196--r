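#' Two-condition pipeline configuration
#'
#' Bundles everything one run needs: a named list of per-condition inputs
#' (each either a [sim_config()] to simulate or a path to a real TIFF movie
#' plus calibration), the detection/linking/kinematics parameter blocks and
#' a master seed. Per-condition child seeds are derived deterministically
#' from `(seed, condition index)`, so adding a condition does not reshuffle
#' the others.
#'
#' @param conditions named list; each element is either a `sim_config` or a
#'   list `list(movie = "path.tif", pixel_size_um = , frame_interval_s = )`.
#' @param detection list: `scale_px` (default `NULL` = the condition's
#'   `psf_sigma_px`), `quality_threshold` (default `NULL` = median + 5 MAD).
#' @param linking a [linking_params()].
#' @param kinematics list: `min_steps` (default 3), `per_step`,
#'   `population_sd`.
#' @param seed master integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(conditions,
                            detection = list(scale_px = NULL,
                                             quality_threshold = NULL),
                            linking = linking_params(max_link_dist_px = 6),
                            kinematics = list(min_steps = 3L,
                                              per_step = FALSE,
                                              population_sd = FALSE),
                            seed = 1L) {
  stopifnot(is.list(conditions), length(conditions) >= 1L,
            !is.null(names(conditions)), all(nzchar(names(conditions))))
  for (nm in names(conditions)) {
    cond <- conditions[[nm]]
    ok_sim <- inherits(cond, "sim_config")
    ok_real <- is.list(cond) && !is.null(cond$movie) &&
      !is.null(cond$pixel_size_um) && !is.null(cond$frame_interval_s)
    if (!xor(ok_sim, ok_real))
      stop_bad("condition '%s' must be exactly one of: a sim_config, or a real-movie spec", nm)
  }
  kin <- utils::modifyList(list(min_steps = 3L, per_step = FALSE,
                                population_sd = FALSE), kinematics)
  det <- utils::modifyList(list(scale_px = NULL, quality_threshold = NULL),
                           detection)
  structure(list(conditions = conditions, detection = det,
                 linking = linking, kinematics = kin,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Run the full comet-kinematics pipeline
#'
#' For each condition: simulate (or load) the movie, detect comets, link
#' tracks, compute per-track kinematics and the movie summary; then compare
#' every pair of conditions on the four statistics (velocity, per-track
#' directionality concentration, angle fluctuation, straightness) with the
#' normality-gated two-group protocol. All stage
#' artifacts are written under `out_dir` (TIFF movie, detections /
#' tracks / kinematics CSVs with 6 significant digits, JSON summaries) and
#' a manifest records package version, seed, parameters, per-file MD5
#' hashes and the stage outcome. Any stage error aborts the run with the
#' stage name; the manifest (written before rethrowing) records the
#' failure.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return The manifest, invisibly, as a list. Comparison results are in
#'   `manifest$comparisons` and per-condition summaries in
#'   `manifest$summaries`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "cometkin",
    version = as.character(utils::packageVersion("cometkin")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    parameters = list(
      detection = config$detection,
      linking = unclass(config$linking),
      kinematics = config$kinematics),
    status = "running", failed_stage = NULL, conditions = list())
  stage <- "setup"
  kin_tables <- list()
  summaries <- list()
  result <- tryCatch({
    for (ci in seq_along(config$conditions)) {
      nm <- names(config$conditions)[ci]
      cond <- config$conditions[[ci]]
      prefix <- file.path(out_dir, nm)
      files <- list()

      stage <- paste0(nm, "/simulate")
      if (inherits(cond, "sim_config")) {
        cond$seed <- as.integer(child_seed(config$seed, ci))
        traj <- simulate_trajectories(cond)
        movie <- render_movie(traj, cond)
        scale_px <- config$detection$scale_px %||% cond$psf_sigma_px
        write_trajectories_csv(traj, paste0(prefix, "_truth.csv"))
        write_movie_tiff(movie, paste0(prefix, "_movie.tif"))
        files <- c(files, truth = paste0(prefix, "_truth.csv"),
                   movie = paste0(prefix, "_movie.tif"))
      } else {
        movie <- read_movie_tiff(cond$movie, cond$pixel_size_um,
                                 cond$frame_interval_s)
        scale_px <- config$detection$scale_px %||%
          stop_bad("detection$scale_px is required for real movies")
      }

      stage <- paste0(nm, "/detect")
      det <- detect_movie(movie, scale_px,
                          quality_threshold = config$detection$quality_threshold)
      readr::write_csv(
        dplyr::mutate(det, dplyr::across(dplyr::where(is.double),
                                         ~ signif(.x, 6))),
        paste0(prefix, "_detections.csv"))
      files <- c(files, detections = paste0(prefix, "_detections.csv"))

      stage <- paste0(nm, "/track")
      tracks <- link_tracks(det, config$linking)
      readr::write_csv(
        dplyr::mutate(tracks, dplyr::across(dplyr::where(is.double),
                                            ~ signif(.x, 6))),
        paste0(prefix, "_tracks.csv"))
      files <- c(files, tracks = paste0(prefix, "_tracks.csv"))

      stage <- paste0(nm, "/kinematics")
      calib <- calibration(pixel_size_um(movie), frame_interval_s(movie))
      summ <- summarize_movie(tracks, calib,
                              min_steps = config$kinematics$min_steps,
                              per_step = config$kinematics$per_step,
                              population_sd = config$kinematics$population_sd)
      kin <- tidy.movie_summary(summ)
      readr::write_csv(
        dplyr::mutate(kin, dplyr::across(dplyr::where(is.double),
                                         ~ signif(.x, 6))),
        paste0(prefix, "_kinematics.csv"))
      write_json_file(as.list(glance.movie_summary(summ)),
                      paste0(prefix, "_summary.json"))
      files <- c(files, kinematics = paste0(prefix, "_kinematics.csv"),
                 summary = paste0(prefix, "_summary.json"))

      kin_tables[[nm]] <- kin
      summaries[[nm]] <- glance.movie_summary(summ)
      manifest$conditions[[nm]] <- list(
        n_detections = nrow(det),
        n_tracks = dplyr::n_distinct(tracks$track_id),
        n_tracks_dropped = attr(tracks, "n_dropped"),
        files = lapply(files, basename))
    }

    stage <- "compare"
    comparisons <- list()
    nms <- names(config$conditions)
    stats_cols <- c(velocity = "velocity_um_min",
                    directionality_concentration = "track_dc",
                    angle_fluctuation = "angle_fluctuation_deg",
                    straightness = "straightness")
    if (length(nms) >= 2L) {
      for (i in seq_len(length(nms) - 1L)) for (j in (i + 1L):length(nms)) {
        pair <- sprintf("%s_vs_%s", nms[i], nms[j])
        res <- list()
        for (sn in names(stats_cols)) {
          av <- kin_tables[[nms[i]]][[stats_cols[[sn]]]]
          bv <- kin_tables[[nms[j]]][[stats_cols[[sn]]]]
          res[[sn]] <- as.list(tidy.group_comparison(
            compare_two_groups(av[!is.na(av)], bv[!is.na(bv)])))
        }
        comparisons[[pair]] <- res
      }
    }
    manifest$comparisons <- comparisons
    manifest$summaries <- summaries
    manifest$status <- "ok"
    manifest
  }, error = function(e) {
    manifest$status <<- "failed"
    manifest$failed_stage <<- stage
    manifest$error <<- conditionMessage(e)
    all_files <- list.files(out_dir, full.names = TRUE)
    manifest$file_md5 <<- as.list(tools::md5sum(
      all_files[!grepl("manifest[.]json$", all_files)]))
    write_json_file(manifest, file.path(out_dir, "manifest.json"))
    stop_bad("pipeline failed at stage '%s': %s", stage,
             conditionMessage(e))
  })
  all_files <- list.files(out_dir, full.names = TRUE)
  all_files <- all_files[!grepl("manifest[.]json$", all_files)]
  result$file_md5 <- as.list(stats::setNames(
    unname(tools::md5sum(all_files)), basename(all_files)))
  write_json_file(result, file.path(out_dir, "manifest.json"))
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
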