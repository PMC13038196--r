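test_that("velocity follows path length over duration with calibration", {
  calib <- calibration(0.1, 1.5)
  # one step of (3, 4) px at 0.1 um/px over 1.5 s: 0.5 um / 0.025 min
  tr <- tibble::tibble(frame = 1:2, x_px = c(0, 3), y_px = c(0, 4))
  expect_equal(track_velocity(tr, calib), 20)
  # ten 0.15-um steps over 15 s -> 1.5 um / 0.25 min = 6 um/min
  tr10 <- tibble::tibble(frame = 1:11, x_px = (0:10) * 1.5, y_px = 0)
  expect_equal(track_velocity(tr10, calib), 6)
  stationary <- tibble::tibble(frame = 1:5, x_px = 2, y_px = 2)
  expect_equal(track_velocity(stationary, calib), 0)
  expect_error(track_velocity(tr[1, ], calib), "single detection")
})

test_that("movement angle uses the math convention with image y negated", {
  right <- tibble::tibble(frame = 1:2, x_px = c(0, 1), y_px = 0)
  up <- tibble::tibble(frame = 1:2, x_px = 0, y_px = c(1, 0))
  left <- tibble::tibble(frame = 1:2, x_px = c(1, 0), y_px = 0)
  expect_equal(movement_angle(right), 0)
  expect_equal(movement_angle(up), 90)
  expect_equal(movement_angle(left), 180)
  closed <- tibble::tibble(frame = 1:3, x_px = c(0, 1, 0), y_px = c(0, 1, 0))
  expect_error(movement_angle(closed), "zero net displacement")
})

test_that("angle fluctuation is the sample SD of wrapped direction changes", {
  expect_equal(angle_fluctuation(straight_track(8)), 0)
  # direction changes +10, -10, +10 -> sd = 11.547
  h <- c(0, 10, 0, 10)  # headings producing those changes
  tr <- tibble::tibble(frame = 1:5, x_px = cumsum(c(0, cos(h * pi / 180))),
                       y_px = cumsum(c(0, -sin(h * pi / 180))))
  expect_equal(angle_fluctuation(tr), sd(c(10, -10, 10)), tolerance = 1e-9)
  expect_equal(round(angle_fluctuation(tr), 3), 11.547)
  # wrap contract: 170 deg then -170 deg is a +20 change, not -340
  h2 <- c(0, 170, -170, 160)
  tr2 <- tibble::tibble(frame = 1:5,
                        x_px = cumsum(c(0, cos(h2 * pi / 180))),
                        y_px = cumsum(c(0, -sin(h2 * pi / 180))))
  d <- c(170, 20, -30)
  expect_equal(angle_fluctuation(tr2), sd(d), tolerance = 1e-9)
  # fewer than 3 steps: statistic absent
  expect_true(is.na(angle_fluctuation(straight_track(3))))
})

test_that("straightness is net over path displacement in [0, 1]", {
  expect_equal(track_straightness(straight_track(10, angle_deg = 33)), 1,
               tolerance = 1e-12)
  closed <- tibble::tibble(frame = 1:5, x_px = c(0, 2, 2, 0, 0),
                           y_px = c(0, 0, 2, 2, 0))
  expect_equal(track_straightness(closed), 0)
  corner <- tibble::tibble(frame = 1:3, x_px = c(0, 1, 1), y_px = c(0, 0, -1))
  expect_equal(track_straightness(corner), sqrt(2) / 2)
  expect_error(track_straightness(tibble::tibble(frame = 1:2, x_px = 0,
                                                 y_px = 0)), "zero path")
})

test_that("directionality concentration matches closed forms", {
  expect_equal(directionality_concentration(rep(37, 5)), 1)
  expect_equal(directionality_concentration(c(0, 90, 180, 270)), 0,
               tolerance = 1e-12)
  expect_equal(directionality_concentration(c(0, 90)), sqrt(2) / 2)
  expect_error(directionality_concentration(numeric(0)), ">= 1")
})

test_that("DC of wrapped-Gaussian headings approaches exp(-sigma^2/2)", {
  set.seed(101)
  for (sd_deg in c(5, 15, 30)) {
    ang <- rnorm(1000, 0, sd_deg)
    sig <- sd_deg * pi / 180
    expect_equal(directionality_concentration(ang), exp(-sig^2 / 2),
                 tolerance = 0.02 / exp(-sig^2 / 2))
  }
})

test_that("equal mixing of opposed headings drives DC towards zero", {
  set.seed(7)
  th <- runif(500, 0, 360)
  expect_lt(directionality_concentration(c(th, th + 180)), 1e-10)
})

test_that("kinematics are invariant under global rotation; angles shift by it", {
  cfg <- radial_config(seed = 3)
  tr <- simulate_trajectories(cfg)
  calib <- fixture_calib()
  rot <- 77 * pi / 180
  # rotate in the physical frame (x, -y)
  xr <- tr$x_px * cos(rot) - (-tr$y_px) * sin(rot)
  yr <- -(tr$x_px * sin(rot) + (-tr$y_px) * cos(rot))
  tr_rot <- dplyr::mutate(tr, x_px = xr, y_px = yr)
  k1 <- track_kinematics(tr, calib)
  k2 <- track_kinematics(tr_rot, calib)
  expect_equal(k2$velocity_um_min, k1$velocity_um_min, tolerance = 1e-9)
  expect_equal(k2$angle_fluctuation_deg, k1$angle_fluctuation_deg,
               tolerance = 1e-6)
  expect_equal(k2$straightness, k1$straightness, tolerance = 1e-9)
  defined <- !is.na(k1$movement_angle_deg)  # single-detection tracks have none
  shift <- (k2$movement_angle_deg[defined] -
              k1$movement_angle_deg[defined]) %% 360
  expect_equal(shift, rep(77, sum(defined)), tolerance = 1e-6)
  ang1 <- k1$movement_angle_deg[!is.na(k1$movement_angle_deg)]
  ang2 <- k2$movement_angle_deg[!is.na(k2$movement_angle_deg)]
  expect_equal(directionality_concentration(ang2),
               directionality_concentration(ang1), tolerance = 1e-9)
})

test_that("straightness ignores spatial scale; velocity scales with pixel size", {
  tr <- straight_track(6, step = 2, angle_deg = 20)
  tr_scaled <- dplyr::mutate(tr, x_px = x_px * 3, y_px = y_px * 3)
  expect_equal(track_straightness(tr_scaled), track_straightness(tr))
  v1 <- track_velocity(tr, calibration(0.1, 1.5))
  v2 <- track_velocity(tr, calibration(0.2, 1.5))
  expect_equal(v2, 2 * v1)
})

test_that("movie summary aggregates usable tracks and counts exclusions", {
  calib <- calibration(0.1, 1.5)
  # velocities 4 and 6 um/min: steps of 1 px = 0.1 um per 1.5 s frame
  t1 <- tibble::tibble(track_id = 1L, frame = 1:5,
                       x_px = (0:4) * 1.0, y_px = 0)    # 4 um/min
  t2 <- tibble::tibble(track_id = 2L, frame = 1:5,
                       x_px = (0:4) * 1.5, y_px = 0)    # 6 um/min
  sm <- summarize_movie(dplyr::bind_rows(t1, t2), calib)
  expect_equal(sm$mean_velocity_um_min, 5)
  expect_equal(sm$n_tracks_used, 2L)
  # opposed movement angles give DC = 0
  t3 <- dplyr::mutate(t2, track_id = 3L, x_px = -x_px)
  sm2 <- summarize_movie(dplyr::bind_rows(t1, t3), calib)
  expect_equal(sm2$directionality_concentration, 0, tolerance = 1e-12)
  # a lone 2-detection track cannot be summarised at min_steps = 3
  short <- tibble::tibble(track_id = 1L, frame = 1:2, x_px = c(0, 1), y_px = 0)
  expect_error(summarize_movie(short, calib), "zero usable tracks")
  sm3 <- summarize_movie(dplyr::bind_rows(t1, dplyr::mutate(short, track_id = 9L)),
                         calib)
  expect_equal(sm3$n_tracks_excluded, 1L)
  # tidy/glance round trip
  expect_s3_class(tidy(sm3), "tbl_df")
  expect_equal(nrow(glance(sm3)), 1L)
  expect_false(inherits(glance(sm3), "movie_summary"))
})

test_that("per-step DC pools step headings rather than net angles", {
  # a zig-zag with net direction 0: per-track DC over steps < 1, net-angle DC = 1
  zig <- tibble::tibble(track_id = 1L, frame = 1:7,
                        x_px = c(0, 1, 2, 3, 4, 5, 6),
                        y_px = c(0, 1, 0, 1, 0, 1, 0))
  sm_net <- summarize_movie(zig, fixture_calib())
  sm_step <- summarize_movie(zig, fixture_calib(), per_step = TRUE)
  expect_equal(sm_net$directionality_concentration, 1)
  expect_lt(sm_step$directionality_concentration, 1)
  expect_equal(sm_step$directionality_concentration,
               directionality_concentration(rep(c(45, -45), 3)))
})
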