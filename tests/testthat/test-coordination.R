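test_that("body-frame transform and its inverse compose to the identity", {
  pose <- make_pose(cx = 120, cy = 60, theta = 0.7, L = 48)
  # body centre maps to the origin
  bf <- to_body_frame(120, 60, pose)
  expect_equal(c(bf$longitudinal, bf$lateral), c(0, 0))
  # one body length ahead along the axis -> (1, 0)
  bf2 <- to_body_frame(120 + 48 * cos(0.7), 60 + 48 * sin(0.7), pose)
  expect_equal(bf2$longitudinal, 1, tolerance = 1e-12)
  expect_equal(bf2$lateral, 0, tolerance = 1e-12)
  # round trip
  set.seed(3)
  xs <- stats::runif(20, 0, 300); ys <- stats::runif(20, 0, 120)
  bf3 <- to_body_frame(xs, ys, pose)
  back <- from_body_frame(bf3$longitudinal, bf3$lateral, pose)
  expect_lt(max(abs(back$x - xs)), 1e-9)
  expect_lt(max(abs(back$y - ys)), 1e-9)
  # bottom-view convention: heading +x, +y side is the animal's left
  bfl <- to_body_frame(100, 55, make_pose(cx = 100, cy = 50, theta = 0, L = 50))
  expect_gt(bfl$lateral, 0)
  expect_error(to_body_frame(1, 1, make_pose(L = NA_real_)), "body length")
})

test_that("stance traces run anteriorly to posteriorly as the body advances", {
  poses <- make_moving_poses(40, step_px = 2)
  ev <- make_event(0:39, rep(120, 40), rep(40, 40), leg = "LF")
  tr <- build_stance_trace(ev, poses)
  expect_equal(nrow(tr), 40)
  expect_true(all(diff(tr$longitudinal) < 0))       # fixed floor point recedes
  expect_lt(max(abs(tr$lateral - tr$lateral[1])), 1e-12)
  expect_equal(attr(tr, "aep")[["longitudinal"]], tr$longitudinal[1])
  expect_equal(attr(tr, "pep")[["longitudinal"]], tr$longitudinal[40])
  expect_false(attr(tr, "flagged"))
  # zero body motion: trace collapses to one repeated point
  still <- make_moving_poses(10, step_px = 0)
  ev0 <- make_event(0:9, rep(60, 10), rep(45, 10), leg = "RF")
  tr0 <- build_stance_trace(ev0, still)
  expect_lt(max(dist(cbind(tr0$longitudinal, tr0$lateral))), 1e-12)
  # under-tracked poses flag the trace
  poses_gap <- poses; poses_gap$tracked[10:39] <- FALSE
  expect_true(attr(build_stance_trace(ev, poses_gap), "flagged"))
})

test_that("stance linearity is zero for straight uniform traces and matches
          a brute-force oracle for a displaced point", {
  straight <- tibble::tibble(longitudinal = seq(0.5, -0.5, length.out = 21),
                             lateral = rep(0.1, 21))
  expect_equal(stance_linearity_index(straight, smooth_win = 15), 0,
               tolerance = 1e-12)
  expect_true(is.na(stance_linearity_index(straight[1:5, ], smooth_win = 15)))

  # 7-point straight trace, one point displaced laterally by d, window 3:
  # expected index from direct enumeration
  d <- 0.05
  lon <- seq(0, 0.6, by = 0.1); lat <- rep(0, 7); lat[4] <- d
  trace <- tibble::tibble(longitudinal = lon, lateral = lat)
  n <- 7
  exp_dev <- numeric(n)
  for (i in 1:n) {
    hh <- min(1, i - 1, n - i)
    sm_lon <- mean(lon[(i - hh):(i + hh)])
    sm_lat <- mean(lat[(i - hh):(i + hh)])
    exp_dev[i] <- sqrt((lon[i] - sm_lon)^2 + (lat[i] - sm_lat)^2)
  }
  expect_equal(stance_linearity_index(trace, smooth_win = 3), mean(exp_dev),
               tolerance = 1e-12)

  # index grows monotonically with injected lateral noise
  set.seed(5)
  vals <- vapply(c(0.001, 0.005, 0.02), function(s) {
    tr <- tibble::tibble(longitudinal = seq(0.5, -0.5, length.out = 40),
                         lateral = stats::rnorm(40, 0, s))
    stance_linearity_index(tr, smooth_win = 15)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals >= 0))
})

test_that("footprint clustering is the standard distance of endpoints", {
  mk_trace <- function(leg, aep, pep) {
    pts <- tibble::tibble(leg = leg,
                          frame = 0:1,
                          longitudinal = c(aep[1], pep[1]),
                          lateral = c(aep[2], pep[2]))
    structure(pts, aep = c(longitudinal = aep[1], lateral = aep[2]),
              pep = c(longitudinal = pep[1], lateral = pep[2]),
              flagged = FALSE, class = c("stance_trace", class(pts)))
  }
  same <- list(mk_trace("LF", c(0.3, 0.1), c(-0.2, 0.1)),
               mk_trace("LF", c(0.3, 0.1), c(-0.2, 0.1)))
  expect_equal(footprint_clustering(same, "AEP"), 0)
  expect_equal(footprint_clustering(same, "PEP"), 0)
  # two AEPs (0.1, 0) and (0.3, 0): population SD over one axis = 0.1
  two <- list(mk_trace("LF", c(0.1, 0), c(0, 0)),
              mk_trace("LF", c(0.3, 0), c(0, 0)))
  expect_equal(footprint_clustering(two, "AEP"), 0.1, tolerance = 1e-12)
  # a leg with a single step is excluded; none left -> NA with warning
  one <- list(mk_trace("RF", c(0.1, 0), c(0, 0)))
  expect_warning(out <- footprint_clustering(one, "AEP"), "undefined")
  expect_true(is.na(out))
})

test_that("frame combination is total with the exact category census", {
  grid <- expand.grid(lf = c(TRUE, FALSE), lh = c(TRUE, FALSE),
                      rf = c(TRUE, FALSE), rh = c(TRUE, FALSE))
  cats <- frame_combination(grid$lf, grid$lh, grid$rf, grid$rh)
  expect_false(anyNA(cats))
  census <- table(cats)
  expect_equal(as.numeric(census[c("no_swing", "single", "diagonal",
                                   "lateral", "front_or_hind", "three_leg",
                                   "all_legs")]),
               c(1, 4, 2, 2, 2, 4, 1))
  expect_equal(as.character(frame_combination(TRUE, TRUE, TRUE, TRUE)),
               "no_swing")
  # LF and RH swinging -> diagonal (trot conformation)
  expect_equal(as.character(frame_combination(FALSE, TRUE, TRUE, FALSE)),
               "diagonal")
  expect_equal(as.character(frame_combination(FALSE, FALSE, TRUE, TRUE)),
               "lateral")
  expect_equal(as.character(frame_combination(FALSE, TRUE, FALSE, TRUE)),
               "front_or_hind")
})

test_that("combination indexes are fractions of classified frames summing to 1", {
  all_diag <- rep("diagonal", 10)
  ci <- combination_indexes(all_diag)
  expect_equal(ci$diagonal, 1)
  expect_equal(sum(unlist(ci)), 1)
  set.seed(8)
  mixed <- sample(c("no_swing", "single", "diagonal", NA), 200, replace = TRUE)
  ci2 <- combination_indexes(mixed)
  expect_equal(sum(unlist(ci2)), 1, tolerance = 1e-12)
  expect_error(combination_indexes(c(NA, NA)), "no classified")
})

test_that("phase statistics are circular", {
  st <- circular_phase_stats(c(0.95, 0.05))
  expect_equal(st$mean_phase, 0, tolerance = 1e-9)
  st2 <- circular_phase_stats(rep(0.5, 6))
  expect_equal(st2$mean_phase, 0.5)
  expect_equal(st2$dispersion, 0)

  cyc <- tibble::tibble(leg = "LF", stance_onset = c(0, 100, 200),
                        stance_offset = c(50, 150, 250),
                        next_onset = c(100, 200, 300))
  mid <- contralateral_phase(cyc, partner_onsets = c(50, 150, 250))
  expect_equal(mid$mean_phase, 0.5)
  expect_equal(mid$dispersion, 0)
  sync <- contralateral_phase(cyc, partner_onsets = c(0, 100, 200))
  expect_equal(sync$mean_phase, 0)
  expect_error(contralateral_phase(cyc[0, ], 1), "at least one")
  expect_error(contralateral_phase(cyc, partner_onsets = 999),
               "no partner onsets")
})

test_that("tail metrics report relative angles and perpendicular velocity", {
  cfg <- gait_config(frame_rate_hz = 250, px_per_cm = 8)
  n <- 100
  p <- make_moving_poses(n, step_px = 1)
  # straight tail collinear with the body axis: anterior-pointing segments
  p$tail1_or <- 0; p$tail2_or <- 0; p$tail3_or <- 0
  p$tail2_x <- p$center_x - 40; p$tail2_y <- p$center_y
  tm <- tail_metrics(p, cfg)
  expect_true(all(tm$tail1_vs_body == 0))
  expect_true(all(tm$proximal_vs_middle == 0))
  expect_true(all(tm$distal_vs_middle == 0))
  # rigid translation -> zero perpendicular velocity
  expect_true(all(tm$perp_velocity_cm_s[-1] == 0))

  # sinusoidal sway of the middle point: peak speed ~ 2*pi*f*A
  f_sway <- 2; A_cm <- 0.5
  t <- (seq_len(n) - 1) / 250
  p2 <- p
  p2$tail2_y <- p$center_y + A_cm * 8 * sin(2 * pi * f_sway * t)
  tm2 <- tail_metrics(p2, cfg)
  peak <- max(abs(tm2$perp_velocity_cm_s), na.rm = TRUE)
  expect_lt(abs(peak - 2 * pi * f_sway * A_cm) / (2 * pi * f_sway * A_cm),
            0.05)
  # missing tail -> undefined rows
  p3 <- p; p3$has_tail[5] <- FALSE
  tm3 <- tail_metrics(p3, cfg)
  expect_true(is.na(tm3$perp_velocity_cm_s[6]))
})

test_that("pressure series reports area, intensity and their ratio", {
  cfg <- gait_config(px_per_cm = 10)
  ev <- make_event(0:4, rep(10, 5), rep(10, 5),
                   areas = rep(25, 5), bright = rep(2500, 5))
  pr <- pressure_series(ev, cfg)
  expect_equal(pr$area_cm2, rep(0.25, 5))
  expect_equal(pr$intensity, rep(2500, 5))
  expect_equal(pr$pressure, rep(100, 5))
  # doubling pixel values doubles intensity and ratio, not area
  ev2 <- make_event(0:4, rep(10, 5), rep(10, 5),
                    areas = rep(25, 5), bright = rep(5000, 5))
  pr2 <- pressure_series(ev2, cfg)
  expect_equal(pr2$area_cm2, pr$area_cm2)
  expect_equal(pr2$intensity, 2 * pr$intensity)
  expect_equal(pr2$pressure, 2 * pr$pressure)
  # gap-filled frames have undefined pressure
  ev3 <- make_event(0:2, rep(10, 3), rep(10, 3),
                    areas = c(25, NA, 25), bright = c(2500, NA, 2500))
  expect_true(is.na(pressure_series(ev3, cfg)$pressure[2]))
})

test_that("body linearity measures deviation of the centre path in mm", {
  cfg <- gait_config(px_per_cm = 8)
  straight <- make_moving_poses(60, step_px = 1.5)
  expect_equal(body_linearity_index(straight, cfg), 0, tolerance = 1e-9)
  set.seed(12)
  wobbly <- straight
  wobbly$center_y <- wobbly$center_y + stats::rnorm(60, 0, 2)
  expect_gt(body_linearity_index(wobbly, cfg), 0)
})
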