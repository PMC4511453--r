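blob_row <- function(frame, x, y, area = 25, bright = 2500) {
  tibble::tibble(frame = frame, x = x, y = y, area_px = area,
                 brightness_sum = bright)
}

test_that("a stationary blob links into one stance event", {
  cfg <- gait_config()
  blobs <- dplyr::bind_rows(lapply(0:9, function(f) blob_row(f, 50, 20)))
  ev <- link_blobs(blobs, cfg)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset, 0)
  expect_equal(ev$offset, 9)
  expect_equal(length(ev$frames[[1]]), 10)
})

test_that("detection gaps within max_gap_frames are bridged and interpolated", {
  cfg <- gait_config()
  blobs <- dplyr::bind_rows(lapply(c(1:4, 6:9), function(f) blob_row(f, 50, 20)))
  ev <- link_blobs(blobs, cfg)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset, 1); expect_equal(ev$offset, 9)
  expect_equal(ev$frames[[1]], 1:9)
  expect_equal(ev$xs[[1]][5], 50)          # interpolated centroid
  expect_true(is.na(ev$areas[[1]][5]))     # no measured pixels in the gap
  # a gap longer than max_gap_frames splits the track
  blobs2 <- dplyr::bind_rows(lapply(c(1:4, 9:12), function(f) blob_row(f, 50, 20)))
  expect_equal(nrow(link_blobs(blobs2, cfg)), 2)
})

test_that("competing blobs resolve to the closer track; far blobs start fresh", {
  cfg <- gait_config()
  b <- dplyr::bind_rows(
    lapply(0:5, function(f) blob_row(f, 50, 20)),
    blob_row(3, 56, 20), blob_row(4, 56, 20), blob_row(5, 56, 20)
  ) |> dplyr::arrange(frame)
  ev <- link_blobs(b, cfg)
  expect_equal(nrow(ev), 2)
  expect_equal(sort(vapply(ev$xs, mean, numeric(1))), c(50, 56))
  # tracks shorter than min_stance_frames are discarded
  b2 <- dplyr::bind_rows(blob_row(0, 10, 10), blob_row(1, 10, 10))
  expect_equal(nrow(link_blobs(b2, cfg)), 0)
  expect_error(link_blobs(blob_row(c(3, 1), c(1, 1), c(1, 1)), cfg),
               "ascending")
})

test_that("leg identity follows body-frame side and fore/hind position", {
  cfg <- gait_config()
  pose <- make_pose(cx = 100, cy = 50, theta = 0, L = 50)
  ev <- dplyr::bind_rows(
    make_event(0:4, rep(100 + 0.3 * 50, 5), rep(50 + 0.1 * 50, 5), id = 1L),
    make_event(0:4, rep(100 - 0.3 * 50, 5), rep(50 - 0.1 * 50, 5), id = 2L),
    make_event(0:4, rep(100 + 0.3 * 50, 5), rep(50 - 0.1 * 50, 5), id = 3L),
    make_event(0:4, rep(100 - 0.3 * 50, 5), rep(50 + 0.1 * 50, 5), id = 4L)
  )
  out <- assign_leg_identity(ev, pose, cfg)
  got <- out$leg[match(1:4, out$event_id)]
  expect_equal(got, c("LF", "RH", "RF", "LH"))
})

test_that("dead-zone events resolve by continuity with the nearest candidate leg", {
  cfg <- gait_config()
  pose <- make_pose(cx = 100, cy = 50, theta = 0, L = 50)
  near_split <- 100 + 0.005 * 50    # inside +/-0.02 body-length dead zone
  ev <- dplyr::bind_rows(
    make_event(0:4, rep(100 - 0.2 * 50, 5), rep(50 + 0.2 * 50, 5), id = 1L),
    make_event(20:24, rep(near_split, 5), rep(50 + 0.2 * 50, 5), id = 2L)
  )
  out <- assign_leg_identity(ev, pose, cfg)
  expect_equal(out$leg[out$event_id == 1], "LH")
  expect_equal(out$leg[out$event_id == 2], "LH")   # continuity with event 1
  expect_false(out$ambiguous_leg[out$event_id == 2])
  # without a prior event the dead zone is flagged ambiguous
  out2 <- assign_leg_identity(ev[2, ], pose, cfg)
  expect_true(out2$ambiguous_leg)
})

test_that("leg assignment is invariant under translation and 180-degree rotation", {
  cfg <- gait_config()
  pose <- make_pose(cx = 100, cy = 50, theta = 0, L = 50)
  ev <- make_event(0:4, rep(100 + 0.3 * 50, 5), rep(50 + 0.1 * 50, 5))
  base <- assign_leg_identity(ev, pose, cfg)$leg
  # translation
  pose_t <- make_pose(cx = 140, cy = 75, theta = 0, L = 50)
  ev_t <- make_event(0:4, rep(140 + 0.3 * 50, 5), rep(75 + 0.1 * 50, 5))
  expect_equal(assign_leg_identity(ev_t, pose_t, cfg)$leg, base)
  # arena rotated 180 degrees: points reflect through the centre, the
  # animal now heads -x
  rot <- function(x, y, cx, cy) list(x = 2 * cx - x, y = 2 * cy - y)
  p <- rot(100 + 0.3 * 50, 50 + 0.1 * 50, 100, 50)
  pose_r <- make_pose(cx = 100, cy = 50, theta = pi, L = 50)
  ev_r <- make_event(0:4, rep(p$x, 5), rep(p$y, 5))
  expect_equal(assign_leg_identity(ev_r, pose_r, cfg)$leg, base)
})

test_that("step cycles assemble timing and step length exactly", {
  cfg <- gait_config(frame_rate_hz = 250, px_per_cm = 8)
  ev <- dplyr::bind_rows(
    make_event(0:49, rep(50, 50), rep(20, 50), leg = "LF", id = 1L),
    make_event(100:149, rep(82, 50), rep(20, 50), leg = "LF", id = 2L)
  )
  cy <- build_step_cycles(ev, cfg)
  expect_equal(nrow(cy), 1)
  expect_equal(cy$stance_time, 0.2)
  expect_equal(cy$swing_time, 0.2)
  expect_equal(cy$period, 0.4)
  expect_equal(cy$stance_time + cy$swing_time, cy$period)
  expect_equal(cy$step_length_mm, 32 * 10 / 8)
  expect_equal(cy$duty_factor, 0.5)
  # a single event yields no cycle
  expect_equal(nrow(build_step_cycles(ev[1, ], cfg)), 0)
  # overlapping same-leg events are a linking bug
  bad <- dplyr::bind_rows(
    make_event(0:49, rep(50, 50), rep(20, 50), leg = "LF", id = 1L),
    make_event(40:90, rep(60, 51), rep(20, 51), leg = "LF", id = 2L)
  )
  expect_error(build_step_cycles(bad, cfg), "overlap")
})

test_that("synthetic trot events match the generator schedule", {
  tt <- get_trot()
  truth <- tt$trial$truth
  ev <- tt$track$events
  expect_equal(nrow(ev), nrow(truth$schedule))
  sch <- truth$schedule
  hits <- 0; leg_ok <- 0; dur_ok <- 0
  for (i in seq_len(nrow(ev))) {
    d <- sqrt((sch$anchor_x - ev$mean_x[i])^2 + (sch$anchor_y - ev$mean_y[i])^2)
    j <- which.min(d)
    expect_lt(d[j], 3)
    hits <- hits + (abs(ev$onset[i] - sch$onset[j]) <= 1 &&
                      abs(ev$offset[i] - sch$offset[j]) <= 1)
    leg_ok <- leg_ok + (ev$leg[i] == sch$leg[j])
    dur_ok <- dur_ok + (abs((ev$offset[i] - ev$onset[i]) -
                              (sch$offset[j] - sch$onset[j])) <= 1)
  }
  expect_equal(leg_ok, nrow(ev))                  # 100 % leg identification
  expect_gte(hits / nrow(ev), 0.95)               # onsets within one frame
  expect_gte(dur_ok / nrow(ev), 0.95)
  # events of one leg are strictly ordered and non-overlapping
  for (leg in c("LF", "LH", "RF", "RH")) {
    e <- ev[ev$leg == leg, ]
    e <- e[order(e$onset), ]
    if (nrow(e) > 1) expect_true(all(e$onset[-1] > e$offset[-nrow(e)]))
  }
})
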