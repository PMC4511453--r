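test_that("schedule arithmetic follows duty, period and stride identities", {
  # duty 0.5, period 0.4 s at 250 Hz -> 100-frame cycles, 50/50 split
  spec <- gait_spec(speed_cm_s = 15, stride_cm = 6, duty = 0.5,
                    n_cycles = 3, pep_jitter_mm = 0, aep_jitter_mm = 0,
                    seed = 2)
  truth <- generate_ground_truth(spec)
  expect_equal(truth$period_frames, 100L)
  expect_equal(truth$params$period_s, 0.4)
  durs <- truth$schedule$offset - truth$schedule$onset + 1
  expect_true(all(durs == 50))
  # stride = speed x period
  expect_equal(truth$params$stride_cm, 6, tolerance = 1e-9)
  expect_equal(truth$params$duty, 0.5, tolerance = 1e-9)
  # anti-phase pairing is exact by construction
  expect_equal(truth$params$phase_fore, 0.5)
  expect_equal(truth$params$phase_hind, 0.5)
  expect_error(gait_spec(n_cycles = 1), "n_cycles")
})

test_that("trot and pace phase tables pair the right legs", {
  trot <- generate_ground_truth(gait_spec(n_cycles = 3, seed = 4,
                                          aep_jitter_mm = 0,
                                          pep_jitter_mm = 0))
  on <- function(tr, leg) sort(tr$schedule$onset[tr$schedule$leg == leg])
  expect_equal(on(trot, "LF"), on(trot, "RH"))     # diagonal pair together
  pace <- generate_ground_truth(gait_spec(n_cycles = 3, seed = 4,
                                          diagonal = FALSE,
                                          aep_jitter_mm = 0,
                                          pep_jitter_mm = 0))
  expect_equal(on(pace, "LF"), on(pace, "LH"))     # lateral pair together
})

test_that("generation is deterministic in the seed", {
  spec <- gait_spec(n_cycles = 3, seed = 9)
  t1 <- generate_ground_truth(spec)
  t2 <- generate_ground_truth(spec)
  expect_identical(t1$schedule, t2$schedule)
  expect_identical(t1$poses, t2$poses)
  t3 <- generate_ground_truth(gait_spec(n_cycles = 3, seed = 10))
  expect_false(identical(t1$schedule$anchor_x, t3$schedule$anchor_x))
})

test_that("fixture files are byte-identical for the same seed", {
  spec <- gait_spec(speed_cm_s = 45, n_cycles = 2, seed = 21)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture(simulate_trial(spec), d1, overwrite = TRUE)
  write_fixture(simulate_trial(spec), d2, overwrite = TRUE)
  for (f in c("truth_poses.csv", "truth_schedule.csv", "truth_params.csv",
              "config.yaml", "frame_000010.png")) {
    expect_identical(readBin(file.path(d1, f), "raw", 2e6),
                     readBin(file.path(d2, f), "raw", 2e6), label = f)
  }
  expect_error(write_fixture(simulate_trial(spec), d1), "not empty")
  # different seeds realise different placement jitter
  d3 <- withr::local_tempdir()
  write_fixture(simulate_trial(gait_spec(speed_cm_s = 45, n_cycles = 2,
                                         seed = 22)), d3, overwrite = TRUE)
  expect_false(identical(
    readBin(file.path(d1, "truth_schedule.csv"), "raw", 2e6),
    readBin(file.path(d3, "truth_schedule.csv"), "raw", 2e6)))
})

test_that("noise-free rendering is the exact silhouette on the background", {
  spec <- gait_spec(n_cycles = 2, seed = 5, pixel_noise_sd = 0,
                    tail_sway_amp_cm = 0)
  truth <- generate_ground_truth(spec)
  truth$schedule <- truth$schedule[0, ]      # no paws down
  fr <- render_frames(truth, spec)[[11]]   # 0-based frame 10
  expect_setequal(unique(as.numeric(fr$pixels)), c(30, 110))
  p <- truth$poses[11, ]
  expect_equal(fr$pixels[round(p$center_y) + 1, round(p$center_x) + 1], 110)
  expect_equal(fr$pixels[1, 1], 30)
  # the silhouette matches the declared ground-truth mask
  expect_equal(fr$pixels == 110, truth_body_mask(truth, 10))
})

test_that("scheduled contacts are detectable in nearly every rendered frame", {
  tt <- get_trot()
  truth <- tt$trial$truth
  blobs <- tt$track$blobs
  sched <- truth$schedule
  total <- 0; found <- 0
  for (i in seq_len(nrow(sched))) {
    for (f in sched$onset[i]:sched$offset[i]) {
      total <- total + 1
      b <- blobs[blobs$frame == f, ]
      if (nrow(b) && min(sqrt((b$x - sched$anchor_x[i])^2 +
                                (b$y - sched$anchor_y[i])^2)) < 3) {
        found <- found + 1
      }
    }
  }
  expect_gte(found / total, 0.99)
})

test_that("colour rendering separates body and paw channels", {
  spec <- gait_spec(n_cycles = 2, seed = 6, color = TRUE, pixel_noise_sd = 0)
  trial <- simulate_trial(spec)
  truth <- trial$truth
  st <- truth$schedule[3, ]
  f <- floor((st$onset + st$offset) / 2)
  px <- trial$frames[[f + 1]]$pixels
  p <- truth$poses[f + 1, ]
  cx <- round(p$center_x) + 1; cy <- round(p$center_y) + 1
  expect_equal(px[cy, cx, 1], 110)             # body in the red channel
  expect_equal(px[cy, cx, 3], 30)
  ax <- round(st$anchor_x) + 1; ay <- round(st$anchor_y) + 1
  expect_gt(px[ay, ax, 2], 200)                # paw in the green channel
  expect_equal(px[1, 1, 1], 30)
  # colour pipeline tracks with the matching config
  tr <- run_track(trial$frames, trial$config)
  expect_equal(nrow(tr$events), nrow(truth$schedule))
})
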