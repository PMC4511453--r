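test_that("background model is the per-pixel median", {
  frames <- lapply(0:9, function(i) new_frame(i, matrix(40, 8, 10), 250))
  bg <- build_background(frames)
  expect_equal(bg$median, matrix(40, 8, 10))

  # one pixel takes values {10, 10, 10, 200, 200} -> median 10
  mats <- lapply(c(10, 10, 10, 200, 200), function(v) matrix(v, 4, 4))
  mats <- lapply(seq_along(mats), function(i) {
    m <- matrix(10, 4, 4); m[2, 3] <- c(10, 10, 10, 200, 200)[i]
    new_frame(i - 1, m, 250)
  })
  bg <- build_background(mats)
  expect_equal(bg$median[2, 3], 10)

  expect_error(build_background(list()), "empty")
  expect_error(build_background(frames[1:2]), "at least 3")
  bad <- c(frames[1:3], list(new_frame(3, matrix(40, 9, 10), 250)))
  expect_error(build_background(bad), "mismatch")
})

test_that("background is permutation-invariant over frame order", {
  set.seed(42)
  frames <- lapply(0:6, function(i) {
    new_frame(i, matrix(sample(0:255, 30, replace = TRUE), 5, 6), 250)
  })
  bg1 <- build_background(frames)
  bg2 <- build_background(frames[sample(7)])
  expect_equal(bg1$median, bg2$median)
})

test_that("exclusion masks drop animal pixels from the median", {
  # pixel [1,1] is 'animal' (value 200) in 3 of 5 frames; excluded,
  # its median must come from the remaining clean frames (value 35)
  frames <- lapply(0:4, function(i) {
    m <- matrix(35, 4, 4)
    if (i < 3) m[1, 1] <- 200
    new_frame(i, m, 250)
  })
  masks <- lapply(0:4, function(i) {
    e <- matrix(FALSE, 4, 4); if (i < 3) e[1, 1] <- TRUE; e
  })
  bg <- build_background(frames, exclusion_masks = masks)
  expect_equal(bg$median[1, 1], 35)
  # a pixel excluded everywhere falls back to the global median, flagged
  masks_all <- lapply(masks, function(e) { e[2, 2] <- TRUE; e })
  bg2 <- build_background(frames, exclusion_masks = masks_all)
  expect_true(bg2$never_background[2, 2])
  expect_equal(bg2$median[2, 2], 35)
})

test_that("pixel classification partitions the frame with footprint precedence", {
  cfg <- gait_config()
  bgmat <- matrix(30, 6, 6)
  bg <- build_background(lapply(0:2, function(i) new_frame(i, bgmat, 250)),
                         tolerance = cfg$bg_tolerance)
  # frame identical to background -> all background
  m <- classify_pixels(new_frame(0, bgmat, 250), bg, cfg)
  expect_true(all(m$background))
  expect_false(any(m$body | m$footprint))

  fr <- bgmat
  fr[2, 2] <- 110   # body range
  fr[4, 4] <- 200   # footprint range
  m <- classify_pixels(new_frame(0, fr, 250), bg, cfg)
  expect_true(m$body[2, 2]); expect_true(m$footprint[4, 4])
  # partition: exactly one mask true per pixel
  expect_equal(m$body + m$footprint + m$background, matrix(1, 6, 6))

  # a pixel matching both an (overlapping) body and footprint rule is footprint
  cfg2 <- gait_config(body_min = 70, body_max = 220,
                      footprint_min = 150, footprint_max = 255)
  m2 <- classify_pixels(new_frame(0, fr, 250), bg, cfg2)
  expect_true(m2$footprint[4, 4])
  expect_false(m2$body[4, 4])

  expect_error(gait_config(footprint_max = 300), "outside")
})

test_that("footprint blobs report area, brightness sum and weighted centroid", {
  cfg <- gait_config()
  expect_equal(nrow(extract_footprints(
    make_masks(matrix(FALSE, 10, 10)), new_frame(0, matrix(0, 10, 10), 250),
    cfg)), 0)

  # two disjoint 5x5 squares of value 100
  px <- matrix(0, 20, 40)
  px[3:7, 3:7] <- 100
  px[12:16, 30:34] <- 100
  fp <- px == 100
  blobs <- extract_footprints(make_masks(fp, fp), new_frame(0, px, 250), cfg)
  expect_equal(nrow(blobs), 2)
  expect_equal(blobs$area_px, c(25L, 25L))
  expect_equal(blobs$brightness_sum, c(2500, 2500))
  expect_equal(sort(blobs$x), c(4, 31))  # 0-based centroids
  expect_equal(sort(blobs$y), c(4, 13))

  # blobs below min_blob_area are dropped
  small <- matrix(FALSE, 10, 10); small[5, 5] <- TRUE
  px2 <- matrix(0, 10, 10); px2[5, 5] <- 200
  expect_equal(nrow(extract_footprints(make_masks(small, small),
                                       new_frame(0, px2, 250), cfg)), 0)
})

test_that("labelling is 8-connected", {
  cfg <- gait_config(min_blob_area = 1, footprint_close_px = 0)
  fp <- matrix(FALSE, 8, 8)
  fp[2, 2] <- TRUE; fp[3, 3] <- TRUE; fp[4, 4] <- TRUE  # diagonal chain
  px <- matrix(0, 8, 8); px[fp] <- 200
  blobs <- extract_footprints(make_masks(fp, fp), new_frame(0, px, 250), cfg)
  expect_equal(nrow(blobs), 1)
  expect_equal(blobs$area_px, 3L)
})

test_that("noise-free synthetic frames segment to ground truth", {
  cl <- get_clean()
  trial <- cl$trial; truth <- trial$truth; cfg <- trial$config
  sub <- trial$frames[seq(1, length(trial$frames), by = 7)]
  # with candidate-animal pixels excluded, the median matches the true
  # background field everywhere, even where the animal lingered
  excl <- lapply(sub, candidate_animal_mask, cfg = cfg)
  bg <- build_background(sub, exclusion_masks = excl,
                         tolerance = cfg$bg_tolerance)
  expect_true(max(abs(bg$median - truth$background)) <= 1)

  # mid-stance contacts: one blob per scheduled paw, centroid within 1 px
  sched <- truth$schedule
  mid <- floor((sched$onset + sched$offset) / 2)
  test_frames <- unique(mid[c(3, 6, 9)])
  for (f in test_frames) {
    fr <- trial$frames[[f + 1]]
    masks <- classify_pixels(fr, bg, cfg)
    expect_equal(masks$body + masks$footprint + masks$background,
                 matrix(1, truth$height, truth$width))
    blobs <- extract_footprints(masks, fr, cfg)
    act <- sched[sched$onset <= f & sched$offset >= f, ]
    expect_equal(nrow(blobs), nrow(act))
    for (j in seq_len(nrow(act))) {
      d <- sqrt((blobs$x - act$anchor_x[j])^2 + (blobs$y - act$anchor_y[j])^2)
      expect_lt(min(d), 1)
    }
    # body mask matches the rendered silhouette within a 1-pixel band;
    # the mid-intensity skirt of a paw spot may add body pixels near an
    # active anchor
    sil <- truth_body_mask(truth, f)
    dil <- EBImage::dilate(sil + 0, EBImage::makeBrush(3, "box")) > 0
    ero <- EBImage::erode(sil + 0, EBImage::makeBrush(3, "box")) > 0
    X <- matrix(rep(0:(truth$width - 1), each = truth$height), truth$height)
    Y <- matrix(rep(0:(truth$height - 1), truth$width), truth$height)
    near_paw <- matrix(FALSE, truth$height, truth$width)
    for (j in seq_len(nrow(act))) {
      near_paw <- near_paw |
        ((X - act$anchor_x[j])^2 + (Y - act$anchor_y[j])^2 <= 25)
    }
    expect_true(all((dil | near_paw)[masks$body]))
    expect_true(all((masks$body | masks$footprint)[ero]))
  }
})
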