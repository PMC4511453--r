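# Shared synthetic fixtures, built once per test session.
fixture_cache <- new.env(parent = emptyenv())

# default-noise trot trial with tracking + analysis
get_trot <- function() {
  if (is.null(fixture_cache$trot)) {
    spec <- gait_spec(speed_cm_s = 30, n_cycles = 5, seed = 7)
    trial <- simulate_trial(spec)
    track <- run_track(trial$frames, trial$config)
    analysis <- run_analyze(track)
    fixture_cache$trot <- list(spec = spec, trial = trial, track = track,
                               analysis = analysis)
  }
  fixture_cache$trot
}

# noise-free trial for segmentation oracles
get_clean <- function() {
  if (is.null(fixture_cache$clean)) {
    spec <- gait_spec(speed_cm_s = 30, n_cycles = 4, seed = 11,
                      pixel_noise_sd = 0)
    trial <- simulate_trial(spec)
    fixture_cache$clean <- list(spec = spec, trial = trial)
  }
  fixture_cache$clean
}

# one-row pose for body-frame geometry tests
make_pose <- function(cx = 100, cy = 50, theta = 0, L = 50) {
  tibble::tibble(frame = 0L, tracked = TRUE, has_tail = TRUE,
                 center_x = cx, center_y = cy, orientation = theta,
                 body_length_px = L)
}

# uniform-motion pose table (cm/frame along +x)
make_moving_poses <- function(n, step_px, cx0 = 50, cy = 40, L = 56) {
  tibble::tibble(frame = seq_len(n) - 1L, tracked = TRUE, has_tail = TRUE,
                 center_x = cx0 + (seq_len(n) - 1L) * step_px,
                 center_y = cy, orientation = 0, body_length_px = L)
}

# pixel-mask triple from a logical body/footprint pair
make_masks <- function(body, footprint = NULL) {
  if (is.null(footprint)) footprint <- body & FALSE
  structure(list(body = body & !footprint, footprint = footprint,
                 background = !(body | footprint)),
            class = "pixel_masks")
}

# filled ellipse mask (0-based centre coordinates)
ellipse_mask <- function(H, W, cx, cy, a, b, theta = 0) {
  X <- matrix(rep(0:(W - 1), each = H), H)
  Y <- matrix(rep(0:(H - 1), times = W), H)
  dx <- X - cx; dy <- Y - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# event tibble row from explicit per-frame series
make_event <- function(frames, xs, ys, areas = NULL, bright = NULL,
                       leg = NA_character_, id = 1L) {
  n <- length(frames)
  if (is.null(areas)) areas <- rep(25, n)
  if (is.null(bright)) bright <- rep(2500, n)
  tibble::tibble(event_id = id, leg = leg, ambiguous_leg = FALSE,
                 onset = frames[1], offset = frames[n],
                 mean_x = mean(xs), mean_y = mean(ys),
                 peak_brightness = max(bright),
                 frames = list(frames), xs = list(xs), ys = list(ys),
                 areas = list(areas), brightness = list(bright))
}
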