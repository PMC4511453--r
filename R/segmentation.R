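#' Build a per-pixel median background model
#'
#' The background is modelled independently for each pixel as the
#' per-channel median over the frames in which the animal is not present
#' at that pixel. When exclusion masks are supplied (TRUE = animal
#' present), excluded observations are dropped pixel-wise; pixels excluded
#' in every frame receive the global median of the modelled pixels and are
#' flagged.
#'
#' @param frames List of `gait_frame` objects sharing dimensions.
#' @param exclusion_masks Optional list of `H x W` logical matrices, one
#'   per frame, marking pixels occupied by the animal.
#' @param tolerance Per-channel symmetric background tolerance stored with
#'   the model (same units as channel values).
#' @return A list of class `background_model` with fields `median`
#'   (matrix/array shaped like a frame), `tolerance`, and `never_background`
#'   (logical matrix flagging pixels excluded in every frame).
#' @export
build_background <- function(frames, exclusion_masks = NULL, tolerance = 12) {
  if (!length(frames)) stop("empty frame list", call. = FALSE)
  if (length(frames) < 3) stop("need at least 3 frames", call. = FALSE)
  if (any(tolerance < 0)) stop("tolerance must be >= 0", call. = FALSE)
  d0 <- frame_dim(frames[[1]])
  nc <- frame_nchan(frames[[1]])
  same <- vapply(frames, function(f) identical(frame_dim(f), d0) &&
                   frame_nchan(f) == nc, logical(1))
  if (!all(same)) stop("mismatched frame dimensions", call. = FALSE)
  if (!is.null(exclusion_masks)) stopifnot(length(exclusion_masks) == length(frames))

  npx <- prod(d0)
  med_one <- function(ch) {
    # rows = pixels, cols = frames
    mat <- vapply(seq_along(frames), function(i) {
      px <- frames[[i]]$pixels
      v <- if (nc == 3L) as.numeric(px[, , ch]) else as.numeric(px)
      if (!is.null(exclusion_masks)) v[as.logical(exclusion_masks[[i]])] <- NA_real_
      v
    }, numeric(npx))
    m <- apply(mat, 1L, stats::median, na.rm = TRUE)
    matrix(m, d0[1], d0[2])
  }
  med <- if (nc == 3L) {
    arr <- array(NA_real_, c(d0, 3L))
    for (ch in 1:3) arr[, , ch] <- med_one(ch)
    arr
  } else {
    med_one(1L)
  }
  never <- if (nc == 3L) is.na(med[, , 1]) else is.na(med)
  if (any(never)) {
    if (nc == 3L) {
      for (ch in 1:3) {
        sl <- med[, , ch]
        sl[never] <- stats::median(sl, na.rm = TRUE)
        med[, , ch] <- sl
      }
    } else {
      med[never] <- stats::median(med, na.rm = TRUE)
    }
  }
  structure(list(median = med, tolerance = tolerance, never_background = never),
            class = "background_model")
}

#' Classify frame pixels as background, body or footprint
#'
#' A pixel within the background tolerance of its per-pixel median is
#' background. Remaining pixels are tested against the footprint
#' colour/intensity rule first (footprint has precedence), then the body
#' rule; pixels matching neither revert to background. The three masks are
#' pairwise disjoint and cover every pixel.
#'
#' @param frame A `gait_frame`.
#' @param bg A `background_model` with matching dimensions.
#' @param cfg A [gait_config()] list; for colour frames `body_min` etc. may
#'   be length-3 per-channel vectors (scalars are recycled).
#' @return A list of class `pixel_masks` with logical matrices `body`,
#'   `footprint`, `background`.
#' @export
classify_pixels <- function(frame, bg, cfg) {
  validate_gait_config(cfg)
  d0 <- frame_dim(frame)
  if (!identical(dim(bg$median)[1:2], d0)) {
    stop("frame and background dimensions differ", call. = FALSE)
  }
  nc <- frame_nchan(frame)
  px <- frame$pixels
  in_box <- function(lo, hi) {
    if (nc == 3L) {
      lo <- rep_len(lo, 3L); hi <- rep_len(hi, 3L)
      px[, , 1] >= lo[1] & px[, , 1] <= hi[1] &
        px[, , 2] >= lo[2] & px[, , 2] <= hi[2] &
        px[, , 3] >= lo[3] & px[, , 3] <= hi[3]
    } else {
      px >= lo[1] & px <= hi[1]
    }
  }
  tol <- rep_len(bg$tolerance, if (nc == 3L) 3L else 1L)
  is_bg <- if (nc == 3L) {
    abs(px[, , 1] - bg$median[, , 1]) <= tol[1] &
      abs(px[, , 2] - bg$median[, , 2]) <= tol[2] &
      abs(px[, , 3] - bg$median[, , 3]) <= tol[3]
  } else {
    abs(px - bg$median) <= tol[1]
  }
  fp <- !is_bg & in_box(cfg$footprint_min, cfg$footprint_max)
  body <- !is_bg & !fp & in_box(cfg$body_min, cfg$body_max)
  structure(list(body = body, footprint = fp, background = !(fp | body)),
            class = "pixel_masks")
}

#' Candidate-animal mask for the background bootstrap
#'
#' Pixels whose colour/intensity matches the body or footprint rule,
#' independently of any background model. Used to exclude animal-occupied
#' observations when recomputing the per-pixel background median, so that
#' pixels whose first-pass median latched onto the animal are corrected.
#'
#' @param frame A `gait_frame`.
#' @param cfg A [gait_config()] list.
#' @return Logical `H x W` matrix, TRUE where a candidate animal pixel.
#' @export
candidate_animal_mask <- function(frame, cfg) {
  nc <- frame_nchan(frame)
  px <- frame$pixels
  in_box <- function(lo, hi) {
    if (nc == 3L) {
      lo <- rep_len(lo, 3L); hi <- rep_len(hi, 3L)
      px[, , 1] >= lo[1] & px[, , 1] <= hi[1] &
        px[, , 2] >= lo[2] & px[, , 2] <= hi[2] &
        px[, , 3] >= lo[3] & px[, , 3] <= hi[3]
    } else {
      px >= lo[1] & px <= hi[1]
    }
  }
  in_box(cfg$body_min, cfg$body_max) |
    in_box(cfg$footprint_min, cfg$footprint_max)
}

# 8-connected labelling built on EBImage's 4-connected bwlabel:
# diagonal-touching 4-labels are merged by union-find.
label8 <- function(mask) {
  L <- EBImage::bwlabel(mask)
  n <- max(L)
  if (n <= 1L) return(L)
  nr <- nrow(L); nc <- ncol(L)
  a1 <- L[-nr, -nc]; b1 <- L[-1, -1]    # down-right diagonal
  a2 <- L[-1, -nc];  b2 <- L[-nr, -1]   # up-right diagonal
  keep1 <- a1 > 0 & b1 > 0 & a1 != b1
  keep2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
  if (!nrow(pairs)) return(L)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- L
  out[L > 0] <- dense[L[L > 0]]
  out
}

#' Extract footprint blobs from a classified frame
#'
#' 8-connected components of the footprint mask with area at least
#' `min_blob_area`, each summarised by its brightness-weighted centroid
#' (brightness = mean across channels), pixel count and brightness sum.
#'
#' @param masks `pixel_masks` from [classify_pixels()].
#' @param frame The corresponding `gait_frame`.
#' @param cfg A [gait_config()] list (uses `min_blob_area`).
#' @return Tibble with one row per blob: `frame`, `x`, `y` (0-based pixel
#'   centroid), `area_px`, `brightness_sum`. Zero rows when no blob passes.
#' @export
extract_footprints <- function(masks, frame, cfg) {
  fp <- masks$footprint
  r <- cfg$footprint_close_px %||% 0
  if (r > 0 && any(fp)) {
    # closing bridges the pad-toe gap of one paw; membership stays
    # restricted to originally classified footprint pixels
    brush <- EBImage::makeBrush(2L * as.integer(r) + 1L, "disc")
    closed <- EBImage::erode(EBImage::dilate(fp + 0, brush), brush) > 0
    Lc <- label8(closed)
    L <- Lc
    L[!fp] <- 0L
  } else {
    L <- label8(fp)
  }
  n <- max(L)
  empty <- tibble::tibble(frame = integer(), x = numeric(), y = numeric(),
                          area_px = integer(), brightness_sum = numeric())
  if (n == 0L) return(empty)
  bright <- frame_brightness(frame)
  idx <- which(L > 0)
  lab <- L[idx]
  b <- bright[idx]
  row0 <- (idx - 1L) %% nrow(L)        # 0-based y
  col0 <- (idx - 1L) %/% nrow(L)       # 0-based x
  bs <- tapply(b, lab, sum)
  area <- tapply(b, lab, length)
  cx <- tapply(b * col0, lab, sum) / bs
  cy <- tapply(b * row0, lab, sum) / bs
  out <- tibble::tibble(frame = frame$index,
                        x = as.numeric(cx), y = as.numeric(cy),
                        area_px = as.integer(area),
                        brightness_sum = as.numeric(bs))
  out[out$area_px >= cfg$min_blob_area, , drop = FALSE]
}
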