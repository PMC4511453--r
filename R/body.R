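#' Decompose the body mask into pose landmarks
#'
#' Separates the tail from the body by local thickness, then derives the
#' full per-frame pose: nose, head centre and direction, body centre and
#' major-axis orientation (oriented toward the nose), back point, tail base
#' and three points equidistant along the tail with their local
#' orientations.
#'
#' The tail is the longest thin appendage of the body mask: pixels farther
#' than half the tail-thickness threshold from the mask boundary form the
#' body core, and mask parts not reachable from the core within that
#' half-thickness are tail candidates. The thickness threshold is
#' `tail_thickness_frac` times the maximum body width (twice the maximum
#' inscribed-disc radius).
#'
#' @param masks `pixel_masks` from [classify_pixels()].
#' @param cfg A [gait_config()] list.
#' @param frame_index 0-based frame number recorded in the pose row.
#' @param prev Optional tibble of previously tracked poses (most recent
#'   last); used to orient the nose when the silhouette has no tail.
#' @return A one-row tibble (an untracked row when no body component of at
#'   least `min_body_area` pixels exists) with landmark coordinates in
#'   0-based pixel units, `orientation` in radians, and `body_length_cm`.
#' @export
decompose_body <- function(masks, cfg, frame_index = NA_integer_, prev = NULL) {
  out <- empty_pose(frame_index)
  L <- label8(masks$body)
  if (max(L) == 0L) return(out)
  areas <- tabulate(L[L > 0L])
  big <- which(areas >= cfg$min_body_area)
  if (!length(big)) return(out)
  lab <- big[which.max(areas[big])]
  B <- L == lab

  dist <- EBImage::distmap(B + 0)
  half <- cfg$tail_thickness_frac * max(dist)   # half of thickness threshold
  core <- label8(dist > half)
  if (max(core) == 0L) return(out)              # body thinner than threshold everywhere
  core_areas <- tabulate(core[core > 0L])
  C <- core == which.max(core_areas)

  k <- 2L * as.integer(ceiling(half)) + 1L
  tailless <- B & (EBImage::dilate(C + 0, EBImage::makeBrush(k, "disc")) > 0)
  cand <- label8(B & !tailless)

  has_tail <- FALSE
  ambiguous_tail <- FALSE
  tail_px <- NULL
  if (max(cand) > 0L) {
    # reach of each candidate appendage = max distance from the tail-less body
    dt_out <- EBImage::distmap(!tailless + 0)
    reach <- vapply(seq_len(max(cand)), function(i) max(dt_out[cand == i]),
                    numeric(1))
    thick <- 2 * half
    real <- which(reach > thick)
    if (length(real) >= 2L) ambiguous_tail <- TRUE
    best <- which.max(reach)
    if (reach[best] > thick) {
      has_tail <- TRUE
      tail_px <- cand == best
      tailless <- tailless | (B & !tailless & !tail_px)  # re-absorb short spurs
    } else {
      tailless <- B
    }
  }

  tl_idx <- which(tailless)
  tx <- (tl_idx - 1L) %/% nrow(tailless)   # 0-based x (column)
  ty <- (tl_idx - 1L) %% nrow(tailless)    # 0-based y (row)
  center <- c(mean(tx), mean(ty))
  mu20 <- mean((tx - center[1])^2); mu02 <- mean((ty - center[2])^2)
  mu11 <- mean((tx - center[1]) * (ty - center[2]))
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02)

  tail <- NULL
  if (has_tail) tail <- trace_tail(tail_px, tailless, half)

  if (has_tail) {
    d2 <- (tx - tail$base[1])^2 + (ty - tail$base[2])^2
    nose <- tie_centroid(tx, ty, sqrt(d2))
  } else {
    dir <- travel_direction(prev)
    if (is.null(dir)) dir <- c(cos(theta), sin(theta))
    proj <- tx * dir[1] + ty * dir[2]
    nose <- tie_centroid(tx, ty, proj)
  }
  if (sum(c(cos(theta), sin(theta)) * (nose - center)) < 0) theta <- theta + pi
  theta <- wrap_angle(theta)

  body_len_px <- if (has_tail) {
    sqrt(sum((nose - tail$base)^2))
  } else {
    proj <- tx * cos(theta) + ty * sin(theta)
    max(proj) - min(proj)
  }

  hd <- cfg$head_distance_frac * body_len_px
  hsel <- (tx - nose[1])^2 + (ty - nose[2])^2 <= hd^2
  if (sum(hsel) >= 3) {
    head_c <- c(mean(tx[hsel]), mean(ty[hsel]))
    hdir <- pca_dir(tx[hsel], ty[hsel])
    ref <- nose - head_c
    if (sqrt(sum(ref^2)) < 1e-9) ref <- c(cos(theta), sin(theta))
    if (sum(hdir * ref) < 0) hdir <- -hdir
  } else {
    head_c <- nose
    hdir <- c(cos(theta), sin(theta))
  }

  out$tracked <- TRUE
  out$has_tail <- has_tail
  out$ambiguous_tail <- ambiguous_tail
  out$nose_x <- nose[1]; out$nose_y <- nose[2]
  out$head_x <- head_c[1]; out$head_y <- head_c[2]
  out$head_dir_x <- hdir[1]; out$head_dir_y <- hdir[2]
  out$center_x <- center[1]; out$center_y <- center[2]
  out$orientation <- theta
  out$body_length_px <- body_len_px
  out$body_length_cm <- body_len_px / cfg$px_per_cm
  if (has_tail) {
    out$tailbase_x <- tail$base[1]; out$tailbase_y <- tail$base[2]
    back <- (center + tail$base) / 2
    bdir <- center - tail$base
    bdir <- bdir / sqrt(sum(bdir^2))
    out$back_x <- back[1]; out$back_y <- back[2]
    out$back_dir_x <- bdir[1]; out$back_dir_y <- bdir[2]
    for (i in 1:3) {
      out[[paste0("tail", i, "_x")]] <- tail$points[i, 1]
      out[[paste0("tail", i, "_y")]] <- tail$points[i, 2]
      out[[paste0("tail", i, "_or")]] <- tail$orientations[i]
    }
  }
  out
}

empty_pose <- function(frame_index) {
  out <- tibble::tibble(
    frame = as.integer(frame_index), tracked = FALSE, has_tail = FALSE,
    ambiguous_tail = FALSE,
    nose_x = NA_real_, nose_y = NA_real_,
    head_x = NA_real_, head_y = NA_real_,
    head_dir_x = NA_real_, head_dir_y = NA_real_,
    center_x = NA_real_, center_y = NA_real_, orientation = NA_real_,
    back_x = NA_real_, back_y = NA_real_,
    back_dir_x = NA_real_, back_dir_y = NA_real_,
    tailbase_x = NA_real_, tailbase_y = NA_real_,
    body_length_px = NA_real_, body_length_cm = NA_real_
  )
  for (i in 1:3) {
    out[[paste0("tail", i, "_x")]] <- NA_real_
    out[[paste0("tail", i, "_y")]] <- NA_real_
    out[[paste0("tail", i, "_or")]] <- NA_real_
  }
  out
}

# centroid of the pixels tied (within 0.5) for the maximum of `score`;
# symmetric under mirroring, unlike a first-index argmax
tie_centroid <- function(tx, ty, score) {
  sel <- score >= max(score) - 0.5
  c(mean(tx[sel]), mean(ty[sel]))
}

pca_dir <- function(xs, ys) {
  cx <- xs - mean(xs); cy <- ys - mean(ys)
  m <- matrix(c(mean(cx^2), mean(cx * cy), mean(cx * cy), mean(cy^2)), 2)
  v <- eigen(m, symmetric = TRUE)$vectors[, 1]
  v / sqrt(sum(v^2))
}

wrap_angle <- function(a) atan2(sin(a), cos(a))

# displacement direction of the body centre over the last <= 5 tracked poses
travel_direction <- function(prev) {
  if (is.null(prev) || !nrow(prev)) return(NULL)
  p <- prev[prev$tracked, , drop = FALSE]
  if (nrow(p) < 2) return(NULL)
  p <- utils::tail(p, 5L)
  d <- c(p$center_x[nrow(p)] - p$center_x[1], p$center_y[nrow(p)] - p$center_y[1])
  n <- sqrt(sum(d^2))
  if (n < 1e-6) return(NULL)
  d / n
}

# Geodesic parameterisation of the tail: chamfer distance from the pixels
# adjoining the tail-less body, then landmarks at 1/4, 1/2, 3/4 arc length
# with local PCA orientations signed base -> tip.
trace_tail <- function(tail_px, tailless, half) {
  idx <- which(tail_px)
  r <- range((idx - 1L) %% nrow(tail_px))
  cc <- range((idx - 1L) %/% nrow(tail_px))
  r0 <- max(1L, r[1] + 1L - 1L); r1 <- min(nrow(tail_px), r[2] + 1L + 1L)
  c0 <- max(1L, cc[1] + 1L - 1L); c1 <- min(ncol(tail_px), cc[2] + 1L + 1L)
  Tm <- tail_px[r0:r1, c0:c1, drop = FALSE]
  # seeds: tail pixels adjacent to the tail-less body
  near <- EBImage::distmap(!tailless + 0)[r0:r1, c0:c1, drop = FALSE]
  g <- matrix(Inf, nrow(Tm), ncol(Tm))
  g[Tm & near <= 1.5] <- 0
  if (!any(is.finite(g))) g[Tm & near <= min(near[Tm]) + 0.5] <- 0
  g[!Tm] <- NA
  g <- chamfer_sweep(g)
  fin <- is.finite(g) & !is.na(g)
  tip_len <- max(g[fin])
  gx <- (which(fin) - 1L) %/% nrow(g) + (c0 - 1L)   # 0-based full-image x
  gy <- (which(fin) - 1L) %% nrow(g) + (r0 - 1L)
  gd <- g[fin]
  base <- c(mean(gx[gd <= 1]), mean(gy[gd <= 1]))
  pts <- matrix(NA_real_, 3, 2)
  ors <- rep(NA_real_, 3)
  for (i in 1:3) {
    q <- tip_len * i / 4
    w <- 0.75
    sel <- abs(gd - q) <= w
    while (sum(sel) < 1 && w < tip_len) { w <- w * 2; sel <- abs(gd - q) <= w }
    pts[i, ] <- c(mean(gx[sel]), mean(gy[sel]))
    nb <- abs(gd - q) <= max(2, half + 1)
    if (sum(nb) >= 3) {
      v <- pca_dir(gx[nb], gy[nb])
      # sign the local axis anteriorly (tip -> base), so a straight tail
      # collinear with the body axis has zero relative angle
      tipward <- gd > q & gd <= q + 3; baseward <- gd < q & gd >= q - 3
      if (any(tipward) && any(baseward)) {
        ref <- c(mean(gx[baseward]) - mean(gx[tipward]),
                 mean(gy[baseward]) - mean(gy[tipward]))
        if (sum(v * ref) < 0) v <- -v
      }
      ors[i] <- atan2(v[2], v[1])
    }
  }
  list(base = base, points = pts, orientations = ors, tip_len = tip_len)
}

# iterative 8-neighbour chamfer relaxation restricted to non-NA cells
chamfer_sweep <- function(g) {
  mask <- !is.na(g)
  g[is.na(g)] <- Inf
  nr <- nrow(g); nc <- ncol(g)
  pad <- function(m) {
    out <- matrix(Inf, nr + 2L, nc + 2L)
    out[2:(nr + 1L), 2:(nc + 1L)] <- m
    out
  }
  repeat {
    p <- pad(g)
    cand <- pmin(
      p[1:nr, 2:(nc + 1L)] + 1, p[3:(nr + 2L), 2:(nc + 1L)] + 1,
      p[2:(nr + 1L), 1:nc] + 1, p[2:(nr + 1L), 3:(nc + 2L)] + 1,
      p[1:nr, 1:nc] + sqrt(2), p[1:nr, 3:(nc + 2L)] + sqrt(2),
      p[3:(nr + 2L), 1:nc] + sqrt(2), p[3:(nr + 2L), 3:(nc + 2L)] + sqrt(2)
    )
    new <- pmin(g, cand)
    new[!mask] <- Inf
    if (max(abs(new - g)[mask & is.finite(g) & is.finite(new)],
            0) < 1e-9 && !any(is.finite(new) & !is.finite(g))) break
    g <- new
  }
  g[!mask] <- NA
  g
}
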