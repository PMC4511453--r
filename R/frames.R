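#' Construct a video frame
#'
#' A frame is a pixel grid with an acquisition index and timestamp. Pixels
#' are stored as a numeric `H x W` matrix (grayscale) or `H x W x 3` array
#' (RGB), channel values on the 0-255 scale; the origin is the top-left
#' pixel, `x` runs rightward along the walkway, `y` downward.
#'
#' @param index 0-based frame number.
#' @param pixels Matrix or 3-slice array of channel values in [0, 255].
#' @param frame_rate_hz Frame rate used to derive the timestamp.
#' @return A list of class `gait_frame` with fields `index`, `time`,
#'   `pixels`.
#' @export
new_frame <- function(index, pixels, frame_rate_hz) {
  stopifnot(is.numeric(pixels), length(dim(pixels)) %in% c(2L, 3L))
  if (length(dim(pixels)) == 3L && dim(pixels)[3] != 3L) {
    stop("colour frames must have exactly 3 channels", call. = FALSE)
  }
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 255) {
    stop("channel values must lie in [0, 255]", call. = FALSE)
  }
  structure(list(index = as.integer(index),
                 time = index / frame_rate_hz,
                 pixels = pixels),
            class = "gait_frame")
}

frame_dim <- function(frame) dim(frame$pixels)[1:2]
frame_nchan <- function(frame) if (length(dim(frame$pixels)) == 3L) 3L else 1L

#' Read a frame sequence from disk
#'
#' Accepts either a directory of zero-padded numbered PNG or TIFF files
#' (sorted lexicographically, which equals numeric order for zero-padded
#' names) or a single multi-page TIFF. Images decoded on the unit scale are
#' rescaled to 0-255.
#'
#' @param path Directory of image files, or one multi-page TIFF file.
#' @param frame_rate_hz Frame rate (from the configuration file, never
#'   inferred).
#' @return List of `gait_frame` objects with 0-based indices.
#' @export
read_frames <- function(path, frame_rate_hz) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop("no PNG/TIFF frames found in ", path, call. = FALSE)
    imgs <- lapply(files, read_one_image)
  } else if (file.exists(path)) {
    if (!grepl("\\.tiff?$", path, ignore.case = TRUE)) {
      stop("single-file input must be a multi-page TIFF: ", path, call. = FALSE)
    }
    imgs <- tiff::readTIFF(path, all = TRUE)
    imgs <- lapply(imgs, normalise_image)
  } else {
    stop("frame input not found: ", path, call. = FALSE)
  }
  d0 <- dim(imgs[[1]])
  ok <- vapply(imgs, function(im) identical(dim(im)[1:2], d0[1:2]) &&
                 length(dim(im)) == length(d0), logical(1))
  if (!all(ok)) stop("frames have mismatched dimensions", call. = FALSE)
  lapply(seq_along(imgs) - 1L, function(i) {
    new_frame(i, imgs[[i + 1L]], frame_rate_hz)
  })
}

read_one_image <- function(file) {
  im <- if (grepl("\\.png$", file, ignore.case = TRUE)) {
    png::readPNG(file)
  } else {
    tiff::readTIFF(file)
  }
  normalise_image(im)
}

# unit-scale decode -> 0-255; alpha dropped; 1/3 channels kept as-is
normalise_image <- function(im) {
  if (length(dim(im)) == 3L) {
    if (dim(im)[3] == 4L) im <- im[, , 1:3, drop = FALSE]
    if (dim(im)[3] == 1L) im <- im[, , 1L]
    if (length(dim(im)) == 3L && dim(im)[3] == 2L) im <- im[, , 1L]
  }
  im * 255
}

# mean across channels -> H x W brightness matrix
frame_brightness <- function(frame) {
  px <- frame$pixels
  if (length(dim(px)) == 3L) (px[, , 1] + px[, , 2] + px[, , 3]) / 3 else px
}
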