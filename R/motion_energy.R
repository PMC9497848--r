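#' Frame stack
#'
#' A stack of grayscale frames: `height x width x n_frames` array with
#' integer intensities in \[0, 255\].
#'
#' @param frames 3-D array (`h x w x n`) of intensities in \[0, 255\].
#' @param fps frames per second.
#' @return Object of class `frame_stack`.
#' @export
frame_stack <- function(frames, fps = 25) {
  if (length(dim(frames)) != 3) stop("frames must be a h x w x n array")
  if (min(frames) < 0 || max(frames) > 255) {
    stop("intensities must lie in [0, 255]")
  }
  structure(list(frames = frames, fps = fps), class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames of %dx%d px @ %g fps\n",
              d[3], d[1], d[2], x$fps))
  invisible(x)
}

#' Region-of-interest mask
#'
#' Boolean grid marking the pixels that belong to one person's movement area.
#'
#' @param mask logical matrix (TRUE = inside the ROI).
#' @return Object of class `roi_mask` with a `size` field (count of TRUE).
#' @export
roi_mask <- function(mask) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  size <- sum(mask)
  if (size < 1) stop("empty ROI")
  structure(list(mask = mask, size = size), class = "roi_mask")
}

#' Read an ROI mask from a PNG file (nonzero = inside)
#' @param path PNG file path.
#' @return An `roi_mask`.
#' @export
read_roi_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  roi_mask(img > 0)
}

#' Read a frame stack from a directory of PNG frames
#'
#' Files are read in lexicographic order; images are converted to 0-255
#' grayscale (first channel if multi-channel).
#' @param dir directory containing `.png` frames.
#' @param fps frames per second.
#' @return A `frame_stack`.
#' @export
read_frames_png <- function(dir, fps = 25) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) < 2) stop("need at least two frames")
  imgs <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3) img <- img[, , 1]
    round(img * 255)
  })
  d <- dim(imgs[[1]])
  frames <- array(0L, dim = c(d[1], d[2], length(imgs)))
  for (i in seq_along(imgs)) {
    if (!identical(dim(imgs[[i]]), d)) stop("frames differ in shape")
    frames[, , i] <- imgs[[i]]
  }
  frame_stack(frames, fps = fps)
}

#' Read a frame stack from a TIFF file or directory of TIFF frames
#'
#' A single multi-page TIFF is read page by page; a directory is read in
#' lexicographic order. Requires the `tiff` package.
#' @param path multi-page TIFF file, or directory containing `.tif`/`.tiff`
#'   frames.
#' @param fps frames per second.
#' @return A `frame_stack`.
#' @export
read_frames_tiff <- function(path, fps = 25) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("reading TIFF frames requires the `tiff` package")
  }
  imgs <- if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE))
    lapply(files, function(f) tiff::readTIFF(f))
  } else {
    tiff::readTIFF(path, all = TRUE)
  }
  if (length(imgs) < 2) stop("need at least two frames")
  imgs <- lapply(imgs, function(img) {
    if (length(dim(img)) == 3) img <- img[, , 1]
    round(img * 255)
  })
  d <- dim(imgs[[1]])
  frames <- array(0L, dim = c(d[1], d[2], length(imgs)))
  for (i in seq_along(imgs)) {
    if (!identical(dim(imgs[[i]]), d)) stop("frames differ in shape")
    frames[, , i] <- imgs[[i]]
  }
  frame_stack(frames, fps = fps)
}

#' Motion energy by frame differencing inside an ROI
#'
#' For each pair of subsequent frames (t, t+1), counts the ROI pixels whose
#' grayscale value changes by at least `threshold` (of 256 gray levels,
#' default cut-off 12). The count sequence is the raw motion-energy series of
#' that ROI.
#'
#' @param stack a `frame_stack` with at least two frames.
#' @param roi an `roi_mask` matching the frame shape.
#' @param threshold gray-level change cut-off (default 12).
#' @param inclusive if `TRUE` (default) a change of exactly `threshold`
#'   counts; if `FALSE` the comparison is strict.
#' @return An `me_series` of kind `"raw-count"`, length `n_frames - 1`.
#' @export
compute_motion_energy <- function(stack, roi, threshold = 12, inclusive = TRUE) {
  stopifnot(inherits(stack, "frame_stack"), inherits(roi, "roi_mask"))
  d <- dim(stack$frames)
  if (!identical(dim(roi$mask), d[1:2])) stop("ROI shape does not match frames")
  if (d[3] < 2) stop("need at least two frames")
  m <- which(roi$mask)
  counts <- vapply(seq_len(d[3] - 1), function(t) {
    dif <- abs(stack$frames[, , t + 1][m] - stack$frames[, , t][m])
    if (inclusive) sum(dif >= threshold) else sum(dif > threshold)
  }, numeric(1))
  me_series(counts, fps = stack$fps, kind = "raw-count")
}

#' Standardize a raw motion-energy series by ROI size
#'
#' Each count becomes `100 * count / roi_size`, the percentage of the ROI
#' activated (0 = no motion, 100 = entire ROI).
#'
#' @param raw an `me_series` of kind `"raw-count"` (or numeric counts).
#' @param roi_size number of ROI pixels (>= 1).
#' @return An `me_series` of kind `"standardized"`.
#' @export
standardize_series <- function(raw, roi_size) {
  if (roi_size <= 0) stop("roi_size must be >= 1")
  fps <- attr(raw, "fps"); if (is.null(fps)) fps <- 25
  me_series(100 * as.numeric(raw) / roi_size, fps = fps, kind = "standardized")
}

#' Moving-median smoothing
#'
#' Centered moving median with odd bandwidth (default 5 frames). At the
#' series ends the window shrinks symmetrically (the first and last value use
#' bandwidth 1, the next 3, ...), so output length equals input length.
#'
#' @param series an `me_series` (or numeric vector).
#' @param bandwidth odd window width in frames.
#' @return An `me_series` of kind `"smoothed"`.
#' @export
smooth_series <- function(series, bandwidth = 5) {
  if (bandwidth %% 2 == 0 || bandwidth < 1) stop("bandwidth must be odd, >= 1")
  x <- as.numeric(series)
  if (length(x) < bandwidth) stop("series shorter than bandwidth")
  fps <- attr(series, "fps"); if (is.null(fps)) fps <- 25
  if (bandwidth == 1) {
    return(me_series(x, fps = fps, kind = "smoothed"))
  }
  n <- length(x)
  h <- (bandwidth - 1) %/% 2
  out <- as.numeric(stats::runmed(x, bandwidth, endrule = "keep"))
  for (i in seq_len(h)) {          # symmetric shrink at both ends
    k <- i - 1
    out[i] <- stats::median(x[(i - k):(i + k)])
    j <- n - i + 1
    out[j] <- stats::median(x[(j - k):(j + k)])
  }
  me_series(out, fps = fps, kind = "smoothed")
}

#' Full motion-energy preprocessing pipeline
#'
#' Frame differencing, ROI standardization, moving-median smoothing.
#' @inheritParams compute_motion_energy
#' @inheritParams smooth_series
#' @return An `me_series` of kind `"smoothed"`, values in \[0, 100\].
#' @export
motion_energy_pipeline <- function(stack, roi, threshold = 12, bandwidth = 5) {
  raw <- compute_motion_energy(stack, roi, threshold = threshold)
  smooth_series(standardize_series(raw, roi$size), bandwidth = bandwidth)
}
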