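# Image sequences: the raw object of study.  Frames are stored as an
# H x W x F array of float intensities (typically on 0-255); pixel
# coordinates are 0-based, row-major, origin top-left throughout.

#' Construct an image sequence
#'
#' @param frames Numeric H x W x F array (or a list of H x W matrices) of
#'   grayscale intensities.  All frames must share one geometry and contain
#'   only finite values; at least two frames are required.
#' @param frame_rate_hz Acquisition frame rate in Hz (> 0).  The B-mode
#'   captures this package emulates run at 78.6 Hz.
#' @param source_id Free-text label identifying the capture.
#' @return Object of class `"image_sequence"` with elements `frames`,
#'   `frame_rate_hz`, `source_id`.
#' @examples
#' f <- array(runif(32 * 32 * 4, 0, 255), c(32, 32, 4))
#' seq <- image_sequence(f, frame_rate_hz = 78.6, source_id = "demo")
#' n_frames(seq)
#' @export
image_sequence <- function(frames, frame_rate_hz = 78.6,
                           source_id = "sequence") {
  if (is.list(frames)) {
    shapes <- unique(lapply(frames, dim))
    if (length(shapes) != 1L)
      stop("all frames must share the same H x W geometry", call. = FALSE)
    frames <- array(unlist(frames, use.names = FALSE),
                    c(shapes[[1]], length(frames)))
  }
  if (length(dim(frames)) != 3L)
    stop("`frames` must be an H x W x F array", call. = FALSE)
  if (dim(frames)[3] < 2L)
    stop("an image sequence needs at least 2 frames", call. = FALSE)
  if (any(!is.finite(frames)))
    stop("frame intensities must be finite (no NA/NaN/Inf)", call. = FALSE)
  if (!is.numeric(frame_rate_hz) || frame_rate_hz <= 0)
    stop("`frame_rate_hz` must be > 0", call. = FALSE)
  structure(list(frames = frames,
                 frame_rate_hz = as.numeric(frame_rate_hz),
                 source_id = as.character(source_id)),
            class = "image_sequence")
}

#' @rdname image_sequence
#' @param x An `"image_sequence"`.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "image_sequence"))
  dim(x$frames)[3]
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Image sequence '%s': %d frames of %dx%d at %.1f Hz\n",
              x$source_id, d[3], d[1], d[2], x$frame_rate_hz))
  cat(sprintf("  intensity range [%.3g, %.3g]\n", min(x$frames),
              max(x$frames)))
  invisible(x)
}

#' Per-frame time stamps in seconds
#'
#' @param x An `"image_sequence"`.
#' @return Numeric vector of length F: `(0:(F-1)) / frame_rate_hz`.
#' @export
frame_times <- function(x) {
  stopifnot(inherits(x, "image_sequence"))
  (seq_len(n_frames(x)) - 1L) / x$frame_rate_hz
}

# coerce one decoded image (possibly RGB(A) in [0,1]) to a float grayscale
# matrix on the 0-255 scale
.to_gray <- function(img, what) {
  if (length(dim(img)) == 3L) {
    ch <- dim(img)[3]
    rgb <- img[, , seq_len(min(ch, 3L)), drop = FALSE]
    if (dim(rgb)[3] > 1L) {
      rng <- max(abs(rgb - rgb[, , rep(1L, dim(rgb)[3])]))
      if (rng > 1e-9)
        stop(sprintf("%s is RGB with distinct channels; convert to grayscale first",
                     what), call. = FALSE)
    }
    img <- rgb[, , 1L]
  }
  img * 255
}

#' Read an image sequence from disk
#'
#' Accepts either a multi-page TIFF file or a directory of single-frame
#' PNG/TIFF files (frames ordered by lexicographic file name).  Frames are
#' coerced to float grayscale on the 0-255 scale; RGB images are rejected
#' unless all channels are identical.
#'
#' @param path Path to a `.tif`/`.tiff` file or a directory of frames.
#' @param frame_rate_hz Frame rate to attach (Hz).
#' @param source_id Label; defaults to the file/directory name.
#' @return An [image_sequence()].
#' @export
read_sequence <- function(path, frame_rate_hz = 78.6, source_id = NULL) {
  if (is.null(source_id)) source_id <- basename(path)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) < 2L)
      stop(sprintf("directory '%s' holds fewer than 2 frame images", path),
           call. = FALSE)
    frames <- lapply(files, function(f) {
      img <- if (grepl("\\.png$", f, ignore.case = TRUE))
        png::readPNG(f) else tiff::readTIFF(f)
      .to_gray(img, f)
    })
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    frames <- lapply(pages, .to_gray, what = path)
  }
  image_sequence(frames, frame_rate_hz = frame_rate_hz,
                 source_id = source_id)
}

#' Write an image sequence as a multi-page TIFF
#'
#' Intensities are stored as 32-bit float on the 0-1 scale (divided by 255),
#' so the sequence round-trips through [read_sequence()].
#'
#' @param x An [image_sequence()].
#' @param path Output `.tiff` path.
#' @return `path`, invisibly.
#' @export
write_sequence_tiff <- function(x, path) {
  stopifnot(inherits(x, "image_sequence"))
  pages <- lapply(seq_len(n_frames(x)),
                  function(f) x$frames[, , f] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}
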