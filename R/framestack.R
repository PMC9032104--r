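#' Ordered stack of grayscale frames
#'
#' The raw substrate for all video analyses: an ordered set of 2-D grayscale
#' frames with a fixed acquisition rate and, optionally, a physical pixel
#' size. Frames are stored as a 3-D array indexed `[row, col, frame]`
#' (row-major, row = y).
#'
#' @param frames A 3-D numeric array `h x w x n` or a list of equally sized
#'   numeric matrices.
#' @param fps Frames per second; must be positive.
#' @param pixel_size Optional physical length of one pixel (e.g. mm/px).
#' @return A `frame_stack` object.
#' @export
frame_stack <- function(frames, fps, pixel_size = NULL) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1) stop("all frames must have the same shape")
    frames <- array(unlist(frames), dim = c(dims[[1]], length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3)
    stop("frames must be a h x w x n array or list of matrices")
  if (dim(frames)[3] < 2) stop("a frame stack needs at least 2 frames")
  if (!is.numeric(fps) || length(fps) != 1 || fps <= 0) stop("fps must be a positive scalar")
  if (!is.null(pixel_size) && (!is.numeric(pixel_size) || pixel_size <= 0))
    stop("pixel_size must be positive")
  structure(
    list(frames = frames, fps = fps, pixel_size = pixel_size),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames of %d x %d px, %.6g fps (%.3g s)",
              d[3], d[1], d[2], x$fps, d[3] / x$fps))
  if (!is.null(x$pixel_size)) cat(sprintf(", pixel size %.4g", x$pixel_size))
  cat("\n")
  invisible(x)
}

n_frames <- function(stack) dim(stack$frames)[3]
frame_dim <- function(stack) dim(stack$frames)[1:2]

#' Read a multi-page TIFF as a frame stack
#'
#' @param path Path to a grayscale multi-page TIFF.
#' @param fps Frames per second of the recording (TIFF carries no rate).
#' @param pixel_size Optional physical pixel size.
#' @return A [frame_stack()].
#' @export
read_frame_stack <- function(path, fps, pixel_size = NULL) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("reading TIFF stacks requires the 'tiff' package")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  frame_stack(pages, fps = fps, pixel_size = pixel_size)
}

#' Write a frame stack to a multi-page TIFF
#'
#' Intensities are clamped to `[0, 1]` for storage.
#'
#' @param stack A [frame_stack()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("writing TIFF stacks requires the 'tiff' package")
  stopifnot(inherits(stack, "frame_stack"))
  pages <- lapply(seq_len(n_frames(stack)),
                  function(k) clamp(stack$frames[, , k], 0, 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}
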