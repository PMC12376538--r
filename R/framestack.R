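#' Frame stack container
#'
#' A \code{FrameStack} holds an ordered sequence of 2D grayscale frames
#' together with the acquisition metadata the pipeline needs: the time
#' between frames and the physical pixel size. The \code{stage} tag records
#' which pipeline stage produced the stack (\code{"raw"}, \code{"averaged"},
#' \code{"normalized"} or \code{"differential"}).
#'
#' @param pixels numeric 3D array with dimensions (frame, row, col).
#' @param frame_interval seconds between consecutive frames; must be > 0.
#' @param pixel_size physical pixel size in nm (metadata only).
#' @param stage pipeline stage label.
#' @return An object of class \code{FrameStack}.
#' @export
frame_stack <- function(pixels, frame_interval, pixel_size = NA_real_,
                        stage = c("raw", "averaged", "normalized", "differential")) {
  stage <- match.arg(stage)
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    stop("pixels must be a 3D array (frame, row, col)")
  if (dim(pixels)[1] < 1L) stop("stack must contain at least one frame")
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      !is.finite(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be a single positive number")
  structure(
    list(pixels = pixels, frame_interval = frame_interval,
         pixel_size = pixel_size, stage = stage),
    class = "FrameStack"
  )
}

#' @export
print.FrameStack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("FrameStack [%s]: %d frames of %d x %d px, dt = %g s\n",
              x$stage, d[1], d[2], d[3], x$frame_interval))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack a \code{FrameStack}.
#' @return integer frame count.
#' @export
n_frames <- function(stack) dim(stack$pixels)[1]

#' Extract one frame as a matrix
#' @param stack a \code{FrameStack}.
#' @param i frame index (1-based).
#' @return numeric matrix (row, col).
#' @export
get_frame <- function(stack, i) {
  stopifnot(i >= 1L, i <= n_frames(stack))
  matrix(stack$pixels[i, , ], nrow = dim(stack$pixels)[2])
}
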