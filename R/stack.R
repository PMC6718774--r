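#' Time-lapse fluorescence image stack
#'
#' An `image_stack` is the in-memory representation of a calcium-imaging
#' movie: a numeric 3-D array of intensities indexed `[row, col, frame]`,
#' together with the temporal calibration (`fps`, frames per second) and the
#' spatial calibration (`um_per_px`, micrometers per pixel). Intensities are
#' non-negative reals on whatever scale the source data used (raw camera
#' counts for 8/16-bit files); downstream segmentation normalizes scale
#' internally, so no bit-depth normalization is applied on construction.
#'
#' @param frames Numeric 3-D array `[row, col, frame]`, or a list of equally
#'   sized numeric matrices (stacked in list order).
#' @param fps Frame rate in frames per second; must be `> 0`.
#' @param um_per_px Pixel size in micrometers; must be `> 0`.
#'
#' @return An object of class `image_stack`.
#' @examples
#' frames <- replicate(4, matrix(runif(64), 8, 8), simplify = FALSE)
#' stk <- image_stack(frames, fps = 10, um_per_px = 2)
#' n_frames(stk)
#' @export
image_stack <- function(frames, fps = 1, um_per_px = 1) {
  if (is.list(frames)) {
    if (length(frames) == 0L) abort("`frames` must contain at least one frame.")
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L || is.null(dims[[1]])) {
      abort("All frames must be matrices with identical dimensions.")
    }
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1]], length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    abort("`frames` must be a 3-D array [row, col, frame] or a list of matrices.")
  }
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0) {
    abort("`fps` must be a single positive number.")
  }
  if (!is.numeric(um_per_px) || length(um_per_px) != 1L ||
      !is.finite(um_per_px) || um_per_px <= 0) {
    abort("`um_per_px` must be a single positive number.")
  }
  storage.mode(frames) <- "double"
  structure(frames, fps = fps, um_per_px = um_per_px,
            class = c("image_stack", "array"))
}

#' Number of frames in an image stack
#' @param stack An [image_stack()].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) dim(stack)[3L]

#' Extract one frame from a stack
#' @param stack An [image_stack()].
#' @param i Frame index (1-based).
#' @return A numeric matrix.
#' @export
get_frame <- function(stack, i) {
  nf <- n_frames(stack)
  if (!is.numeric(i) || length(i) != 1L || i < 1 || i > nf || i != floor(i)) {
    abort(sprintf("Frame index must be an integer in [1, %d].", nf))
  }
  stack[, , i]
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<image_stack> %d x %d px, %d frame(s), %g fps, %g um/px\n",
              d[1], d[2], d[3], attr(x, "fps"), attr(x, "um_per_px")))
  invisible(x)
}
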