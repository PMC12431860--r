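#' Frame stack: a time-ordered single-channel image stack
#'
#' Thin container for a `(t, y, x)` array of pixel intensities plus its
#' [pixel_calibration()]. A single 2-D image is promoted to a one-frame stack.
#' The coordinate convention throughout the package is 0-based pixel centres
#' with y increasing downward: pixel `[row r, col c]` sits at
#' `(x, y) = (c - 1, r - 1)`.
#'
#' @param data Numeric array, either 2-D `(y, x)` or 3-D `(t, y, x)`.
#' @param calibration A [pixel_calibration()].
#' @return A `frame_stack` object (list with `data` and `calibration`).
#' @export
frame_stack <- function(data, calibration) {
  stopifnot(inherits(calibration, "pixel_calibration"))
  if (is.matrix(data)) data <- array(data, dim = c(1, dim(data)))
  if (!is.array(data) || length(dim(data)) != 3)
    stop("data must be a 2-D matrix or a 3-D (t, y, x) array")
  if (any(!is.finite(data))) stop("frame stack contains non-finite pixels")
  structure(list(data = data, calibration = calibration),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("frame_stack: %d frame(s) of %d x %d px, %g %s/px\n",
              d[1], d[2], d[3],
              x$calibration$pixel_size, x$calibration$space_unit))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack A [frame_stack()].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  dim(stack$data)[1]
}

#' Acquisition time of each frame
#'
#' Frame `i` is assigned time `(i - 1) * frame_interval` in the calibration's
#' time unit.
#' @param stack A [frame_stack()].
#' @return Numeric vector of frame times.
#' @export
frame_times <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  (seq_len(n_frames(stack)) - 1) * stack$calibration$frame_interval
}

#' Extract one frame as a matrix
#' @param stack A [frame_stack()].
#' @param i Frame index (1-based).
#' @return `(y, x)` matrix.
#' @export
get_frame <- function(stack, i) {
  stopifnot(inherits(stack, "frame_stack"),
            i >= 1, i <= n_frames(stack))
  stack$data[i, , ]
}
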