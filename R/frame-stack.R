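#' Construct a frame stack
#'
#' A `frame_stack` holds an ordered grayscale time-lapse as an H x W x T
#' array of intensities in \eqn{[0, 1]} together with its frame rate. It is
#' the substrate for all contractility analysis.
#'
#' @param frames Numeric H x W x T array (or a list of equal-shaped matrices)
#'   with values in \eqn{[0, 1]}.
#' @param fps Frame rate in frames per second.
#' @param origin Provenance tag, `"synthetic"` or `"file"`.
#' @return An object of class `frame_stack` with elements `frames`, `fps`,
#'   `origin`.
#' @export
frame_stack <- function(frames, fps, origin = "synthetic") {
  if (is.list(frames)) {
    shapes <- vapply(frames, function(f) paste(dim(f) %||% length(f), collapse = "x"),
                     character(1))
    if (length(unique(shapes)) != 1L) {
      stop_classed("format_error", "all frames must have the same shape")
    }
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dim(frames[[1]]), length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop_classed("format_error", "`frames` must be an H x W x T array")
  }
  if (dim(frames)[3] < 2L) {
    stop_classed("format_error", "a frame stack needs at least 2 frames")
  }
  check_number(fps, "fps", min = 0, strict_min = TRUE)
  if (anyNA(frames) || min(frames) < 0 || max(frames) > 1 + 1e-12) {
    stop_classed("format_error", "frame intensities must lie in [0, 1]")
  }
  structure(list(frames = frames, fps = fps, origin = origin),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames of %d x %d px at %g fps (%s)\n",
              d[3], d[1], d[2], x$fps, x$origin))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack A `frame_stack`.
#' @return Integer frame count.
#' @export
n_frames <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  dim(stack$frames)[3]
}

#' Read a grayscale time-lapse stack from a multi-page TIFF
#'
#' Frames are normalized to \eqn{[0, 1]} by the container's bit-depth maximum
#' (8/16-bit integer pages) or taken as-is for float pages, so movement
#' indices are comparable across sources. Page order is preserved.
#'
#' @param path Path to a multi-page grayscale TIFF.
#' @param fps Frame rate in frames per second (TIFF carries no standard rate
#'   tag, so it must be supplied).
#' @return A [frame_stack()] with `origin = "file"`.
#' @export
read_stack <- function(path, fps) {
  if (missing(fps)) {
    stop_classed("configuration_error", "`fps` must be supplied when reading a stack")
  }
  if (!file.exists(path)) {
    stop_classed("io_error", "no such file: %s", path)
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L) {
    stop_classed("format_error", "stack at %s has fewer than 2 frames", path)
  }
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1] # collapse replicated gray channels
    p
  })
  frame_stack(pages, fps = fps, origin = "file")
}

#' Write a frame stack to a multi-page TIFF
#'
#' Uses a 32-bit container so that a write-then-read round trip preserves
#' intensities to better than 1e-9.
#'
#' @param stack A [frame_stack()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  pages <- lapply(seq_len(d[3]), function(t) stack$frames[, , t])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}
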