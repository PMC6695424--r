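#' Per-frame motion activity trace
#'
#' Reduces a stack to a scalar activity signal: `a[1] = 0` and, for `t >= 2`,
#' `a[t]` is the mean absolute pixel difference between frame `t` and frame
#' `t - 1`. Peaks of this trace mark contraction events; it is used to anchor
#' the frame pairing at the first maximum-contraction frame.
#'
#' @param stack A [frame_stack()].
#' @return Numeric vector of length `n_frames(stack)`.
#' @export
motion_trace <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  f <- stack$frames
  T <- dim(f)[3]
  npx <- dim(f)[1] * dim(f)[2]
  a <- numeric(T)
  for (t in 2:T) {
    a[t] <- sum(abs(f[, , t] - f[, , t - 1])) / npx
  }
  a
}

# Centered moving average with edge replication; width forced to the nearest
# odd integer >= width so the window is symmetric.
smooth_trace <- function(a, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width == 1L) return(a)
  half <- (width - 1L) %/% 2L
  padded <- c(rep(a[1], half), a, rep(a[length(a)], half))
  as.numeric(stats::filter(padded, rep(1 / width, width), sides = 2))[
    (half + 1):(half + length(a))]
}

#' Locate the first maximum-contraction frame
#'
#' The pairing of contraction and relaxation frames is anchored at the first
#' maximum-contraction image. Operationally: the activity trace is smoothed
#' with a centered moving average of width `round(fps / (4 * stim_freq_hz))`
#' frames (rounded up to odd), and the first local maximum whose height above
#' the trace median reaches `prominence_frac` of the maximum-minus-median
#' range is returned. Ties and plateaus resolve to the earliest frame.
#'
#' @param trace Activity trace from [motion_trace()].
#' @param fps Frame rate, frames/second.
#' @param stim_freq_hz Stimulation frequency, Hz.
#' @param prominence_frac Fraction of `max(a) - median(a)` a peak must rise
#'   above the median to count (default 0.25).
#' @return Integer frame index (1-based) of the first maximum contraction.
#'   Signals a condition of class `no_contraction_error` when no peak
#'   qualifies (a non-contractile field); [movement_index()] catches it and
#'   anchors at frame 1 with a `non_contractile` flag.
#' @export
find_first_max_contraction <- function(trace, fps, stim_freq_hz = 1,
                                       prominence_frac = 0.25) {
  check_number(fps, "fps", min = 0, strict_min = TRUE)
  check_number(stim_freq_hz, "stim_freq_hz", min = 0, strict_min = TRUE)
  if (length(trace) < fps / stim_freq_hz) {
    stop_classed("parameter_error",
                 "trace must cover at least one stimulation period")
  }
  sm <- smooth_trace(trace, round_half_up(fps / (4 * stim_freq_hz)))
  n <- length(sm)
  med <- stats::median(sm)
  rng <- max(sm) - med
  if (rng <= 0) {
    stop_classed("no_contraction_error",
                 "activity trace is flat: no contraction peak detected")
  }
  threshold <- med + prominence_frac * rng
  # local maxima over runs of equal values; a plateau counts once, at its
  # earliest frame, and only if the trace falls (or ends) after it
  runs <- rle(sm)
  run_start <- cumsum(c(1L, runs$lengths[-length(runs$lengths)]))
  v <- runs$values
  for (j in seq_along(v)) {
    up <- j > 1L && v[j] > v[j - 1L]
    down <- j == length(v) || v[j] > v[j + 1L]
    if (up && down && v[j] >= threshold) return(run_start[j])
  }
  stop_classed("no_contraction_error",
               "no activity peak reached the prominence threshold")
}

#' Pair contraction and relaxation frames
#'
#' Starting from the first maximum-contraction frame, one contraction frame
#' is taken per stimulation cycle over the analysis window, and each is
#' paired with the frame half a period later (the relaxation state). With
#' 1-based frame indices: `contraction_k = start_index + round(k * fps /
#' stim_freq_hz)` for `k = 0 .. floor(window_s * stim_freq_hz) - 1`, and
#' `relaxation_k = contraction_k + round(fps / (2 * stim_freq_hz))` (halves
#' round up). Pairs extending past the last frame are dropped.
#'
#' @param start_index 1-based index of the first maximum-contraction frame.
#' @param fps Frame rate, frames/second.
#' @param stim_freq_hz Stimulation frequency, Hz.
#' @param window_s Analysis window in seconds (conventionally 3-5).
#' @param n_frames Total frames available.
#' @return An object of class `frame_pairing`: list with `start_index`,
#'   `pairs` (data.frame of `contraction`/`relaxation` indices), `window_s`,
#'   `stim_freq_hz`, `fps`. Signals `insufficient_frames_error` when no
#'   complete pair fits.
#' @export
pair_frames <- function(start_index, fps, stim_freq_hz = 1, window_s = 3,
                        n_frames) {
  check_number(start_index, "start_index", min = 1)
  check_number(window_s, "window_s", min = 0, strict_min = TRUE)
  check_number(n_frames, "n_frames", min = 2)
  if (start_index > n_frames) {
    stop_classed("parameter_error", "start_index exceeds the frame count")
  }
  n_cycles <- floor(window_s * stim_freq_hz)
  if (n_cycles < 1) {
    stop_classed("parameter_error",
                 "window_s must cover at least one stimulation cycle")
  }
  k <- 0:(n_cycles - 1)
  contraction <- start_index + round_half_up(k * fps / stim_freq_hz)
  relaxation <- contraction + round_half_up(fps / (2 * stim_freq_hz))
  keep <- relaxation <= n_frames & contraction <= n_frames
  if (!any(keep)) {
    stop_classed("insufficient_frames_error",
                 "no complete contraction/relaxation pair fits in %d frames",
                 n_frames)
  }
  structure(list(
    start_index = as.integer(start_index),
    pairs = data.frame(contraction = as.integer(contraction[keep]),
                       relaxation = as.integer(relaxation[keep])),
    window_s = window_s, stim_freq_hz = stim_freq_hz, fps = fps
  ), class = "frame_pairing")
}

#' Differential image of a contraction/relaxation pair
#'
#' Subtracts the relaxation image from the contraction image pixelwise. The
#' intensity difference between the two states is caused by displaced
#' scattering objects, so by default the magnitude `|contraction -
#' relaxation|` is taken (signed differences of opposite-moving edges would
#' cancel in the mean); `signed = TRUE` keeps the raw difference.
#'
#' @param stack A [frame_stack()].
#' @param contraction,relaxation 1-based frame indices.
#' @param signed Keep the sign of the subtraction (default `FALSE`).
#' @return H x W numeric matrix (non-negative unless `signed`).
#' @export
differential_image <- function(stack, contraction, relaxation, signed = FALSE) {
  stopifnot(inherits(stack, "frame_stack"))
  T <- n_frames(stack)
  if (contraction < 1 || contraction > T || relaxation < 1 || relaxation > T) {
    stop_classed("parameter_error", "frame index out of range [1, %d]", T)
  }
  d <- stack$frames[, , contraction] - stack$frames[, , relaxation]
  if (signed) d else abs(d)
}

#' Overlay per-pair differential images
#'
#' Combines the per-cycle differential images into one map of the moving
#' parts of the field. The default is the pixelwise mean, which makes the
#' movement index equal to the mean of the per-pair indices and insensitive
#' to the window length in expectation; `method = "max"` takes the pixelwise
#' maximum instead (a "union of moving parts" rendering).
#'
#' @param diff_images List of equal-shaped matrices from
#'   [differential_image()].
#' @param method `"mean"` (default) or `"max"`.
#' @return H x W numeric matrix.
#' @export
overlay_diffs <- function(diff_images, method = c("mean", "max")) {
  method <- match.arg(method)
  if (!is.list(diff_images) || length(diff_images) == 0L) {
    stop_classed("parameter_error", "need at least one differential image")
  }
  shapes <- vapply(diff_images, function(d) paste(dim(d), collapse = "x"),
                   character(1))
  if (length(unique(shapes)) != 1L) {
    stop_classed("parameter_error", "differential images differ in shape")
  }
  out <- diff_images[[1]]
  if (length(diff_images) > 1L) {
    for (d in diff_images[-1]) {
      out <- if (method == "mean") out + d else pmax(out, d)
    }
  }
  if (method == "mean") out <- out / length(diff_images)
  out
}

#' Movement index of a myotube field
#'
#' The scalar contractility readout of a time-lapse stack, computed by
#' differential image subtraction: locate the first maximum-contraction
#' frame on the motion trace, pair one contraction frame per stimulation
#' cycle with its half-period-later relaxation frame over the analysis
#' window, subtract each pair, overlay the differential images, and average
#' the overlay over all pixels. The index is dimensionless, in the intensity
#' units of the (bit-depth-normalized) input; larger means more movement.
#'
#' When no contraction peak is detected (a static or non-contractile field),
#' the same chain is anchored at frame 1 and the result is flagged
#' `non_contractile` rather than failing, so poorly contracting cultures
#' still report their (low) index.
#'
#' @param stack A [frame_stack()].
#' @param stim_freq_hz Stimulation frequency, Hz.
#' @param window_s Analysis window, seconds (default 3).
#' @param signed Use signed subtraction (default `FALSE`, see
#'   [differential_image()]).
#' @param overlay Overlay method, `"mean"` or `"max"`.
#' @param prominence_frac Peak-detection prominence fraction, see
#'   [find_first_max_contraction()].
#' @param field_id Optional label carried into summaries.
#' @return Object of class `movement_result`: `movement_index`, `overlay`
#'   matrix, `diff_images`, `per_pair_index`, `pairing`, `non_contractile`
#'   flag, `field_id`.
#' @export
movement_index <- function(stack, stim_freq_hz = 1, window_s = 3,
                           signed = FALSE, overlay = c("mean", "max"),
                           prominence_frac = 0.25, field_id = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  overlay <- match.arg(overlay)
  trace <- motion_trace(stack)
  non_contractile <- FALSE
  start <- tryCatch(
    find_first_max_contraction(trace, stack$fps, stim_freq_hz,
                               prominence_frac = prominence_frac),
    no_contraction_error = function(e) {
      non_contractile <<- TRUE
      1L
    }
  )
  pairing <- pair_frames(start, stack$fps, stim_freq_hz, window_s,
                         n_frames(stack))
  diffs <- lapply(seq_len(nrow(pairing$pairs)), function(i) {
    differential_image(stack, pairing$pairs$contraction[i],
                       pairing$pairs$relaxation[i], signed = signed)
  })
  ov <- overlay_diffs(diffs, method = overlay)
  structure(list(
    movement_index = mean(ov),
    overlay = ov,
    diff_images = diffs,
    per_pair_index = vapply(diffs, mean, numeric(1)),
    pairing = pairing,
    non_contractile = non_contractile,
    field_id = field_id
  ), class = "movement_result")
}

#' @export
print.movement_result <- function(x, ...) {
  cat(sprintf("<movement_result>%s MI = %.6g over %d pairs%s\n",
              if (is.null(x$field_id)) "" else paste0(" [", x$field_id, "]"),
              x$movement_index, nrow(x$pairing$pairs),
              if (x$non_contractile) " (non-contractile)" else ""))
  invisible(x)
}

#' Summarize movement indices over fields
#'
#' Contractility of a culture condition is evaluated over several microscopy
#' fields (conventionally three); this reduces the per-field indices to mean
#' +/- standard error.
#'
#' @param results List of [movement_index()] results, or a numeric vector of
#'   per-field indices.
#' @return Object of class `field_summary`: `fields` data.frame (`field_id`,
#'   `movement_index`, `non_contractile`), `mean`, `se` (NA for a single
#'   field), `n_fields`.
#' @export
summarize_fields <- function(results) {
  if (is.numeric(results)) {
    mi <- results
    ids <- names(results) %||% paste0("field_", seq_along(results))
    nc <- rep(NA, length(results))
  } else {
    if (!is.list(results) || length(results) == 0L ||
        !all(vapply(results, inherits, logical(1), "movement_result"))) {
      stop_classed("parameter_error",
                   "`results` must be movement_result objects or a numeric vector")
    }
    mi <- vapply(results, function(r) r$movement_index, numeric(1))
    ids <- vapply(seq_along(results), function(i) {
      results[[i]]$field_id %||% paste0("field_", i)
    }, character(1))
    nc <- vapply(results, function(r) r$non_contractile, logical(1))
  }
  if (length(mi) == 0L) stop_classed("parameter_error", "no fields to summarize")
  structure(list(
    fields = data.frame(field_id = ids, movement_index = mi,
                        non_contractile = nc),
    mean = mean(mi),
    se = standard_error(mi),
    n_fields = length(mi)
  ), class = "field_summary")
}

#' @export
print.field_summary <- function(x, ...) {
  cat(sprintf("<field_summary> n = %d fields: MI = %.6g +/- %s (mean +/- SE)\n",
              x$n_fields, x$mean,
              if (is.na(x$se)) "NA" else sprintf("%.6g", x$se)))
  invisible(x)
}
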