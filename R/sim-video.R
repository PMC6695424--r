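#' Configuration for the synthetic twitching-myotube video generator
#'
#' Bundles and validates the parameters of [simulate_myotube_field()]. The
#' defaults emulate the standard contractility imaging protocol: 1 Hz field
#' stimulation recorded at 14.4 frames per second over a desk-scale
#' 256 x 256 px field containing 5 myotubes. Stimulation voltage and pulse
#' width are carried as metadata only; no electric-field physics is modeled.
#'
#' @param width_px,height_px Field size in pixels.
#' @param fps Frame rate, frames/second.
#' @param stim_freq_hz Stimulation frequency, Hz.
#' @param duration_s Video duration, seconds.
#' @param n_myotubes Number of myotube ribbons placed in the field.
#' @param amplitude_px Peak longitudinal displacement in pixels; a scalar or
#'   one value per myotube (recycled).
#' @param twitch_rise_s,twitch_decay_s Twitch kinetics, see
#'   [simulate_twitch_trace()].
#' @param noise_sd Standard deviation of additive Gaussian intensity noise
#'   (applied after warping, then clipped to \eqn{[0, 1]}).
#' @param baseline Background intensity in \eqn{[0, 1]}.
#' @param seed Integer RNG seed (mandatory; simulators never use global
#'   RNG state).
#' @param pulse_width_ms,voltage_v,electrode_gap_mm Stimulation metadata,
#'   recorded in the truth sidecar but not used in the image model.
#' @return A validated list of class `video_sim_config`.
#' @export
video_sim_config <- function(width_px = 256, height_px = 256, fps = 14.4,
                             stim_freq_hz = 1.0, duration_s = 5,
                             n_myotubes = 5, amplitude_px = 3,
                             twitch_rise_s = 0.1, twitch_decay_s = 0.3,
                             noise_sd = 0.01, baseline = 0.1, seed,
                             pulse_width_ms = 4, voltage_v = 20,
                             electrode_gap_mm = 25) {
  if (missing(seed)) stop_classed("parameter_error", "`seed` is mandatory")
  check_number(width_px, "width_px", min = 32)
  check_number(height_px, "height_px", min = 32)
  check_number(fps, "fps", min = 0, strict_min = TRUE)
  check_number(stim_freq_hz, "stim_freq_hz", min = 0, strict_min = TRUE)
  check_number(duration_s, "duration_s", min = 0, strict_min = TRUE)
  check_number(n_myotubes, "n_myotubes", min = 1)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(baseline, "baseline", min = 0, max = 1)
  if (fps <= 2 * stim_freq_hz) {
    stop_classed("parameter_error", "fps must exceed 2 * stim_freq_hz")
  }
  if (round_half_up(fps * duration_s) < 2) {
    stop_classed("parameter_error", "duration_s * fps must cover at least 2 frames")
  }
  if (!is.numeric(amplitude_px) || any(amplitude_px < 0) || anyNA(amplitude_px)) {
    stop_classed("parameter_error", "amplitude_px must be non-negative")
  }
  structure(list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    fps = fps, stim_freq_hz = stim_freq_hz, duration_s = duration_s,
    n_myotubes = as.integer(n_myotubes),
    amplitude_px = rep_len(as.numeric(amplitude_px), n_myotubes),
    twitch_rise_s = twitch_rise_s, twitch_decay_s = twitch_decay_s,
    noise_sd = noise_sd, baseline = baseline, seed = as.integer(seed),
    pulse_width_ms = pulse_width_ms, voltage_v = voltage_v,
    electrode_gap_mm = electrode_gap_mm
  ), class = "video_sim_config")
}

#' Simulate a field of twitching myotubes
#'
#' Renders a time-lapse stack of elongated bright "myotube" ribbons on a dark
#' background. Each ribbon contracts longitudinally toward its centroid by
#' `amplitude_px * s(t)` pixels, where `s(t)` is the twitch trace of
#' [simulate_twitch_trace()]; Gaussian noise is then added and intensities
#' are clipped to \eqn{[0, 1]}. Identical configurations (including the seed)
#' produce bit-identical stacks.
#'
#' Ribbons have a Gaussian cross-section and a smooth (logistic) longitudinal
#' edge, so sub-pixel displacements still produce graded frame differences,
#' as scattering objects do under brightfield imaging.
#'
#' @param config A [video_sim_config()].
#' @return A list with elements `stack` (a [frame_stack()]) and `truth` (a
#'   `sim_truth` list carrying the displacement trace `s(t)`, per-myotube
#'   binary masks, the planted amplitudes, ribbon geometry, and the seed).
#' @export
simulate_myotube_field <- function(config) {
  stopifnot(inherits(config, "video_sim_config"))
  s <- simulate_twitch_trace(config$fps, config$stim_freq_hz, config$duration_s,
                             config$twitch_rise_s, config$twitch_decay_s)
  H <- config$height_px; W <- config$width_px; T <- length(s)
  n <- config$n_myotubes

  with_seed(config$seed, {
    # ribbon geometry: kept fully inside the frame so contraction (inward
    # motion) can never move a myotube out of view
    half_len <- stats::runif(n, 0.12, 0.22) * min(W, H)
    sigma_v  <- stats::runif(n, 3, 6)
    theta    <- stats::runif(n, 0, pi)
    peak     <- stats::runif(n, 0.5, 0.8)
    margin_x <- abs(half_len * cos(theta)) + 8
    margin_y <- abs(half_len * sin(theta)) + 8
    if (any(margin_x * 2 >= W) || any(margin_y * 2 >= H)) {
      stop_classed("geometry_error", "field too small for the sampled myotubes")
    }
    cx <- stats::runif(n, margin_x, W - margin_x)
    cy <- stats::runif(n, margin_y, H - margin_y)
    amp <- config$amplitude_px
    if (any(amp >= half_len)) {
      stop_classed("parameter_error",
                   "amplitude_px (%g) reaches the myotube half-length (%g): the ribbon would collapse",
                   max(amp), min(half_len))
    }

    xg <- matrix(rep(seq_len(W), each = H), H, W)  # column index
    yg <- matrix(rep(seq_len(H), times = W), H, W) # row index
    edge <- 1.5 # px softness of the ribbon ends

    tubes <- vector("list", n)
    masks <- vector("list", n)
    for (i in seq_len(n)) {
      dx <- xg - cx[i]; dy <- yg - cy[i]
      u <- dx * cos(theta[i]) + dy * sin(theta[i])
      v <- -dx * sin(theta[i]) + dy * cos(theta[i])
      idx <- which(abs(u) <= half_len[i] + 8 & abs(v) <= 4 * sigma_v[i])
      tubes[[i]] <- list(
        idx = idx,
        u = u[idx],
        gv = peak[i] * exp(-v[idx]^2 / (2 * sigma_v[i]^2))
      )
      m <- matrix(FALSE, H, W)
      m[idx[abs(u[idx]) <= half_len[i] & abs(v[idx]) <= 2 * sigma_v[i]]] <- TRUE
      masks[[i]] <- m
    }

    frames <- array(config$baseline, dim = c(H, W, T))
    for (t in seq_len(T)) {
      fr <- frames[, , t]
      for (i in seq_len(n)) {
        scale <- (half_len[i] - amp[i] * s[t]) / half_len[i]
        u_src <- tubes[[i]]$u / scale
        contrib <- tubes[[i]]$gv /
          (1 + exp(-(half_len[i] - abs(u_src)) / edge))
        fr[tubes[[i]]$idx] <- fr[tubes[[i]]$idx] + contrib
      }
      frames[, , t] <- fr
    }
    if (config$noise_sd > 0) {
      frames <- frames + stats::rnorm(length(frames), sd = config$noise_sd)
    }
    frames <- pmin(pmax(frames, 0), 1)

    truth <- structure(list(
      displacement_trace = s,
      myotube_masks = masks,
      amplitude_px = amp,
      geometry = data.frame(cx = cx, cy = cy, theta = theta,
                            half_len = half_len, sigma_v = sigma_v,
                            peak = peak),
      fps = config$fps, stim_freq_hz = config$stim_freq_hz,
      seed = config$seed
    ), class = "sim_truth")

    list(stack = frame_stack(frames, fps = config$fps, origin = "synthetic"),
         truth = truth)
  })
}
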