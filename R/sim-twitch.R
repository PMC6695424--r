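#' Simulate a periodic twitch displacement trace
#'
#' Generates the per-frame displacement fraction \eqn{s(t) \in [0, 1]} of a
#' myotube twitching under periodic electric pulse stimulation. Each
#' stimulation cycle is modeled as a piecewise waveform: a linear rise from 0
#' to the peak over `twitch_rise_s` seconds, followed by an exponential
#' relaxation with time constant `twitch_decay_s`. The sampled trace is
#' rescaled so its maximum is exactly 1.
#'
#' @param fps Sampling rate in frames per second. Must exceed twice the
#'   stimulation frequency so that contraction and relaxation phases are
#'   resolvable.
#' @param stim_freq_hz Stimulation frequency in Hz (default 1, the standard
#'   twitch protocol for cultured myotubes).
#' @param duration_s Trace duration in seconds.
#' @param twitch_rise_s Time from stimulus to peak shortening, seconds.
#' @param twitch_decay_s Relaxation time constant, seconds. `twitch_rise_s +
#'   twitch_decay_s` must fit within one stimulation period.
#' @return Numeric vector of length `round(fps * duration_s)` with values in
#'   \eqn{[0, 1]}; element `i` is the displacement fraction at time
#'   `(i - 1) / fps` seconds.
#' @examples
#' s <- simulate_twitch_trace(fps = 14.4, duration_s = 5)
#' length(s) # 72 frames
#' s[1]      # 0 at cycle start
#' @export
simulate_twitch_trace <- function(fps, stim_freq_hz = 1, duration_s,
                                  twitch_rise_s = 0.1, twitch_decay_s = 0.3) {
  check_number(fps, "fps", min = 0, strict_min = TRUE)
  check_number(stim_freq_hz, "stim_freq_hz", min = 0, strict_min = TRUE)
  check_number(duration_s, "duration_s", min = 0, strict_min = TRUE)
  check_number(twitch_rise_s, "twitch_rise_s", min = 0, strict_min = TRUE)
  check_number(twitch_decay_s, "twitch_decay_s", min = 0, strict_min = TRUE)
  if (fps <= 2 * stim_freq_hz) {
    stop_classed("parameter_error",
                 "fps (%g) must exceed 2 * stim_freq_hz (%g) to resolve the twitch",
                 fps, stim_freq_hz)
  }
  period_s <- 1 / stim_freq_hz
  if (twitch_rise_s + twitch_decay_s > period_s) {
    stop_classed("parameter_error",
                 "twitch_rise_s + twitch_decay_s must fit within one period (%g s)",
                 period_s)
  }
  n <- round_half_up(fps * duration_s)
  if (n < 2) {
    stop_classed("parameter_error",
                 "duration_s * fps must cover at least 2 frames (got %d)", n)
  }
  t <- (seq_len(n) - 1) / fps
  phase <- t %% period_s
  s <- ifelse(phase < twitch_rise_s,
              phase / twitch_rise_s,
              exp(-(phase - twitch_rise_s) / twitch_decay_s))
  peak <- max(s)
  if (peak > 0) s <- s / peak
  s
}
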