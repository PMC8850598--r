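#' Simulate a speed-modulated theta LFP
#'
#' Generates an LFP whose instantaneous frequency is
#' `base_frequency + speed_gain * speed(t)` (speed linearly interpolated
#' from the trajectory), with additive Gaussian noise. With zero gain and
#' zero noise the output is a pure sinusoid at the base frequency.
#'
#' @param traj a `trajectory` with speed
#' @param base_frequency baseline theta frequency, Hz (< Nyquist)
#' @param speed_gain frequency gain, Hz per cm/s
#' @param amplitude oscillation amplitude, arbitrary units
#' @param noise_sd additive Gaussian noise SD, same units
#' @param lfp_rate sampling rate, Hz
#' @param seed RNG seed
#' @return an [lfp_trace()] spanning the trajectory
#' @export
simulate_lfp <- function(traj, base_frequency = 8, speed_gain = 0.04,
                         amplitude = 1, noise_sd = 0.2, lfp_rate = 500,
                         seed = NULL) {
  if (base_frequency <= 0 || base_frequency >= lfp_rate / 2) {
    stop_invalid("base_frequency must be in (0, lfp_rate/2)")
  }
  if (!is.finite(speed_gain)) stop_invalid("speed_gain must be finite")
  t0 <- traj$t[1]
  dur <- traj_duration(traj)
  n <- floor(dur * lfp_rate)
  tt <- t0 + (seq_len(n) - 1) / lfp_rate
  speed <- stats::approx(traj$t, traj$speed, tt, rule = 2)$y
  f_inst <- base_frequency + speed_gain * speed
  phase <- 2 * pi * cumsum(f_inst) / lfp_rate
  noise <- if (noise_sd > 0) {
    with_seed(seed, stats::rnorm(n, 0, noise_sd))
  } else numeric(n)
  lfp_trace(amplitude * sin(phase) + noise, rate = lfp_rate, t0 = t0)
}
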