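# Morlet wavelet power of a signal at one frequency (FFT implementation,
# omega0 cycles). Returns |W(t)|^2 at every sample.
.morlet_power1 <- function(xf, n, rate, f0, omega0 = 6) {
  # frequency axis of the length-n FFT
  fk <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * rate / n
  s <- omega0 / (2 * pi * f0)
  # analytic Morlet in the frequency domain (positive frequencies only)
  H <- sqrt(2 * pi * s * rate) * exp(-0.5 * (2 * pi * s * (fk - f0))^2)
  H[fk < 0] <- 0
  w <- stats::fft(xf * H, inverse = TRUE) / n
  Mod(w)^2
}

#' Theta-by-speed spectrogram of the LFP
#'
#' Wavelet power between 1 and 15 Hz (Morlet, 0.25 Hz frequency steps) is
#' computed for every LFP sample; each sample's spectrum is normalized by
#' its delta-band (2-4 Hz) power and assigned to the concurrent
#' running-speed bin (2 cm/s bins from 2 to 30 cm/s). Per speed bin the
#' normalized spectra are averaged; theta power is the mean relative
#' power between 7 and 12 Hz, and theta frequency is the frequency of
#' peak power per speed bin (the discrete 5-15 Hz argmax refined by
#' quadratic interpolation of log power). Speed bins with less than
#' `min_bin_time` seconds of data are flagged invalid.
#'
#' @param lfp an `lfp_trace`
#' @param traj a time-aligned `trajectory` with speed
#' @param freqs frequency grid, Hz
#' @param speed_breaks speed bin edges, cm/s
#' @param omega0 Morlet width parameter (cycles)
#' @param min_bin_time minimum data per speed bin, s
#' @return a `speed_spectrogram`: `freqs`, `speed_centers`, `rel_power`
#'   (freq x speed matrix), `theta_power_by_speed`, `theta_freq_by_speed`,
#'   `bin_time` (s per speed bin)
#' @export
theta_speed_spectrogram <- function(lfp, traj, freqs = seq(1, 15, by = 0.25),
                                    speed_breaks = seq(2, 30, by = 2),
                                    omega0 = 6, min_bin_time = 5) {
  if (max(freqs) >= lfp$rate / 2) stop_invalid("frequency grid exceeds Nyquist")
  x <- lfp$samples - mean(lfp$samples)
  n <- length(x)
  np <- stats::nextn(n)       # pad to a highly composite FFT length
  tt <- lfp_times(lfp)
  speed <- stats::approx(traj$t, traj$speed, tt, rule = 2)$y
  nb <- length(speed_breaks) - 1L
  sbin <- findInterval(speed, speed_breaks)
  sbin[sbin < 1 | sbin > nb] <- NA_integer_
  ok <- !is.na(sbin)
  bin_n <- tabulate(sbin[ok], nb)
  bin_time <- bin_n / lfp$rate
  xf <- stats::fft(c(x, numeric(np - n)))
  # pass 1: per-sample delta power (mean over 2-4 Hz)
  delta_f <- freqs[freqs >= 2 & freqs <= 4]
  delta <- numeric(n)
  for (f0 in delta_f) {
    delta <- delta + .morlet_power1(xf, np, lfp$rate, f0, omega0)[1:n]
  }
  delta <- delta / length(delta_f)
  delta[delta <= 0] <- NA_real_
  # pass 2: accumulate per-speed-bin mean relative power per frequency
  rel_power <- matrix(NA_real_, length(freqs), nb,
                      dimnames = list(freqs, NULL))
  for (k in seq_along(freqs)) {
    p <- .morlet_power1(xf, np, lfp$rate, freqs[k], omega0)[1:n]
    rp <- p / delta
    sums <- tapply(rp[ok], sbin[ok], sum, na.rm = TRUE)
    cnts <- tapply(is.finite(rp[ok]), sbin[ok], sum)
    rel_power[k, as.integer(names(sums))] <- sums / cnts
  }
  valid_bin <- bin_time >= min_bin_time
  rel_power[, !valid_bin] <- NA_real_
  theta_f <- freqs >= 7 & freqs <= 12
  theta_power <- colMeans(rel_power[theta_f, , drop = FALSE])
  band <- which(freqs >= 5 & freqs <= 15)
  theta_freq <- rep(NA_real_, nb)
  for (b in which(valid_bin)) {
    p <- rel_power[band, b]
    if (all(!is.finite(p))) next
    i <- which.max(p)
    f_hat <- freqs[band[i]]
    # quadratic refinement of the discrete argmax on log power
    if (i > 1 && i < length(band) && all(is.finite(p[(i - 1):(i + 1)]))) {
      lp <- log(p[(i - 1):(i + 1)])
      den <- lp[1] - 2 * lp[2] + lp[3]
      if (is.finite(den) && den < 0) {
        off <- 0.5 * (lp[1] - lp[3]) / den
        f_hat <- f_hat + max(-0.5, min(0.5, off)) * (freqs[2] - freqs[1])
      }
    }
    theta_freq[b] <- f_hat
  }
  centers <- (speed_breaks[-1] + speed_breaks[-length(speed_breaks)]) / 2
  structure(list(freqs = freqs, speed_centers = centers,
                 rel_power = rel_power,
                 theta_power_by_speed = theta_power,
                 theta_freq_by_speed = theta_freq,
                 bin_time = bin_time, valid_bin = valid_bin),
            class = "speed_spectrogram")
}

#' @export
print.speed_spectrogram <- function(x, ...) {
  cat(sprintf("speed_spectrogram: %d freqs x %d speed bins (%d valid)\n",
              length(x$freqs), length(x$speed_centers), sum(x$valid_bin)))
  invisible(x)
}

#' Fit the theta-frequency-versus-speed line
#'
#' Least-squares line through the per-speed-bin theta peak frequencies;
#' the slope is the theta frequency gain (Hz per cm/s) and the intercept
#' the baseline theta frequency.
#'
#' @param spec a `speed_spectrogram`
#' @return list: `intercept` (Hz), `slope` (Hz per cm/s)
#' @export
theta_speed_fit <- function(spec) {
  ok <- is.finite(spec$theta_freq_by_speed)
  if (sum(ok) < 3) stop_insufficient("need at least 3 valid speed bins")
  co <- stats::coef(stats::lm(spec$theta_freq_by_speed[ok] ~
                                spec$speed_centers[ok]))
  list(intercept = unname(co[1]), slope = unname(co[2]))
}

# First discrete prolate spheroidal (Slepian) taper of length n with
# time-bandwidth product nw, via the symmetric tridiagonal formulation.
dpss_taper <- function(n, nw = 3) {
  W <- nw / n
  d <- (((n - 1) - 2 * (0:(n - 1))) / 2)^2 * cos(2 * pi * W)
  e <- (1:(n - 1)) * ((n - 1):1) / 2
  A <- matrix(0, n, n)
  diag(A) <- d
  A[cbind(1:(n - 1), 2:n)] <- e
  A[cbind(2:n, 1:(n - 1))] <- e
  v <- eigen(A, symmetric = TRUE)$vectors[, 1]
  if (sum(v) < 0) v <- -v
  v / sqrt(sum(v^2))
}

#' Intrinsic theta frequency of a spike train
#'
#' The spike train is binned at 5 ms, its temporal autocorrelation
#' computed over +/- `max_lag` seconds, smoothed with a 2-bin-SD Gaussian
#' kernel, mean-subtracted, tapered (single Slepian), zero-padded to
#' `pad` (2^13) samples, and the periodogram taken. The intrinsic
#' frequency is the frequency of maximum power in the 6-12 Hz band.
#'
#' @param spikes a `spike_train` (needs >= `min_spikes` spikes)
#' @param bin autocorrelation bin width, s
#' @param max_lag autocorrelation half-window, s
#' @param smooth_sd_bins Gaussian smoothing SD, bins
#' @param pad FFT length after zero padding
#' @param band frequency band searched for the peak, Hz
#' @param min_spikes minimum spike count
#' @return an `intrinsic_frequency`: `autocorr` data frame (lag, value),
#'   `spectrum` data frame (freq, power), `peak_freq` (Hz),
#'   `peak_power`
#' @export
intrinsic_frequency <- function(spikes, bin = 0.005, max_lag = 1,
                                smooth_sd_bins = 2, pad = 8192,
                                band = c(6, 12), min_spikes = 100) {
  times <- if (inherits(spikes, "spike_train")) spikes$times else spikes
  if (length(times) < min_spikes) {
    stop_insufficient(sprintf("need >= %d spikes, got %d", min_spikes,
                              length(times)))
  }
  t0 <- min(times)
  cnt <- tabulate(floor((times - t0) / bin) + 1L)
  nlag <- round(max_lag / bin)
  # autocorrelation of the binned train via FFT
  m <- length(cnt)
  np <- stats::nextn(m + nlag, 2)
  cf <- stats::fft(c(cnt, numeric(np - m)))
  ac_full <- Re(stats::fft(cf * Conj(cf), inverse = TRUE)) / np
  ac_pos <- ac_full[1:(nlag + 1)]
  ac <- c(rev(ac_pos[-1]), ac_pos)
  lags <- seq(-nlag, nlag) * bin
  ac[lags == 0] <- 0                       # remove the self-count peak
  ac_s <- gauss_smooth1d(ac, smooth_sd_bins)
  ac_s <- ac_s - mean(ac_s)
  taper <- dpss_taper(length(ac_s), 3)
  xt <- ac_s * taper * sqrt(length(ac_s))  # keep amplitude scale
  X <- stats::fft(c(xt, numeric(pad - length(xt))))
  fs <- 1 / bin
  freq <- (0:(pad - 1)) * fs / pad
  half <- freq <= fs / 2
  spec <- data.frame(freq = freq[half], power = Mod(X[half])^2)
  in_band <- spec$freq >= band[1] & spec$freq <= band[2]
  i <- which(in_band)[which.max(spec$power[in_band])]
  structure(list(autocorr = data.frame(lag = lags, value = ac_s),
                 spectrum = spec,
                 peak_freq = spec$freq[i], peak_power = spec$power[i]),
            class = "intrinsic_frequency")
}

#' @export
print.intrinsic_frequency <- function(x, ...) {
  cat(sprintf("intrinsic_frequency: peak %.2f Hz\n", x$peak_freq))
  invisible(x)
}
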