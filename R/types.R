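#' Spike train container
#'
#' @param times spike times in seconds, sorted ascending
#' @param cell_id identifier
#' @param waveform_width trough-to-peak waveform width, ms (narrow < 0.3 ms
#'   marks putative interneurons)
#' @param region recording region, "MEC" or "CA1"
#' @return object of class `spike_train`
#' @export
spike_train <- function(times, cell_id = "cell", waveform_width = 0.4,
                        region = c("MEC", "CA1")) {
  region <- match.arg(region)
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = FALSE)) times <- sort(times)
  structure(list(times = times, cell_id = cell_id,
                 waveform_width = waveform_width, region = region),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("spike_train '%s' (%s): %d spikes", x$cell_id, x$region,
              length(x$times)))
  if (length(x$times)) {
    cat(sprintf(", %.1f-%.1f s", min(x$times), max(x$times)))
  }
  cat(sprintf(", width %.2f ms\n", x$waveform_width))
  invisible(x)
}

#' @export
length.spike_train <- function(x) length(x$times)

#' Local field potential trace
#'
#' @param samples LFP samples, arbitrary units
#' @param rate sampling rate, Hz (500 after downsampling)
#' @param t0 time of the first sample, s
#' @return object of class `lfp_trace`
#' @export
lfp_trace <- function(samples, rate = 500, t0 = 0) {
  if (rate <= 0) stop_invalid("lfp rate must be > 0")
  if (any(!is.finite(samples))) stop_invalid("lfp samples must be finite")
  structure(list(samples = as.numeric(samples), rate = rate, t0 = t0),
            class = "lfp_trace")
}

#' @export
print.lfp_trace <- function(x, ...) {
  cat(sprintf("lfp_trace: %d samples @ %g Hz (%.1f s)\n",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}

# times of the LFP samples
lfp_times <- function(lfp) lfp$t0 + (seq_along(lfp$samples) - 1) / lfp$rate

#' Construct a trajectory from components
#'
#' @param t,x,y,hd,speed equal-length vectors (s, cm, cm, degrees, cm/s)
#' @param arena optional `arena` geometry to attach
#' @return a `trajectory` data frame
#' @export
trajectory <- function(t, x, y, hd = NULL, speed = NULL, arena = NULL) {
  n <- length(t)
  if (length(x) != n || length(y) != n) stop_invalid("t, x, y lengths differ")
  if (is.unsorted(t, strictly = TRUE)) stop_invalid("t must be strictly increasing")
  if (is.null(hd)) hd <- rep(NA_real_, n)
  if (is.null(speed)) speed <- rep(NA_real_, n)
  if (any(speed < 0, na.rm = TRUE)) stop_invalid("speed must be >= 0")
  traj <- data.frame(t = t, x = x, y = y, hd = wrap360(hd), speed = speed)
  attr(traj, "arena") <- arena
  class(traj) <- c("trajectory", "data.frame")
  traj
}

# session duration (s) of a trajectory
traj_duration <- function(traj) traj$t[nrow(traj)] - traj$t[1]

# per-sample dwell times (s); last sample gets the median interval
traj_dt <- function(traj) {
  d <- diff(traj$t)
  c(d, stats::median(d))
}
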