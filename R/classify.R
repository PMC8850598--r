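#' Head-direction tuning curve and mean resultant length
#'
#' Head directions are collected into 6-degree bins; the rate in each bin
#' is the spike count divided by the time spent facing that direction.
#' Directional selectivity is the mean resultant length (MRL) of the
#' polar plot, |sum_j r_j e^{i theta_j}| / sum_j r_j over bin centers
#' theta_j with bin rates r_j. Empty-occupancy bins have undefined rates
#' and are excluded. Cells with MRL >= 0.21 qualify as head-direction
#' cells.
#'
#' @param traj a `trajectory` with head direction
#' @param spikes a `spike_train`
#' @param bin_width directional bin width, degrees
#' @param min_occupancy minimum time (s) facing a direction for its bin
#'   to be defined
#' @return a `polar_tuning`: `bin_centers` (deg), `rates` (Hz, NA where
#'   undefined), `mrl`, `peak_rate`, `mean_rate`
#' @export
polar_tuning <- function(traj, spikes, bin_width = 6, min_occupancy = 0) {
  if (all(is.na(traj$hd))) stop_invalid("trajectory has no head direction")
  nb <- round(360 / bin_width)
  breaks <- seq(0, 360, length.out = nb + 1)
  centers <- breaks[-1] - bin_width / 2
  dt <- traj_dt(traj)
  hb <- findInterval(wrap360(traj$hd), breaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  occ <- numeric(nb)
  agg <- tapply(dt[!is.na(hb)], hb[!is.na(hb)], sum)
  occ[as.integer(names(agg))] <- agg
  times <- if (inherits(spikes, "spike_train")) spikes$times else spikes
  cnt <- numeric(nb)
  if (length(times)) {
    si <- round(stats::approx(traj$t, seq_along(traj$t), times, rule = 2)$y)
    sb <- hb[pmax(1L, pmin(length(hb), si))]
    aggc <- tapply(rep(1, length(sb)), sb, sum)
    cnt[as.integer(names(aggc))] <- aggc
  }
  rates <- ifelse(occ > min_occupancy & occ > 0, cnt / occ, NA_real_)
  ok <- is.finite(rates)
  mrl <- if (sum(rates[ok]) > 0) {
    th <- deg2rad(centers[ok])
    Mod(sum(rates[ok] * exp(1i * th))) / sum(rates[ok])
  } else NA_real_
  structure(list(bin_centers = centers, rates = rates, occupancy = occ,
                 mrl = mrl,
                 peak_rate = suppressWarnings(max(rates, na.rm = TRUE)),
                 mean_rate = length(times) / sum(dt)),
            class = "polar_tuning")
}

#' @export
print.polar_tuning <- function(x, ...) {
  cat(sprintf("polar_tuning: MRL %.3f, peak %.2f Hz, mean %.2f Hz\n",
              x$mrl, x$peak_rate, x$mean_rate))
  invisible(x)
}

#' Shuffle null distribution for a tuning statistic
#'
#' Builds the chance distribution of a spatial/directional statistic by
#' circularly shifting all spike times in time by at least `min_shift`
#' seconds (uniform over \[min_shift, T - min_shift\], wrapped around the
#' session), recomputing the statistic for each of `n` shuffles, and
#' taking the 99th percentile (linear-interpolation percentile) as the
#' significance threshold. The unshuffled statistic is never part of the
#' null.
#'
#' @param traj a `trajectory`
#' @param spikes a `spike_train`
#' @param statistic "gridness", "mrl", or a function
#'   `f(traj, shifted_times)` returning a scalar
#' @param n number of shuffles
#' @param min_shift minimum time shift, s
#' @param seed RNG seed
#' @param probs percentile for the threshold
#' @param ... passed to the built-in statistic (e.g. `bin_size`)
#' @return a `shuffle_null`: `scores` (length n), `threshold`,
#'   `statistic_name`
#' @export
shuffle_null <- function(traj, spikes, statistic = c("gridness", "mrl"),
                         n = 50, min_shift = 30, seed = NULL, probs = 0.99,
                         ...) {
  if (n < 2) stop_invalid("shuffle_null needs n >= 2")
  T_ <- traj_duration(traj)
  if (T_ <= 2 * min_shift) {
    stop_invalid("session must be longer than twice min_shift")
  }
  times <- if (inherits(spikes, "spike_train")) spikes$times else spikes
  t0 <- traj$t[1]
  stat_name <- if (is.function(statistic)) "custom" else match.arg(statistic)
  if (is.function(statistic)) {
    stat_fn <- statistic
  } else if (stat_name == "gridness") {
    pre <- ratemap_precompute(traj, ...)
    stat_fn <- function(tr, ts) {
      m <- ratemap_from_precomp(pre, ts)
      sc <- tryCatch(gridness_score(spatial_autocorr(m)),
                     error = function(e) NULL)
      if (is.null(sc)) NA_real_ else sc$gridness
    }
  } else {
    stat_fn <- function(tr, ts) polar_tuning(tr, ts)$mrl
  }
  scores <- with_seed(seed, {
    shifts <- stats::runif(n, min_shift, T_ - min_shift)
    vapply(shifts, function(sh) {
      shifted <- ((times - t0 + sh) %% T_) + t0
      stat_fn(traj, sort(shifted))
    }, numeric(1))
  })
  structure(list(scores = scores,
                 threshold = percentile(scores, probs),
                 statistic_name = stat_name, n = n, probs = probs),
            class = "shuffle_null")
}

#' @export
print.shuffle_null <- function(x, ...) {
  cat(sprintf("shuffle_null (%s, n = %d): threshold %.3f (p%g)\n",
              x$statistic_name, x$n, x$threshold, 100 * x$probs))
  invisible(x)
}

#' Functional classification of an MEC cell
#'
#' Applies the fixed dataset-wide criteria: putative interneuron when the
#' waveform is narrow (< 0.3 ms) with mean rate >= 0.5 Hz (interneurons
#' are excluded from the spatial classes); grid cell when gridness >=
#' 0.54; head-direction cell when MRL >= 0.21 (a cell can be both grid
#' and head-direction, i.e. conjunctive); non-grid spatially tuned when
#' it did not qualify as a grid cell but has split-half reliability >=
#' 0.6; otherwise unclassified. Thresholds may be replaced by per-dataset
#' shuffle thresholds.
#'
#' @param metrics named list or data frame row with `gridness`, `mrl`,
#'   `split_half`, `width_ms`, `mean_rate`
#' @param gridness_threshold,mrl_threshold,split_half_threshold,
#'   interneuron_width_ms,interneuron_min_rate classification constants
#' @return a `cell_label`: `label` (primary), `labels` (all qualifying),
#'   `evidence` (the metrics used)
#' @export
classify_mec_cell <- function(metrics, gridness_threshold = 0.54,
                              mrl_threshold = 0.21,
                              split_half_threshold = 0.6,
                              interneuron_width_ms = 0.3,
                              interneuron_min_rate = 0.5) {
  need <- c("gridness", "mrl", "split_half", "width_ms", "mean_rate")
  for (nm in need) {
    if (is.null(metrics[[nm]])) {
      stop_invalid(sprintf("missing metric '%s'", nm))
    }
  }
  labels <- character(0)
  if (is.finite(metrics$width_ms) && metrics$width_ms < interneuron_width_ms &&
      is.finite(metrics$mean_rate) && metrics$mean_rate >= interneuron_min_rate) {
    labels <- "interneuron"
  } else {
    is_grid <- is.finite(metrics$gridness) &&
      metrics$gridness >= gridness_threshold
    if (is_grid) labels <- c(labels, "grid")
    if (is.finite(metrics$mrl) && metrics$mrl >= mrl_threshold) {
      labels <- c(labels, "head_direction")
    }
    if (!is_grid && is.finite(metrics$split_half) &&
        metrics$split_half >= split_half_threshold) {
      labels <- c(labels, "nongrid_spatial")
    }
  }
  if (!length(labels)) labels <- "unclassified"
  structure(list(label = labels[1], labels = labels,
                 evidence = metrics[need]),
            class = "cell_label")
}

#' @export
print.cell_label <- function(x, ...) {
  cat(sprintf("cell_label: %s (%s)\n", x$label,
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Place-cell criteria for CA1 cells
#'
#' A CA1 cell is a putative place cell iff its mean rate is in
#' \[0.1, 5.0) Hz and its spatial peak rate exceeds 5.0 Hz.
#'
#' @param mean_rate mean firing rate, Hz
#' @param peak_rate spatial peak rate (smoothed map), Hz
#' @param map optionally, a `rate_map` from which `peak_rate` is taken
#' @return logical
#' @export
classify_place_cell <- function(mean_rate, peak_rate = NULL, map = NULL) {
  if (is.null(peak_rate)) {
    if (is.null(map)) stop_invalid("provide peak_rate or map")
    peak_rate <- suppressWarnings(max(map$rate, na.rm = TRUE))
  }
  isTRUE(mean_rate >= 0.1 && mean_rate < 5.0 && peak_rate > 5.0)
}

#' Speed score: running speed versus firing rate correlation
#'
#' The instantaneous firing rate is estimated on the position-sample time
#' grid as Gaussian-smoothed spike counts (250 ms SD) divided by the
#' sample interval, and Pearson-correlated with running speed.
#'
#' @param traj a `trajectory` with speed
#' @param spikes a `spike_train`
#' @param kernel_sd smoothing SD for the instantaneous rate, s
#' @return correlation in \[-1, 1\]; NA (with warning) for constant speed
#' @export
speed_score <- function(traj, spikes, kernel_sd = 0.25) {
  times <- if (inherits(spikes, "spike_train")) spikes$times else spikes
  dt <- stats::median(diff(traj$t))
  cnt <- numeric(nrow(traj))
  if (length(times)) {
    si <- round(stats::approx(traj$t, seq_along(traj$t), times, rule = 2)$y)
    agg <- tapply(rep(1, length(si)), si, sum)
    cnt[as.integer(names(agg))] <- agg
  }
  rate <- gauss_smooth1d(cnt / dt, sd = kernel_sd / dt)
  ok <- is.finite(rate) & is.finite(traj$speed)
  if (stats::sd(traj$speed[ok]) == 0) {
    warning("constant speed; speed score undefined")
    return(NA_real_)
  }
  stats::cor(rate[ok], traj$speed[ok])
}

#' Compute the full metric set for one MEC cell
#'
#' @param traj a `trajectory`
#' @param spikes a `spike_train`
#' @param ... passed to [make_ratemap()]
#' @return one-row data frame: cell_id, region, gridness, mrl,
#'   split_half, spatial_info, width_ms, mean_rate, peak_rate,
#'   speed_score
#' @export
cell_metrics <- function(traj, spikes, ...) {
  map <- make_ratemap(traj, spikes, ...)
  gs <- tryCatch(gridness_score(spatial_autocorr(map)),
                 error = function(e) NULL)
  pt <- tryCatch(polar_tuning(traj, spikes), error = function(e) NULL)
  sh <- tryCatch(suppressWarnings(split_half_reliability(traj, spikes, ...)),
                 error = function(e) NA_real_)
  dur <- sum(traj_dt(traj))
  data.frame(cell_id = spikes$cell_id, region = spikes$region,
             gridness = if (is.null(gs)) NA_real_ else gs$gridness,
             mrl = if (is.null(pt)) NA_real_ else pt$mrl,
             split_half = sh,
             spatial_info = spatial_information(map),
             width_ms = spikes$waveform_width,
             mean_rate = length(spikes$times) / dur,
             peak_rate = suppressWarnings(max(map$rate, na.rm = TRUE)),
             speed_score = suppressWarnings(speed_score(traj, spikes)),
             stringsAsFactors = FALSE)
}
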