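# Internal: bin edges covering the arena (preferred) or the data extent.
.map_extent <- function(traj, arena = traj_arena(traj), bin_size = 3) {
  if (!is.null(arena) && arena$shape == "rectangle") {
    xlim <- c(0, arena$width); ylim <- c(0, arena$height)
  } else if (!is.null(arena)) {
    R <- arena$circumradius
    xlim <- c(-R, R); ylim <- c(-R, R)
  } else {
    xlim <- range(traj$x); ylim <- range(traj$y)
  }
  nx <- max(1L, ceiling((xlim[2] - xlim[1]) / bin_size - 1e-9))
  ny <- max(1L, ceiling((ylim[2] - ylim[1]) / bin_size - 1e-9))
  list(xbreaks = xlim[1] + bin_size * (0:nx), ybreaks = ylim[1] + bin_size * (0:ny))
}

# Internal: per-session precomputation reused across spike shuffles:
# sample bin indices, occupancy grid, and the nearest-sample lookup.
ratemap_precompute <- function(traj, bin_size = 3, arena = traj_arena(traj),
                               min_occupancy = 0.1) {
  ext <- .map_extent(traj, arena, bin_size)
  nx <- length(ext$xbreaks) - 1L; ny <- length(ext$ybreaks) - 1L
  ix <- findInterval(traj$x, ext$xbreaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  iy <- findInterval(traj$y, ext$ybreaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  bin <- (iy - 1L) * nx + ix
  dt <- traj_dt(traj)
  occ_v <- numeric(nx * ny)
  agg <- tapply(dt, bin, sum)
  occ_v[as.integer(names(agg))] <- agg
  occupancy <- matrix(occ_v, nx, ny)
  list(t = traj$t, bin = bin, occupancy = occupancy, nx = nx, ny = ny,
       bin_size = bin_size, xbreaks = ext$xbreaks, ybreaks = ext$ybreaks,
       visited = occupancy >= min_occupancy, min_occupancy = min_occupancy)
}

# Internal: rate map from precomputed occupancy + spike times.
ratemap_from_precomp <- function(pre, spike_times, smooth_sd = 3) {
  # assign each spike to its nearest trajectory sample's bin, so every
  # spike lands in an occupied bin and spike count is conserved exactly
  if (length(spike_times)) {
    si <- round(stats::approx(pre$t, seq_along(pre$t), spike_times,
                              rule = 2)$y)
    sbin <- pre$bin[pmax(1L, pmin(length(pre$bin), si))]
    cnt_v <- numeric(pre$nx * pre$ny)
    agg <- tapply(rep(1, length(sbin)), sbin, sum)
    cnt_v[as.integer(names(agg))] <- agg
    spikes <- matrix(cnt_v, pre$nx, pre$ny)
  } else {
    spikes <- matrix(0, pre$nx, pre$ny)
  }
  occupied <- pre$occupancy > 0
  rate_raw <- matrix(NA_real_, pre$nx, pre$ny)
  rate_raw[occupied] <- spikes[occupied] / pre$occupancy[occupied]
  rate <- if (!is.null(smooth_sd) && smooth_sd > 0) {
    sm <- smooth_map(rate_raw, pre$visited, smooth_sd)
    sm
  } else {
    out <- rate_raw
    out[!pre$visited] <- NA_real_
    out
  }
  structure(list(rate = rate, rate_unsmoothed = rate_raw, spikes = spikes,
                 occupancy = pre$occupancy, visited = pre$visited,
                 bin_size = pre$bin_size, xbreaks = pre$xbreaks,
                 ybreaks = pre$ybreaks, smooth_sd = smooth_sd),
            class = "rate_map")
}

#' Occupancy-normalized firing-rate map
#'
#' Positions are binned into `bin_size` x `bin_size` cm bins (3 cm
#' default); the unsmoothed rate in each bin is the spike count divided by
#' the occupancy time, and the displayed/analyzed rate is smoothed with a
#' truncated two-dimensional Gaussian kernel (`smooth_sd` bins SD, 3 cm
#' bins so the default SD is 9 cm; radius 3 SD) whose mass is renormalized
#' over visited bins. Spikes are assigned to the bin of their nearest
#' trajectory sample, so the unsmoothed map conserves the spike count
#' exactly: sum(rate_unsmoothed * occupancy) equals the number of spikes.
#'
#' @param traj a `trajectory`
#' @param spikes a `spike_train` (an empty train gives an all-zero map)
#' @param bin_size spatial bin side, cm
#' @param smooth_sd Gaussian SD in bins (0 or NULL for no smoothing)
#' @param arena optional `arena` fixing the map extent (defaults to the
#'   trajectory's arena, else the data extent)
#' @param min_occupancy occupancy (s) for a bin to count as visited
#' @return a `rate_map`: smoothed `rate`, `rate_unsmoothed`, `spikes`,
#'   `occupancy` (s), logical `visited`, and bin geometry. Unvisited bins
#'   are NA in `rate`.
#' @export
make_ratemap <- function(traj, spikes, bin_size = 3, smooth_sd = 3,
                         arena = traj_arena(traj), min_occupancy = 0.1) {
  if (is.null(traj) || nrow(traj) == 0) stop_invalid("empty trajectory")
  times <- if (inherits(spikes, "spike_train")) spikes$times else as.numeric(spikes)
  pre <- ratemap_precompute(traj, bin_size, arena, min_occupancy)
  ratemap_from_precomp(pre, times, smooth_sd)
}

#' Smooth a masked map with an occupancy-renormalized Gaussian kernel
#'
#' @param rate matrix (NA allowed)
#' @param visited logical matrix; only these bins contribute and are kept
#' @param smooth_sd kernel SD in bins; kernel truncated at 3 SD
#' @return smoothed matrix, NA outside `visited`
#' @export
smooth_map <- function(rate, visited, smooth_sd = 3) {
  r <- ceiling(3 * smooth_sd)
  k1 <- exp(-(seq(-r, r))^2 / (2 * smooth_sd^2))
  K <- outer(k1, k1)
  K <- K / sum(K)
  m <- visited & is.finite(rate)
  a <- ifelse(m, rate, 0)
  conv <- function(M) {
    nr <- nrow(M); nc <- ncol(M)
    pr <- nr + 2L * r; pc <- nc + 2L * r
    Mp <- matrix(0, pr, pc); Kp <- matrix(0, pr, pc)
    Mp[r + 1:nr, r + 1:nc] <- M
    Kp[1:(2 * r + 1), 1:(2 * r + 1)] <- K
    ff <- Re(stats::fft(stats::fft(Mp) * stats::fft(Kp), inverse = TRUE)) / (pr * pc)
    ff[2 * r + 1:nr, 2 * r + 1:nc]
  }
  num <- conv(a)
  den <- conv(m + 0)
  out <- matrix(NA_real_, nrow(rate), ncol(rate))
  ok <- visited & den > 1e-9
  out[ok] <- num[ok] / den[ok]
  out[out < 0 & is.finite(out)] <- 0    # clip FFT round-off
  out
}

#' Spatial autocorrelogram of a rate map
#'
#' Pearson product-moment correlation of the smoothed map with itself at
#' every 2-D lag, computed over the mutually visited bins; lags with fewer
#' than `min_overlap` overlapping bins are invalid (NA). The result is
#' point-symmetric about the center and equals 1 at zero lag.
#'
#' @param map a `rate_map`
#' @param min_overlap minimum overlapping visited bins per lag
#' @return a `spatial_autocorr`: `corr`, `n_overlap`, `lag_size` (cm),
#'   and `center` (matrix index of zero lag)
#' @export
spatial_autocorr <- function(map, min_overlap = 20) {
  M <- map$rate
  M[!map$visited] <- NA_real_
  xc <- masked_crosscorr(M, M, min_overlap = min_overlap)
  corr <- xc$corr
  # symmetrize (exact in exact arithmetic; removes FFT round-off)
  flip <- corr[rev(seq_len(nrow(corr))), rev(seq_len(ncol(corr))), drop = FALSE]
  corr <- (corr + flip) / 2
  structure(list(corr = corr, n_overlap = xc$n_overlap,
                 lag_size = map$bin_size,
                 center = c((nrow(corr) + 1L) %/% 2L, (ncol(corr) + 1L) %/% 2L)),
            class = "spatial_autocorr")
}

#' Spatial information (bits per spike)
#'
#' Skaggs information rate per spike,
#' sum_i p_i (lambda_i / lambda) log2(lambda_i / lambda), with p_i the
#' occupancy probability of bin i, lambda_i its firing rate, and lambda
#' the occupancy-weighted mean rate. Zero for a spatially uniform map;
#' undefined (NA with a warning) when the mean rate is zero.
#'
#' @param map a `rate_map`
#' @param use_smoothed use the smoothed rate (default) or the raw rate
#' @return bits/spike (>= 0)
#' @export
spatial_information <- function(map, use_smoothed = TRUE) {
  r <- if (use_smoothed) map$rate else map$rate_unsmoothed
  ok <- map$visited & is.finite(r) & is.finite(map$occupancy)
  p <- map$occupancy[ok] / sum(map$occupancy[ok])
  lam_i <- r[ok]
  lam <- sum(p * lam_i)
  if (!is.finite(lam) || lam <= 0) {
    warning("mean rate is zero; spatial information undefined")
    return(NA_real_)
  }
  ratio <- lam_i / lam
  terms <- ifelse(lam_i > 0, p * ratio * log2(ratio), 0)
  sum(terms)
}

#' Split-half spatial reliability
#'
#' Pearson correlation between the smoothed rate maps of the first and
#' second halves of the session, over bins visited in both halves. Cells
#' with reliability >= 0.6 that do not qualify as grid cells are
#' classified as non-grid spatially tuned.
#'
#' @param traj a `trajectory`
#' @param spikes a `spike_train`
#' @param min_common minimum number of bins visited in both halves
#' @param ... passed to [make_ratemap()]
#' @return correlation in \[-1, 1\], NA (with warning) on insufficient
#'   common coverage
#' @export
split_half_reliability <- function(traj, spikes, min_common = 20, ...) {
  tmid <- traj$t[1] + traj_duration(traj) / 2
  first <- traj$t <= tmid
  t1 <- traj[first, , drop = FALSE]; t2 <- traj[!first, , drop = FALSE]
  attr(t1, "arena") <- attr(t2, "arena") <- traj_arena(traj)
  class(t1) <- class(t2) <- class(traj)
  times <- if (inherits(spikes, "spike_train")) spikes$times else spikes
  m1 <- make_ratemap(t1, times[times <= tmid], arena = traj_arena(traj), ...)
  m2 <- make_ratemap(t2, times[times > tmid], arena = traj_arena(traj), ...)
  both <- m1$visited & m2$visited & is.finite(m1$rate) & is.finite(m2$rate)
  if (sum(both) < min_common) {
    warning("insufficient common coverage across halves")
    return(NA_real_)
  }
  stats::cor(m1$rate[both], m2$rate[both])
}

#' Firing fields of a rate map
#'
#' Detects firing fields as connected components (4-connectivity) of bins
#' at or above 50% of a local peak: local maxima of the smoothed map at or
#' above `min_peak_frac` of the global peak seed fields in descending
#' peak order, and each field floods over not-yet-assigned visited bins
#' >= 50% of its seed peak. The normalized field size divides the mean
#' field area by `spacing^2`, making it invariant to the spatial scale of
#' the grid.
#'
#' @param map a `rate_map`
#' @param spacing grid spacing used for normalization, cm (NA to skip)
#' @param min_peak_frac minimum peak height as a fraction of the global peak
#' @param min_peak_rate minimum absolute peak rate, Hz
#' @return a `field_set`: data frame `fields` (centroid_x, centroid_y,
#'   area_cm2, peak_hz), `normalized_field_size`, and the integer `labels`
#'   matrix (0 = background)
#' @export
field_size <- function(map, spacing = NA, min_peak_frac = 0.2,
                       min_peak_rate = 1) {
  M <- map$rate
  M[!map$visited] <- NA_real_
  nr <- nrow(M); nc <- ncol(M)
  gp <- suppressWarnings(max(M, na.rm = TRUE))
  if (!is.finite(gp) || gp <= 0) {
    return(structure(list(fields = data.frame(centroid_x = numeric(0),
                                              centroid_y = numeric(0),
                                              area_cm2 = numeric(0),
                                              peak_hz = numeric(0)),
                          normalized_field_size = NA_real_,
                          labels = matrix(0L, nr, nc)),
                     class = "field_set"))
  }
  # local maxima over the 8-neighborhood
  is_peak <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    v <- M[i, j]
    if (!is.finite(v) || v < max(min_peak_rate, min_peak_frac * gp)) next
    nb <- M[max(1, i - 1):min(nr, i + 1), max(1, j - 1):min(nc, j + 1)]
    if (v >= max(nb, na.rm = TRUE)) is_peak[i, j] <- TRUE
  }
  peaks <- which(is_peak, arr.ind = TRUE)
  if (nrow(peaks) == 0) {
    return(structure(list(fields = data.frame(centroid_x = numeric(0),
                                              centroid_y = numeric(0),
                                              area_cm2 = numeric(0),
                                              peak_hz = numeric(0)),
                          normalized_field_size = NA_real_,
                          labels = matrix(0L, nr, nc)),
                     class = "field_set"))
  }
  ord <- order(M[peaks], decreasing = TRUE)
  peaks <- peaks[ord, , drop = FALSE]
  labels <- matrix(0L, nr, nc)
  fields <- list()
  lab <- 0L
  for (p in seq_len(nrow(peaks))) {
    pi_ <- peaks[p, 1]; pj <- peaks[p, 2]
    if (labels[pi_, pj] != 0L) next
    peak_v <- M[pi_, pj]
    thr <- 0.5 * peak_v
    lab <- lab + 1L
    # flood fill (4-connectivity) over unassigned bins >= threshold
    stack <- list(c(pi_, pj))
    cells <- matrix(integer(0), 0, 2)
    while (length(stack)) {
      q <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      i <- q[1]; j <- q[2]
      if (i < 1 || i > nr || j < 1 || j > nc) next
      if (labels[i, j] != 0L) next
      v <- M[i, j]
      if (!is.finite(v) || v < thr) next
      labels[i, j] <- lab
      cells <- rbind(cells, c(i, j))
      stack <- c(stack, list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1)))
    }
    if (nrow(cells) == 0) { lab <- lab - 1L; next }
    cx <- map$xbreaks[1] + (cells[, 1] - 0.5) * map$bin_size
    cy <- map$ybreaks[1] + (cells[, 2] - 0.5) * map$bin_size
    w <- M[cells]
    fields[[lab]] <- data.frame(centroid_x = sum(cx * w) / sum(w),
                                centroid_y = sum(cy * w) / sum(w),
                                area_cm2 = nrow(cells) * map$bin_size^2,
                                peak_hz = peak_v)
  }
  fields <- if (length(fields)) do.call(rbind, fields) else
    data.frame(centroid_x = numeric(0), centroid_y = numeric(0),
               area_cm2 = numeric(0), peak_hz = numeric(0))
  nfs <- if (nrow(fields) && is.finite(spacing) && spacing > 0) {
    mean(fields$area_cm2) / spacing^2
  } else NA_real_
  structure(list(fields = fields, normalized_field_size = nfs,
                 labels = labels),
            class = "field_set")
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf("rate_map: %d x %d bins of %g cm, %d visited, peak %.2f Hz\n",
              nrow(x$rate), ncol(x$rate), x$bin_size, sum(x$visited),
              suppressWarnings(max(x$rate, na.rm = TRUE))))
  invisible(x)
}
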