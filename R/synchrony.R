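#' Spike-time cross-correlogram between two cells
#'
#' Counts spike-time differences (b minus a) in 5 ms bins from -400 to
#' +400 ms over the overlapping recording interval. Counts are divided by
#' the overlap-corrected duration per lag (T - |lag|; the unbiased
#' estimator), convolved with a 25 ms Gaussian, and normalized to their
#' median absolute deviation (a robust z-score: the smoothed correlogram
#' is centered on its median and scaled by its MAD, so independent pairs
#' fluctuate around zero and synchronous pairs show a positive central
#' peak). By construction cc(a,b)(tau) = cc(b,a)(-tau).
#'
#' @param a,b `spike_train`s (non-empty) recorded simultaneously
#' @param lag_max correlogram half-window, s
#' @param bin bin width, s
#' @param smooth_sd Gaussian smoothing SD, s
#' @param normalize "mad" (median absolute deviation, the default) or
#'   "median"
#' @param min_overlap required overlap of the recording intervals, s
#' @return a `crosscorrelogram`: `lags` (s, bin centers), `raw`
#'   (rate-like, overlap-corrected), `smoothed`, `normalized` (NA with a
#'   warning when the normalizer is zero), `pair` (cell ids)
#' @export
crosscorrelogram <- function(a, b, lag_max = 0.4, bin = 0.005,
                             smooth_sd = 0.025,
                             normalize = c("mad", "median"),
                             min_overlap = 600) {
  normalize <- match.arg(normalize)
  ta <- if (inherits(a, "spike_train")) a$times else a
  tb <- if (inherits(b, "spike_train")) b$times else b
  if (!length(ta) || !length(tb)) stop_invalid("empty spike train")
  lo <- max(min(ta), min(tb)); hi <- min(max(ta), max(tb))
  T_ <- hi - lo
  if (T_ < 0.98 * min_overlap) {   # 2% slack for spike-time jitter at the ends
    stop_insufficient(sprintf(
      "overlapping interval is %.0f s; %.0f s required", T_, min_overlap))
  }
  nb2 <- round(lag_max / bin)
  edges <- (seq(-nb2, nb2 + 1) - 0.5) * bin
  centers <- seq(-nb2, nb2) * bin
  # all pairwise differences within the window, via a sorted-train sweep
  lo_i <- findInterval(ta - lag_max - bin / 2, tb)
  hi_i <- findInterval(ta + lag_max + bin / 2, tb)
  cnt <- hi_i - lo_i
  ai <- rep.int(seq_along(ta), cnt)
  bj <- sequence(cnt) + rep.int(lo_i, cnt)
  diffs <- tb[bj] - ta[ai]
  k <- findInterval(diffs, edges)
  k <- k[k >= 1 & k <= length(centers)]
  counts <- tabulate(k, length(centers))
  raw <- counts / (T_ - abs(centers))
  smoothed <- gauss_smooth1d(raw, smooth_sd / bin)
  med <- stats::median(smoothed)
  normalizer <- if (normalize == "mad") {
    stats::mad(smoothed, constant = 1)
  } else {
    med
  }
  normalized <- if (!is.finite(normalizer) || normalizer <= 0) {
    warning("degenerate correlogram: zero ", normalize,
            "; normalized values undefined")
    rep(NA_real_, length(centers))
  } else if (normalize == "mad") {
    # robust z-score: center on the median, scale by the MAD
    (smoothed - med) / normalizer
  } else {
    smoothed / normalizer
  }
  structure(list(lags = centers, counts = counts, raw = raw,
                 smoothed = smoothed, normalized = normalized,
                 normalizer = normalizer, normalize = normalize,
                 overlap = T_,
                 pair = c(if (inherits(a, "spike_train")) a$cell_id else "a",
                          if (inherits(b, "spike_train")) b$cell_id else "b")),
            class = "crosscorrelogram")
}

#' @export
print.crosscorrelogram <- function(x, ...) {
  pk <- x$lags[which.max(x$smoothed)]
  cat(sprintf("crosscorrelogram %s vs %s: peak at %+.0f ms\n",
              x$pair[1], x$pair[2], 1000 * pk))
  invisible(x)
}

#' Co-activity within a time window
#'
#' Mean of the normalized cross-correlogram over lags within
#' +/- `window` (25 ms default); the pairwise synchrony statistic.
#'
#' @param cc a `crosscorrelogram`
#' @param window half-window, s
#' @return dimensionless mean normalized correlation
#' @export
coactivity <- function(cc, window = 0.025) {
  sel <- abs(cc$lags) <= window + 1e-9
  mean(cc$normalized[sel])
}

#' Synchrony table for a set of labeled cells
#'
#' Builds cross-correlograms for all pairs of cells whose labels fall in
#' `types_a` x `types_b` (e.g. grid vs interneuron) and tabulates the
#' co-activity and peak lag per pair.
#'
#' @param cells list of `spike_train`s
#' @param labels character vector of functional labels, parallel to
#'   `cells`
#' @param types_a,types_b label sets defining the pair types
#' @param ... passed to [crosscorrelogram()]
#' @return data frame: pair_id, cell_a, cell_b, type_a, type_b,
#'   coactivity, peak_lag_ms
#' @export
synchrony_table <- function(cells, labels, types_a = "grid",
                            types_b = c("interneuron", "head_direction"),
                            ...) {
  stopifnot(length(cells) == length(labels))
  rows <- list()
  for (i in seq_along(cells)) for (j in seq_along(cells)) {
    if (i == j) next
    if (!(labels[i] %in% types_a) || !(labels[j] %in% types_b)) next
    if (labels[i] %in% types_b && labels[j] %in% types_a && j < i) next
    cc <- tryCatch(crosscorrelogram(cells[[i]], cells[[j]], ...),
                   error = function(e) NULL)
    if (is.null(cc)) next
    rows[[length(rows) + 1L]] <- data.frame(
      pair_id = paste(cells[[i]]$cell_id, cells[[j]]$cell_id, sep = "-"),
      cell_a = cells[[i]]$cell_id, cell_b = cells[[j]]$cell_id,
      type_a = labels[i], type_b = labels[j],
      coactivity = coactivity(cc),
      peak_lag_ms = 1000 * cc$lags[which.max(cc$smoothed)],
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(pair_id = character(0), cell_a = character(0),
                      cell_b = character(0), type_a = character(0),
                      type_b = character(0), coactivity = numeric(0),
                      peak_lag_ms = numeric(0)))
  }
  do.call(rbind, rows)
}
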