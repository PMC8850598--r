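#' Epoch-wise rate maps
#'
#' Divides the first `n_epochs * epoch_len` seconds of a recording into
#' contiguous, non-overlapping epochs (default: the first 30 min into 10
#' three-minute epochs) and builds a smoothed rate map per epoch on a
#' shared spatial grid.
#'
#' @param traj a `trajectory`
#' @param spikes a `spike_train`
#' @param n_epochs number of epochs
#' @param epoch_len epoch length, s
#' @param ... passed to [make_ratemap()]
#' @return list of `rate_map`s, length `n_epochs`
#' @export
epoch_maps <- function(traj, spikes, n_epochs = 10, epoch_len = 180, ...) {
  dt <- stats::median(diff(traj$t))
  T_ <- traj_duration(traj) + dt    # span of the sampled interval
  need <- n_epochs * epoch_len
  if (T_ < need - 1e-9) {
    stop_insufficient(sprintf(
      "session is %.1f s but %d epochs of %g s require %.0f s",
      T_, n_epochs, epoch_len, need))
  }
  times <- if (inherits(spikes, "spike_train")) spikes$times else spikes
  arena <- traj_arena(traj)
  t0 <- traj$t[1]
  lapply(seq_len(n_epochs), function(k) {
    lo <- t0 + (k - 1) * epoch_len
    hi <- t0 + k * epoch_len
    sel <- traj$t >= lo & traj$t < hi
    sub <- traj[sel, , drop = FALSE]
    attr(sub, "arena") <- arena
    class(sub) <- class(traj)
    make_ratemap(sub, times[times >= lo & times < hi], arena = arena, ...)
  })
}

#' Optimal 2-D shift between two rate maps (central-patch rule)
#'
#' Computes the masked Pearson spatial cross-correlogram between two rate
#' maps over a window of +/- `max_lag` bins (+/-15 cm at 3 cm bins) in
#' both dimensions. Because grid periodicity can produce multiple local
#' maxima, the peak is taken inside the patch of correlation values
#' nearest the center for which all contiguous (4-connected) values are
#' at least 50% of the maximum: the qualifying pixel closest to the
#' center seeds the patch, and the displacement is the distance from the
#' center (no shift) to the maximum within that patch.
#'
#' @param map_a,map_b `rate_map`s on the same grid
#' @param max_lag half-width of the lag window, bins
#' @param min_overlap minimum overlapping visited bins per lag
#' @return list: `dx`, `dy` (cm), `displacement` (cm), `corr_window`
#'   (the (2 max_lag + 1)^2 correlogram), `peak_corr`; all-NA lags give
#'   `displacement = NA` flagged by attribute `valid = FALSE`
#' @export
pairwise_shift <- function(map_a, map_b, max_lag = 5, min_overlap = 20) {
  stopifnot(all(dim(map_a$rate) == dim(map_b$rate)))
  A <- map_a$rate; A[!map_a$visited] <- NA_real_
  B <- map_b$rate; B[!map_b$visited] <- NA_real_
  xc <- masked_crosscorr(A, B, min_overlap = min_overlap)
  ctr_r <- which(xc$lag_rows == 0)
  ctr_c <- which(xc$lag_cols == 0)
  sel_r <- (ctr_r - max_lag):(ctr_r + max_lag)
  sel_c <- (ctr_c - max_lag):(ctr_c + max_lag)
  W <- xc$corr[sel_r, sel_c, drop = FALSE]
  n <- 2L * max_lag + 1L
  out <- list(dx = NA_real_, dy = NA_real_, displacement = NA_real_,
              corr_window = W, peak_corr = NA_real_)
  if (all(!is.finite(W))) { attr(out, "valid") <- FALSE; return(out) }
  mx <- max(W, na.rm = TRUE)
  qual <- is.finite(W) & W >= 0.5 * mx
  # the 50%-of-max rule assumes a positive maximum; for all-negative
  # windows only the maximum itself qualifies
  if (!any(qual)) qual <- is.finite(W) & W == mx
  # seed: qualifying pixel nearest the center, ties by angle
  ctr <- max_lag + 1
  idx <- which(qual, arr.ind = TRUE)
  dd <- sqrt((idx[, 1] - ctr)^2 + (idx[, 2] - ctr)^2)
  aa <- wrap360(rad2deg(atan2(idx[, 2] - ctr, idx[, 1] - ctr)))
  seed <- idx[order(dd, aa)[1], ]
  # flood fill 4-connectivity over qualifying pixels
  patch <- matrix(FALSE, n, n)
  stack <- list(seed)
  while (length(stack)) {
    q <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- q[1]; j <- q[2]
    if (i < 1 || i > n || j < 1 || j > n) next
    if (patch[i, j] || !qual[i, j]) next
    patch[i, j] <- TRUE
    stack <- c(stack, list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1)))
  }
  Wp <- ifelse(patch, W, NA_real_)
  pk <- which(Wp == max(Wp, na.rm = TRUE), arr.ind = TRUE)
  if (nrow(pk) > 1) {  # ties: nearest center, then angle
    pd <- sqrt((pk[, 1] - ctr)^2 + (pk[, 2] - ctr)^2)
    pa <- wrap360(rad2deg(atan2(pk[, 2] - ctr, pk[, 1] - ctr)))
    pk <- pk[order(pd, pa)[1], , drop = FALSE]
  }
  bs <- map_a$bin_size
  out$dx <- unname(pk[1, 1] - ctr) * bs
  out$dy <- unname(pk[1, 2] - ctr) * bs
  out$displacement <- sqrt(out$dx^2 + out$dy^2)
  out$peak_corr <- W[pk]
  attr(out, "valid") <- TRUE
  out
}

#' Optimal rotation between two rate maps
#'
#' Rotates `map_b` in `step`-degree increments over \[-range, range\]
#' about the map center and, at each candidate rotation, takes the
#' maximum of the masked cross-correlogram over the +/- `max_lag` shift
#' window (rotation optimized jointly with translation). Returns the
#' absolute angle of the best rotation; 0 for identical, stable maps.
#'
#' @param map_a,map_b `rate_map`s on the same grid
#' @param range rotation search half-range, degrees (one 60-degree
#'   lattice sector)
#' @param step rotation step, degrees
#' @param max_lag shift window half-width, bins
#' @param min_overlap minimum overlapping bins per lag
#' @return list: `rotation` (|degrees|), `signed_rotation`, `corr`
#' @export
pairwise_rotation <- function(map_a, map_b, range = 30, step = 3,
                              max_lag = 5, min_overlap = 20) {
  A <- map_a$rate; A[!map_a$visited] <- NA_real_
  B <- map_b$rate; B[!map_b$visited] <- NA_real_
  angles <- seq(-range, range, by = step)
  best <- -Inf; best_ang <- NA_real_
  for (ang in angles) {
    Brot <- if (ang == 0) B else rotate_matrix(B, ang)
    xc <- masked_crosscorr(A, Brot, min_overlap = min_overlap)
    ctr_r <- which(xc$lag_rows == 0); ctr_c <- which(xc$lag_cols == 0)
    W <- xc$corr[(ctr_r - max_lag):(ctr_r + max_lag),
                 (ctr_c - max_lag):(ctr_c + max_lag), drop = FALSE]
    v <- suppressWarnings(max(W, na.rm = TRUE))
    if (is.finite(v) && (v > best ||
        (v == best && is.finite(best_ang) && abs(ang) < abs(best_ang)))) {
      best <- v; best_ang <- ang
    }
  }
  list(rotation = abs(best_ang), signed_rotation = best_ang,
       corr = if (is.finite(best)) best else NA_real_)
}

#' Pairwise 2-D displacement summary across epochs
#'
#' Computes [pairwise_shift()] for all epoch pairs, the mean displacement
#' per epoch lag, and the overall mean displacement (the per-cell 2-D
#' phase-noise statistic). Invalid pairs are excluded from the means.
#'
#' @param maps list of `rate_map`s from [epoch_maps()]
#' @param rotations also compute [pairwise_rotation()] per pair
#' @param ... passed to [pairwise_shift()]
#' @return a `displacement_result`: `pair_shift` (symmetric matrix, cm),
#'   `pair_rotation` (if requested), `mean_displacement` (cm), `by_lag`
#'   data frame (lag, mean_displacement, n_pairs)
#' @export
displacement_summary <- function(maps, rotations = FALSE, ...) {
  K <- length(maps)
  if (K < 2) stop_invalid("need at least two epoch maps")
  D <- matrix(0, K, K)
  R <- if (rotations) matrix(0, K, K) else NULL
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    ps <- pairwise_shift(maps[[i]], maps[[j]], ...)
    D[i, j] <- D[j, i] <- ps$displacement
    if (rotations) {
      pr <- pairwise_rotation(maps[[i]], maps[[j]])
      R[i, j] <- R[j, i] <- pr$rotation
    }
  }
  ut <- upper.tri(D)
  lags <- abs(row(D) - col(D))
  by_lag <- do.call(rbind, lapply(1:(K - 1), function(L) {
    v <- D[ut & lags == L]
    data.frame(lag = L, mean_displacement = mean(v, na.rm = TRUE),
               n_pairs = sum(is.finite(v)))
  }))
  structure(list(pair_shift = D, pair_rotation = R,
                 mean_displacement = mean(D[ut], na.rm = TRUE),
                 mean_rotation = if (rotations) mean(R[ut], na.rm = TRUE) else NA_real_,
                 by_lag = by_lag, epoch_count = K),
            class = "displacement_result")
}

#' @export
print.displacement_result <- function(x, ...) {
  cat(sprintf("displacement_result: %d epochs, mean displacement %.2f cm\n",
              x$epoch_count, x$mean_displacement))
  invisible(x)
}
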