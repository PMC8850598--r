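# Shared fixtures, built once per test run. Sessions are kept short where
# the property under test allows it; the acceptance tests use the full
# study-scale sessions.

box75 <- arena_rect(75, 75)

# memoised trajectories so several test files can share them
.fix <- new.env()

fix_traj <- function(duration = 600, seed = 1, arena = box75) {
  key <- sprintf("traj_%d_%d", duration, seed)
  if (is.null(.fix[[key]])) {
    .fix[[key]] <- simulate_trajectory(duration, arena, seed = seed)
  }
  .fix[[key]]
}

# a rate_map object wrapping an analytic matrix (fully visited, unit occupancy)
analytic_map <- function(M, bin_size = 3) {
  nr <- nrow(M); nc <- ncol(M)
  structure(list(rate = M, rate_unsmoothed = M,
                 spikes = M, occupancy = matrix(1, nr, nc),
                 visited = matrix(TRUE, nr, nc), bin_size = bin_size,
                 xbreaks = bin_size * (0:nr), ybreaks = bin_size * (0:nc),
                 smooth_sd = 0),
            class = "rate_map")
}

# analytic hexagonal rate matrix sampled at bin centers
hex_matrix <- function(n = 25, spacing = 40, bin_size = 3, orientation = 0,
                       phase = c(0, 0), peak = 15) {
  gc <- grid_cell(spacing = spacing, orientation = orientation,
                  phase = phase, peak_rate = peak)
  xs <- (seq_len(n) - 0.5) * bin_size
  outer(xs, xs, function(x, y) grid_rate_at(gc, x, y))
}

# brute-force masked Pearson cross-correlogram (loop oracle)
xcorr_oracle <- function(A, B, min_overlap = 20) {
  nr <- nrow(A); nc <- ncol(A)
  lr <- -(nr - 1):(nr - 1); lc <- -(nc - 1):(nc - 1)
  out <- matrix(NA_real_, length(lr), length(lc))
  for (i in seq_along(lr)) for (j in seq_along(lc)) {
    du <- lr[i]; dv <- lc[j]
    r1 <- max(1, 1 - du):min(nr, nr - du)
    c1 <- max(1, 1 - dv):min(nc, nc - dv)
    a <- A[r1, c1]; b <- B[r1 + du, c1 + dv]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) >= min_overlap && stats::sd(a[ok]) > 0 && stats::sd(b[ok]) > 0) {
      out[i, j] <- stats::cor(a[ok], b[ok])
    }
  }
  out
}

# sort-based percentile oracle (type-7 linear interpolation)
percentile_oracle <- function(x, p) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(n, lo + 1)] - x[lo])
}
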