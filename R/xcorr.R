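# Masked 2-D Pearson cross-correlation of rate maps via FFT.
#
# For every 2-D lag u, the Pearson correlation between A(x) and B(x + u)
# is computed over the bins where both maps are valid (visited and
# finite). All six required lagged sums (overlap count, sums, sums of
# squares and cross products) are cross-correlations of masked arrays and
# are evaluated together with zero-padded FFTs, which makes dense
# autocorrelograms and the many epoch-pair cross-correlograms of the
# stability analysis cheap.

# cross-correlation C(u) = sum_x A(x) * B(x + u), lags -(n-1)..(n-1)
.xcorr2 <- function(A, B) {
  nr <- nrow(A); nc <- ncol(A)
  pr <- 2L * nr - 1L; pc <- 2L * nc - 1L
  Ap <- matrix(0, pr, pc); Bp <- matrix(0, pr, pc)
  Ap[1:nr, 1:nc] <- A
  Bp[1:nr, 1:nc] <- B
  ff <- stats::fft(Conj(stats::fft(Ap)) * stats::fft(Bp), inverse = TRUE)
  re <- Re(ff) / (pr * pc)
  # index shift: lag (du, dv) at position ((du mod pr)+1, (dv mod pc)+1)
  idx_r <- c((pr - nr + 2L):pr, 1L:nr)   # lags -(nr-1)..(nr-1)
  idx_c <- c((pc - nc + 2L):pc, 1L:nc)
  re[idx_r, idx_c]
}

# Full masked Pearson cross-correlogram between two maps (matrices with
# NA at invalid bins). Returns corr and n_overlap matrices with lag
# (0,0) at the center, plus the lag offsets in bins.
masked_crosscorr <- function(A, B, min_overlap = 20) {
  stopifnot(all(dim(A) == dim(B)))
  MA <- is.finite(A); MB <- is.finite(B)
  a <- ifelse(MA, A, 0); b <- ifelse(MB, B, 0)
  mA <- MA + 0; mB <- MB + 0
  n   <- .xcorr2(mA, mB)
  Sa  <- .xcorr2(a, mB)
  Sb  <- .xcorr2(mA, b)
  Sab <- .xcorr2(a, b)
  Saa <- .xcorr2(a * a, mB)
  Sbb <- .xcorr2(mA, b * b)
  n <- round(n)
  num <- n * Sab - Sa * Sb
  v1 <- n * Saa - Sa^2
  v2 <- n * Sbb - Sb^2
  v1[v1 < 0] <- 0; v2[v2 < 0] <- 0
  den <- sqrt(v1 * v2)
  corr <- ifelse(n >= max(2, min_overlap) & den > 1e-12, num / den, NA_real_)
  corr[corr > 1] <- 1; corr[corr < -1] <- -1
  nr <- nrow(A); nc <- ncol(A)
  list(corr = corr, n_overlap = n,
       lag_rows = -(nr - 1L):(nr - 1L), lag_cols = -(nc - 1L):(nc - 1L))
}

# Bilinear sampling of matrix M at fractional (row, col) coordinates,
# NA-aware: missing neighbors are dropped and weights renormalized; a
# sample is NA when less than half of the neighbor weight is available
# or the point falls outside the matrix.
bilinear_sample <- function(M, r, c) {
  nr <- nrow(M); nc <- ncol(M)
  out <- rep(NA_real_, length(r))
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  ok <- r0 >= 1 & r0 <= nr - 1 & c0 >= 1 & c0 <= nc - 1
  # allow points exactly on the last row/col
  edge_r <- r0 == nr & fr == 0; edge_c <- c0 == nc & fc == 0
  r0[edge_r] <- nr - 1L; fr[edge_r] <- 1
  c0[edge_c] <- nc - 1L; fc[edge_c] <- 1
  ok <- ok | (r0 >= 1 & r0 <= nr - 1 & c0 >= 1 & c0 <= nc - 1)
  i <- which(ok)
  if (!length(i)) return(out)
  w11 <- (1 - fr[i]) * (1 - fc[i]); w21 <- fr[i] * (1 - fc[i])
  w12 <- (1 - fr[i]) * fc[i];       w22 <- fr[i] * fc[i]
  g <- function(rr, cc) M[cbind(rr, cc)]
  v11 <- g(r0[i], c0[i]);     v21 <- g(r0[i] + 1L, c0[i])
  v12 <- g(r0[i], c0[i] + 1L); v22 <- g(r0[i] + 1L, c0[i] + 1L)
  V <- cbind(v11, v21, v12, v22)
  W <- cbind(w11, w21, w12, w22)
  W[!is.finite(V)] <- 0
  V[!is.finite(V)] <- 0
  wsum <- rowSums(W)
  val <- rowSums(V * W) / wsum
  val[wsum < 0.5] <- NA_real_
  out[i] <- val
  out
}

# Rotate a matrix about its center by theta degrees (counterclockwise in
# x-y space) using NA-aware bilinear interpolation.
rotate_matrix <- function(M, theta_deg, center = (dim(M) + 1) / 2) {
  th <- deg2rad(theta_deg)
  nr <- nrow(M); nc <- ncol(M)
  # treat rows as x and columns as y; rotation is its own inverse pair
  rc <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  dx <- rc$r - center[1]; dy <- rc$c - center[2]
  sr <- center[1] + cos(th) * dx + sin(th) * dy
  sc <- center[2] - sin(th) * dx + cos(th) * dy
  matrix(bilinear_sample(M, sr, sc), nr, nc)
}
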