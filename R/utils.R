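#' @keywords internal
"_PACKAGE"

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards so generators never disturb global RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# wrap angle in degrees to [0, 360)
wrap360 <- function(d) ((d %% 360) + 360) %% 360

# absolute angular difference in degrees, in [0, 180]
ang_diff <- function(a, b) {
  d <- abs(wrap360(a) - wrap360(b)) %% 360
  pmin(d, 360 - d)
}

# Gaussian kernel vector, sd in bins, truncated at `radius` sd, sums to 1
gauss_kernel <- function(sd, radius = 3) {
  r <- max(1L, ceiling(sd * radius))
  k <- exp(-(seq(-r, r))^2 / (2 * sd^2))
  k / sum(k)
}

# 1-D Gaussian smoothing with edge renormalization (kernel mass restricted
# to the observed support), NA-aware.
gauss_smooth1d <- function(x, sd, radius = 3) {
  k <- gauss_kernel(sd, radius)
  m <- as.numeric(is.finite(x))
  x0 <- ifelse(is.finite(x), x, 0)
  num <- stats::filter(x0, k, sides = 2)
  den <- stats::filter(m, k, sides = 2)
  # stats::filter leaves NAs at the edges; redo edges explicitly
  n <- length(x)
  r <- (length(k) - 1L) / 2L
  out <- as.numeric(num) / as.numeric(den)
  for (i in seq_len(n)) {
    if (i <= r || i > n - r) {
      j <- max(1L, i - r):min(n, i + r)
      w <- k[j - i + r + 1L] * m[j]
      out[i] <- if (sum(w) > 0) sum(x0[j] * k[j - i + r + 1L]) / sum(w) else NA_real_
    }
  }
  out[den == 0] <- NA_real_
  out
}

# Linear-interpolation percentile (quantile type 7), the package's single
# percentile rule so shuffle thresholds are reproducible.
percentile <- function(x, p) {
  stats::quantile(x, probs = p, type = 7, na.rm = TRUE, names = FALSE)
}

# 32-bit polynomial rolling hash of a character scalar, for run
# manifests (fingerprint only, no external deps)
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

stop_invalid <- function(msg) {
  stop(errorCondition(msg, class = c("gridcells_invalid_config", "error")))
}

stop_insufficient <- function(msg, class = "gridcells_insufficient_data") {
  stop(errorCondition(msg, class = c(class, "error")))
}
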