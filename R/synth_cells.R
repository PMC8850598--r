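#' Synthetic grid cell
#'
#' A hexagonal-lattice firing-rate field built from three cosine gratings
#' 60 degrees apart. The field peaks at `peak_rate` on the lattice nodes,
#' is periodic with center-to-center field spacing `spacing`, and can be
#' elliptically stretched (`ellipticity` >= 1 along `orientation`). Grid
#' phase may diffuse over time: every minute the spatial phase takes an
#' isotropic Gaussian step with total per-minute displacement variance
#' `drift_rate^2` (cm^2), emulating an unstable grid pattern.
#'
#' @param spacing field spacing, cm (> 0)
#' @param orientation lattice orientation, degrees
#' @param phase length-2 spatial phase offset, cm
#' @param peak_rate peak firing rate, Hz (> 0)
#' @param drift_rate phase diffusion scale, cm per minute (>= 0)
#' @param ellipticity major/minor axis ratio (>= 1)
#' @param duration session length the drift path must cover, s
#' @param sharpness exponent applied to the normalized lattice profile
#'   (larger -> narrower fields)
#' @param seed RNG seed for the drift path
#' @return object of class `grid_cell` with a precomputed per-minute drift
#'   path; evaluate with [grid_rate_at()]
#' @export
grid_cell <- function(spacing = 40, orientation = 0, phase = c(0, 0),
                      peak_rate = 15, drift_rate = 0, ellipticity = 1,
                      duration = 1800, sharpness = 2, seed = NULL) {
  if (spacing <= 0) stop_invalid("spacing must be > 0")
  if (peak_rate <= 0) stop_invalid("peak_rate must be > 0")
  if (drift_rate < 0) stop_invalid("drift_rate must be >= 0")
  if (ellipticity < 1) stop_invalid("ellipticity must be >= 1")
  n_min <- max(1L, ceiling(duration / 60))
  drift <- matrix(0, n_min + 1L, 2)
  if (drift_rate > 0) {
    steps <- with_seed(seed,
      matrix(stats::rnorm(2 * n_min, 0, drift_rate / sqrt(2)), ncol = 2))
    drift[-1, ] <- apply(steps, 2, cumsum)
  }
  structure(list(spacing = spacing, orientation = orientation,
                 phase = phase, peak_rate = peak_rate,
                 drift_rate = drift_rate, ellipticity = ellipticity,
                 sharpness = sharpness, drift = drift),
            class = "grid_cell")
}

#' Evaluate a grid cell's firing rate
#'
#' @param cell a [grid_cell()]
#' @param x,y positions, cm
#' @param t times, s (used to index the drift path; ignored when
#'   `drift_rate = 0`)
#' @return firing rate in Hz (>= 0), vectorized
#' @export
grid_rate_at <- function(cell, x, y, t = 0) {
  off <- cell$phase
  if (cell$drift_rate > 0) {
    idx <- pmin(nrow(cell$drift), pmax(1L, floor(t / 60) + 1L))
    ox <- off[1] + cell$drift[idx, 1]
    oy <- off[2] + cell$drift[idx, 2]
  } else {
    ox <- off[1]; oy <- off[2]
  }
  ux <- x - ox; uy <- y - oy
  # rotate into the lattice frame, undo elliptic stretch along x
  a <- deg2rad(cell$orientation)
  rx <- (cos(a) * ux + sin(a) * uy) / cell$ellipticity
  ry <- -sin(a) * ux + cos(a) * uy
  k <- 4 * pi / (sqrt(3) * cell$spacing)
  # three gratings at 0, 60, 120 degrees in the lattice frame
  s <- cos(k * rx) +
    cos(k * (rx / 2 + ry * sqrt(3) / 2)) +
    cos(k * (rx / 2 - ry * sqrt(3) / 2))
  g <- (s / 3 + 0.5) / 1.5          # in [0, 1], 1 at lattice nodes
  cell$peak_rate * pmax(0, g)^cell$sharpness
}

#' Synthetic head-direction cell (von Mises tuning)
#'
#' @param preferred_direction degrees
#' @param kappa von Mises concentration (>= 0; 0 = untuned)
#' @param peak_rate firing rate at the preferred direction, Hz
#' @return object of class `hd_cell`
#' @export
hd_cell <- function(preferred_direction = 0, kappa = 2, peak_rate = 20) {
  if (kappa < 0) stop_invalid("kappa must be >= 0")
  if (peak_rate <= 0) stop_invalid("peak_rate must be > 0")
  structure(list(preferred_direction = preferred_direction, kappa = kappa,
                 peak_rate = peak_rate), class = "hd_cell")
}

#' @rdname hd_cell
#' @param cell an `hd_cell`
#' @param hd head direction, degrees
#' @return firing rate, Hz
#' @export
hd_rate_at <- function(cell, hd) {
  cell$peak_rate *
    exp(cell$kappa * (cos(deg2rad(hd - cell$preferred_direction)) - 1))
}

#' Synthetic theta-modulated interneuron
#'
#' Firing rate `base_rate * (1 + depth * sin(2 pi f t + phase))`; used for
#' synchrony and intrinsic-frequency recovery tests.
#'
#' @param base_rate mean rate, Hz
#' @param theta_freq modulation frequency, Hz
#' @param depth modulation depth in \[0, 1\]
#' @param phase modulation phase, radians
#' @return object of class `theta_cell`
#' @export
theta_cell <- function(base_rate = 20, theta_freq = 8, depth = 0.5, phase = 0) {
  if (base_rate <= 0) stop_invalid("base_rate must be > 0")
  if (depth < 0 || depth > 1) stop_invalid("depth must be in [0, 1]")
  structure(list(base_rate = base_rate, theta_freq = theta_freq,
                 depth = depth, phase = phase), class = "theta_cell")
}

#' @rdname theta_cell
#' @param cell a `theta_cell`
#' @param t times, s
#' @return firing rate, Hz
#' @export
theta_rate_at <- function(cell, t) {
  cell$base_rate * (1 + cell$depth * sin(2 * pi * cell$theta_freq * t + cell$phase))
}

#' Synthetic place cell (single Gaussian field)
#'
#' @param center field center, cm
#' @param sd field SD, cm
#' @param peak_rate rate at the field center, Hz
#' @param base_rate out-of-field rate, Hz
#' @return object of class `place_cell`
#' @export
place_cell <- function(center = c(30, 30), sd = 8, peak_rate = 10, base_rate = 0.1) {
  structure(list(center = center, sd = sd, peak_rate = peak_rate,
                 base_rate = base_rate), class = "place_cell")
}

#' @rdname place_cell
#' @param cell a `place_cell`
#' @param x,y positions, cm
#' @return firing rate, Hz
#' @export
place_rate_at <- function(cell, x, y) {
  d2 <- (x - cell$center[1])^2 + (y - cell$center[2])^2
  cell$base_rate + cell$peak_rate * exp(-d2 / (2 * cell$sd^2))
}

# rate along a trajectory for any synthetic cell (or a plain function
# rate(x, y, t, hd)); vectorized over samples
.rate_along <- function(rate, traj, t = traj$t, x = traj$x, y = traj$y,
                        hd = traj$hd) {
  r <- if (inherits(rate, "grid_cell")) grid_rate_at(rate, x, y, t)
  else if (inherits(rate, "hd_cell")) hd_rate_at(rate, hd)
  else if (inherits(rate, "theta_cell")) theta_rate_at(rate, t)
  else if (inherits(rate, "place_cell")) place_rate_at(rate, x, y)
  else if (is.function(rate)) rate(x, y, t, hd)
  else stop_invalid("unsupported rate model")
  if (any(r < 0, na.rm = TRUE)) {
    stop(errorCondition("rate function returned negative rates",
                        class = c("gridcells_contract_violation", "error")))
  }
  r
}

#' Inhomogeneous Poisson spike generation along a trajectory
#'
#' Spikes are drawn by thinning a homogeneous Poisson process at an upper
#' bound of the rate: candidate times are generated over the session, the
#' rate model is evaluated at the (linearly interpolated) position at each
#' candidate time, and candidates are kept with probability rate/bound. A
#' 1 ms refractory period is then enforced so autocorrelograms are
#' realistic near zero lag.
#'
#' @param rate a synthetic cell ([grid_cell()], [hd_cell()],
#'   [theta_cell()], [place_cell()]) or a function `f(x, y, t, hd)` -> Hz
#' @param traj a `trajectory`
#' @param seed RNG seed
#' @param refractory minimum inter-spike interval, s
#' @param rate_max optional explicit rate bound, Hz; defaults to 1.05 x
#'   the maximum rate observed along the trajectory samples
#' @param cell_id,waveform_width,region metadata stored on the result
#' @return a [spike_train()]
#' @export
poisson_spikes <- function(rate, traj, seed = NULL, refractory = 0.001,
                           rate_max = NULL, cell_id = "cell",
                           waveform_width = 0.4, region = "MEC") {
  r_samp <- .rate_along(rate, traj)
  lam <- if (is.null(rate_max)) max(r_samp) * 1.05 else rate_max
  t0 <- traj$t[1]; t1 <- traj$t[length(traj$t)]
  if (lam <= 0) {
    return(spike_train(numeric(0), cell_id = cell_id,
                       waveform_width = waveform_width, region = region))
  }
  with_seed(seed, {
    n_cand <- stats::rpois(1, lam * (t1 - t0))
    cand <- sort(stats::runif(n_cand, t0, t1))
    x <- stats::approx(traj$t, traj$x, cand, rule = 2)$y
    y <- stats::approx(traj$t, traj$y, cand, rule = 2)$y
    # nearest-sample head direction (circular interpolation not needed at 30 Hz)
    idx <- pmax(1L, pmin(length(traj$t),
                         round(stats::approx(traj$t, seq_along(traj$t), cand,
                                             rule = 2)$y)))
    r <- .rate_along(rate, traj, t = cand, x = x, y = y, hd = traj$hd[idx])
    keep <- stats::runif(n_cand) < pmin(1, r / lam)
    times <- cand[keep]
    if (refractory > 0 && length(times) > 1) {
      repeat {
        short <- which(diff(times) < refractory)
        if (length(short) == 0) break
        times <- times[-(short + 1L)]
      }
    }
    spike_train(times, cell_id = cell_id, waveform_width = waveform_width,
                region = region)
  })
}
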