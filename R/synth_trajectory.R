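#' Simulate an open-field foraging trajectory
#'
#' Generates a smooth random-walk trajectory emulating a mouse foraging in
#' an open field: running speed follows an Ornstein--Uhlenbeck process
#' around `speed_mean` (clipped at zero) and heading accumulates Gaussian
#' increments, with steering away from walls so positions stay inside the
#' arena. Positional samples are produced at `sample_rate` (default 30 Hz,
#' the camera frame rate). With the default parameters a 20-minute session
#' visits every 3 cm bin of a 75 x 75 cm arena.
#'
#' @param duration session length in seconds (> 0)
#' @param arena an [arena_rect()] or [arena_decagon()] geometry
#' @param sample_rate position sampling rate, Hz
#' @param speed_mean,speed_sd running-speed mean and SD, cm/s
#' @param heading_diffusion heading diffusion, rad per sqrt(s)
#' @param speed_tau OU time constant of the speed process, s
#' @param seed integer RNG seed; identical seeds give identical trajectories
#' @return a `trajectory`: data frame with columns `t` (s), `x`, `y` (cm),
#'   `hd` (degrees in \[0, 360)), `speed` (cm/s), with the arena attached
#'   as attribute `arena`
#' @examples
#' traj <- simulate_trajectory(60, arena_rect(75), seed = 1)
#' range(traj$x)
#' @export
simulate_trajectory <- function(duration, arena = arena_rect(75, 75),
                                sample_rate = 30, speed_mean = 15,
                                speed_sd = 6, heading_diffusion = 1.5,
                                speed_tau = 1, seed = NULL) {
  if (!is.numeric(duration) || duration <= 0) stop_invalid("duration must be > 0")
  if (sample_rate <= 0) stop_invalid("sample_rate must be > 0")
  if (speed_mean <= 0) stop_invalid("speed_mean must be > 0")
  n <- floor(duration * sample_rate)
  dt <- 1 / sample_rate
  with_seed(seed, {
    eps_h <- stats::rnorm(n, 0, heading_diffusion * sqrt(dt))
    eps_v <- stats::rnorm(n, 0, speed_sd * sqrt(2 * dt / speed_tau))
    x <- numeric(n); y <- numeric(n); hd <- numeric(n); v <- numeric(n)
    ctr <- arena$center
    # start at the arena center, random heading and near-mean speed
    x[1] <- ctr[1]; y[1] <- ctr[2]
    hd[1] <- stats::runif(1, 0, 2 * pi)
    v[1] <- max(0, speed_mean + stats::rnorm(1, 0, speed_sd / 2))
    margin <- 1
    for (i in 2:n) {
      v[i] <- max(0, v[i - 1] + (speed_mean - v[i - 1]) * dt / speed_tau + eps_v[i])
      h <- hd[i - 1] + eps_h[i]
      px <- x[i - 1] + v[i] * cos(h) * dt
      py <- y[i - 1] + v[i] * sin(h) * dt
      if (!in_arena(arena, px, py, margin = margin)) {
        # specular reflection off the nearest wall, keeping speed
        w <- nearest_wall(arena, px, py)$wall
        s <- wall_segments(arena)
        phi <- atan2(s[w, "y2"] - s[w, "y1"], s[w, "x2"] - s[w, "x1"])
        h <- 2 * phi - h
        px <- x[i - 1] + v[i] * cos(h) * dt
        py <- y[i - 1] + v[i] * sin(h) * dt
        if (!in_arena(arena, px, py, margin = 0)) {
          # cornered: fall back to steering toward the center
          h <- atan2(ctr[2] - y[i - 1], ctr[1] - x[i - 1]) + eps_h[i] * 2
          px <- x[i - 1] + v[i] * cos(h) * dt
          py <- y[i - 1] + v[i] * sin(h) * dt
          if (!in_arena(arena, px, py, margin = 0)) { px <- x[i - 1]; py <- y[i - 1] }
        }
      }
      x[i] <- px; y[i] <- py; hd[i] <- h
    }
    traj <- data.frame(t = (seq_len(n) - 1) * dt, x = x, y = y,
                       hd = wrap360(rad2deg(hd)), speed = v)
    attr(traj, "arena") <- arena
    class(traj) <- c("trajectory", "data.frame")
    traj
  })
}

#' Arena attached to a trajectory
#' @param traj a `trajectory`
#' @return the `arena` attribute (or NULL)
#' @export
traj_arena <- function(traj) attr(traj, "arena")

#' Convert a trajectory to two-diode raw tracking
#'
#' Produces the raw head-stage tracking representation (red and green
#' diode coordinates straddling the head position along the head
#' direction), optionally knocking out runs of samples to emulate tracking
#' dropouts.
#'
#' @param traj a `trajectory`
#' @param diode_dist separation of the two diodes, cm
#' @param dropout_runs optional list of integer index vectors to set missing
#' @return a `raw_tracking` data frame: t, red_x, red_y, green_x, green_y
#' @export
trajectory_to_tracking <- function(traj, diode_dist = 3, dropout_runs = NULL) {
  th <- deg2rad(traj$hd)
  half <- diode_dist / 2
  raw <- data.frame(t = traj$t,
                    red_x = traj$x + half * cos(th),
                    red_y = traj$y + half * sin(th),
                    green_x = traj$x - half * cos(th),
                    green_y = traj$y - half * sin(th))
  if (!is.null(dropout_runs)) {
    idx <- unlist(dropout_runs)
    raw[idx, c("red_x", "red_y", "green_x", "green_y")] <- NA_real_
  }
  class(raw) <- c("raw_tracking", "data.frame")
  raw
}
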