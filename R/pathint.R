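#' Return-path container for one homing trial
#'
#' @param t,x,y return trajectory from pellet pickup to trial end
#'   (s, cm, cm); the first sample is the pellet location
#' @param arena the decagonal `arena`
#' @param outcome "success", "fail", or "incomplete"
#' @return object of class `return_path`
#' @export
return_path <- function(t, x, y, arena, outcome = "success") {
  structure(list(t = t, x = x, y = y, pellet_xy = c(x[1], y[1]),
                 arena = arena, outcome = outcome),
            class = "return_path")
}

#' @export
print.return_path <- function(x, ...) {
  cat(sprintf("return_path: %d samples, outcome %s\n", length(x$t), x$outcome))
  invisible(x)
}

#' First wall encountered along a return path
#'
#' The first path sample within `contact_dist` (2 cm) of any wall
#' segment; returns that wall's index (W1-W10). Paths that never reach a
#' wall are flagged incomplete (NA wall).
#'
#' @param path a `return_path`
#' @param arena the `arena` (defaults to the path's)
#' @param contact_dist wall-contact distance, cm
#' @return list: `wall` (index or NA), `sample` (index), `contact_xy`
#' @export
first_wall_encounter <- function(path, arena = path$arena, contact_dist = 2) {
  nw <- nearest_wall(arena, path$x, path$y)
  hit <- which(nw$distance <= contact_dist)
  if (!length(hit)) {
    return(list(wall = NA_integer_, sample = NA_integer_,
                contact_xy = c(NA_real_, NA_real_)))
  }
  i <- hit[1]
  list(wall = nw$wall[i], sample = i,
       contact_xy = c(path$x[i], path$y[i]))
}

#' Initial wall angle of a return path
#'
#' Absolute angle at the pellet location between the direction to the
#' refuge-wall center and the direction to the first wall-contact point,
#' in \[0, 180\] degrees; 0 when the first wall reached is the refuge
#' straight ahead.
#'
#' @param path a `return_path`
#' @param arena the `arena`
#' @param contact_dist passed to [first_wall_encounter()]
#' @return degrees in \[0, 180\]; NA if the pellet coincides with the
#'   refuge center or the path is incomplete
#' @export
initial_wall_angle <- function(path, arena = path$arena, contact_dist = 2) {
  fw <- first_wall_encounter(path, arena, contact_dist)
  if (is.na(fw$wall)) return(NA_real_)
  p <- path$pellet_xy
  ref <- refuge_center(arena)
  if (sqrt(sum((ref - p)^2)) < 1e-9) {
    warning("pellet at the refuge center; wall angle undefined")
    return(NA_real_)
  }
  a_ref <- rad2deg(atan2(ref[2] - p[2], ref[1] - p[1]))
  a_hit <- rad2deg(atan2(fw$contact_xy[2] - p[2], fw$contact_xy[1] - p[1]))
  unname(ang_diff(a_ref, a_hit))
}

#' Initial heading angle of a return path
#'
#' Heading over the first `window` cm of the return path (direction of
#' the displacement from the pellet to the first sample at least
#' `window` cm of path length away), compared with the direction from
#' the pellet to the refuge center; absolute angle in \[0, 180\]. For
#' paths shorter than `window` the window shrinks to the path length
#' (flagged by attribute `shrunk`).
#'
#' @param path a `return_path`
#' @param arena the `arena`
#' @param window initial path length, cm
#' @return degrees in \[0, 180\]
#' @export
initial_heading_angle <- function(path, arena = path$arena, window = 10) {
  seg <- sqrt(diff(path$x)^2 + diff(path$y)^2)
  cum <- c(0, cumsum(seg))
  i <- which(cum >= window)[1]
  shrunk <- FALSE
  if (is.na(i)) { i <- length(path$x); shrunk <- TRUE }
  p <- path$pellet_xy
  ref <- refuge_center(arena)
  a_head <- rad2deg(atan2(path$y[i] - p[2], path$x[i] - p[1]))
  a_ref <- rad2deg(atan2(ref[2] - p[2], ref[1] - p[1]))
  out <- unname(ang_diff(a_head, a_ref))
  attr(out, "shrunk") <- shrunk
  out
}

#' Normalized distance travelled
#'
#' Polyline length of the return path divided by the straight-line
#' distance from the pellet to the refuge center, as a percentage
#' (>= 100% for a complete path; 100% for a straight run).
#'
#' @param path a `return_path`
#' @param arena the `arena`
#' @return percent; NA (with a warning) for zero straight-line distance
#' @export
normalized_distance <- function(path, arena = path$arena) {
  p <- path$pellet_xy
  ref <- refuge_center(arena)
  d <- sqrt(sum((ref - p)^2))
  if (d < 1e-9) {
    warning("pellet at refuge; normalized distance undefined")
    return(NA_real_)
  }
  len <- sum(sqrt(diff(path$x)^2 + diff(path$y)^2))
  100 * len / d
}

#' Thigmotaxis fraction of a return path
#'
#' Fraction of return-path samples within the peripheral band (distance
#' to the nearest wall at most `band` of the circumradius, ~4.8 cm for
#' the 63.8 cm decagon).
#'
#' @param path a `return_path`
#' @param arena the `arena`
#' @param band band width as a fraction of the circumradius
#' @return fraction in \[0, 1\]
#' @export
thigmotaxis <- function(path, arena = path$arena, band = 0.15) {
  R <- if (arena$shape == "decagon") arena$circumradius else
    min(arena$width, arena$height) / 2
  band_cm <- band * R
  d <- nearest_wall(arena, path$x, path$y)$distance
  mean(d <= band_cm)
}

#' Probability of reaching the refuge on the first wall encounter
#'
#' @param trials list of `return_path`s
#' @param arena the `arena` (defaults to the first trial's)
#' @param contact_dist wall-contact distance, cm
#' @return fraction of trials whose first wall is the refuge wall
#' @export
refuge_probability <- function(trials, arena = NULL, contact_dist = 2) {
  if (!length(trials)) stop_invalid("empty trial list")
  if (is.null(arena)) arena <- trials[[1]]$arena
  hits <- vapply(trials, function(p)
    first_wall_encounter(p, arena, contact_dist)$wall, integer(1))
  mean(hits == arena$refuge_wall, na.rm = FALSE)
}

#' Wall-likelihood vector over W1-W10
#'
#' @param trials list of `return_path`s
#' @param arena the `arena`
#' @param contact_dist wall-contact distance, cm
#' @return named numeric: P(first wall = W1..W10) plus `incomplete`;
#'   sums to 1
#' @export
wall_likelihood <- function(trials, arena = NULL, contact_dist = 2) {
  if (!length(trials)) stop_invalid("empty trial list")
  if (is.null(arena)) arena <- trials[[1]]$arena
  nwalls <- nrow(wall_segments(arena))
  hits <- vapply(trials, function(p)
    first_wall_encounter(p, arena, contact_dist)$wall, integer(1))
  out <- c(tabulate(hits[!is.na(hits)], nwalls), sum(is.na(hits))) /
    length(trials)
  names(out) <- c(paste0("W", seq_len(nwalls)), "incomplete")
  out
}

#' All four path-integration metrics for one trial
#'
#' @param path a `return_path`
#' @param arena the `arena`
#' @param ... passed to the metric functions
#' @return one-row data frame: first_wall, initial_wall_angle,
#'   initial_heading_angle, normalized_distance, thigmotaxis, outcome
#' @export
path_metrics <- function(path, arena = path$arena, ...) {
  fw <- first_wall_encounter(path, arena, ...)
  data.frame(first_wall = fw$wall,
             initial_wall_angle = initial_wall_angle(path, arena, ...),
             initial_heading_angle = as.numeric(initial_heading_angle(path, arena)),
             normalized_distance = normalized_distance(path, arena),
             thigmotaxis = thigmotaxis(path, arena),
             outcome = path$outcome,
             stringsAsFactors = FALSE)
}

#' Simulate homing (path-integration) trials in the decagonal arena
#'
#' Each trial places a food pellet uniformly in the arena interior; the
#' simulated mouse heads from the pellet toward the refuge-wall center
#' with a von Mises heading error of scale `heading_noise_sd` (>= 180
#' degrees means a uniformly random heading), walks straight until first
#' wall contact, then follows the wall (the short way around) to the
#' refuge. With probability `thigmotaxis_bias` a trial is wall-seeking:
#' the initial heading is aimed at a uniformly random wall point instead
#' of the refuge.
#'
#' @param arena a decagonal `arena`
#' @param n_trials number of trials
#' @param heading_noise_sd heading error scale, degrees (>= 0)
#' @param thigmotaxis_bias probability of a wall-seeking trial, in \[0,1\]
#' @param speed walking speed, cm/s
#' @param sample_rate path sampling rate, Hz
#' @param margin minimum pellet distance from walls, cm
#' @param seed RNG seed
#' @return list of `return_path`s
#' @export
simulate_homing_trials <- function(arena = arena_decagon(), n_trials = 10,
                                   heading_noise_sd = 0,
                                   thigmotaxis_bias = 0, speed = 12,
                                   sample_rate = 30, margin = 5,
                                   seed = NULL) {
  stopifnot(arena$shape == "decagon")
  if (heading_noise_sd < 0) stop_invalid("heading_noise_sd must be >= 0")
  if (thigmotaxis_bias < 0 || thigmotaxis_bias > 1) {
    stop_invalid("thigmotaxis_bias must be in [0, 1]")
  }
  R <- arena$circumradius
  ref <- refuge_center(arena)
  with_seed(seed, {
    lapply(seq_len(n_trials), function(k) {
      # pellet: uniform over the interior with a wall margin
      repeat {
        px <- stats::runif(1, -R, R); py <- stats::runif(1, -R, R)
        if (in_arena(arena, px, py, margin = margin)) break
      }
      wall_seeking <- stats::runif(1) < thigmotaxis_bias
      target_ang <- if (wall_seeking) {
        stats::runif(1, 0, 360)
      } else {
        rad2deg(atan2(ref[2] - py, ref[1] - px))
      }
      err <- if (heading_noise_sd >= 180) {
        stats::runif(1, -180, 180)
      } else if (heading_noise_sd > 0) {
        kappa <- 1 / deg2rad(heading_noise_sd)^2
        rad2deg(rvonmises1(kappa))
      } else 0
      heading <- target_ang + err
      hit <- ray_wall_intersection(arena, px, py, heading)
      dt <- 1 / sample_rate
      # straight leg to the wall-contact point
      n1 <- max(2L, ceiling(hit$distance / speed / dt))
      s <- seq(0, hit$distance, length.out = n1)
      x <- px + s * cos(deg2rad(heading))
      y <- py + s * sin(deg2rad(heading))
      # then follow the boundary the short way around to the refuge center
      if (sqrt((x[n1] - ref[1])^2 + (y[n1] - ref[2])^2) > 1e-9) {
        a0 <- atan2(y[n1], x[n1])
        a1 <- atan2(ref[2], ref[1])
        d_ccw <- (a1 - a0) %% (2 * pi)
        dir <- if (d_ccw <= pi) 1 else -1
        arc <- if (dir == 1) d_ccw else 2 * pi - d_ccw
        n2 <- max(2L, ceiling(arc * R / speed / dt))
        aa <- a0 + dir * seq(0, arc, length.out = n2)[-1]
        rr <- vapply(aa, function(a) {
          ray_wall_intersection(arena, 0, 0, rad2deg(a))$distance
        }, numeric(1))
        x <- c(x, rr * cos(aa))
        y <- c(y, rr * sin(aa))
      }
      t <- seq_along(x) * dt
      return_path(t, x, y, arena, outcome = "success")
    })
  })
}

# one von Mises draw (radians, mean 0) by Best-Fisher rejection
rvonmises1 <- function(kappa) {
  if (kappa < 1e-8) return(stats::runif(1, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  repeat {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u2 > 0 || log(c_ / u2) + 1 - c_ >= 0) {
      return(sign(u3 - 0.5) * acos(pmax(-1, pmin(1, f))))
    }
  }
}
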