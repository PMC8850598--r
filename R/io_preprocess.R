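#' Fill short tracking dropouts by interpolation
#'
#' Runs of up to `max_gap` consecutive missing samples (occluded or
#' reflected tracking diodes) are replaced by linear interpolation of the
#' diode coordinates; longer runs are left missing and excluded from
#' downstream analyses. Observed samples are never altered.
#'
#' @param raw a `raw_tracking` data frame (t, red_x, red_y, green_x, green_y)
#' @param max_gap longest run of missing samples to fill
#' @return `raw_tracking` with short gaps filled
#' @export
interpolate_gaps <- function(raw, max_gap = 5) {
  if (is.unsorted(raw$t, strictly = TRUE)) stop_invalid("t must be strictly increasing")
  cols <- intersect(c("red_x", "red_y", "green_x", "green_y", "x", "y"),
                    names(raw))
  miss <- !stats::complete.cases(raw[cols])
  if (!any(miss)) return(raw)
  runs <- rle(miss)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  fill <- rep(FALSE, nrow(raw))
  for (k in which(runs$values)) {
    # only interior gaps of length <= max_gap are fillable
    if (runs$lengths[k] <= max_gap && starts[k] > 1 && ends[k] < nrow(raw)) {
      fill[starts[k]:ends[k]] <- TRUE
    }
  }
  for (cl in cols) {
    ok <- !is.na(raw[[cl]])
    if (sum(ok) < 2) next
    interp <- stats::approx(raw$t[ok], raw[[cl]][ok], raw$t[fill])$y
    raw[[cl]][fill] <- interp
  }
  raw
}

#' Interpolate short gaps in an angular series (circular)
#'
#' Angles are interpolated on the unit circle (via their sine and cosine),
#' so a gap spanning the 359 -> 1 degree wrap fills with values near 0,
#' not 180. Runs longer than `max_gap` stay missing.
#'
#' @param t sample times, strictly increasing
#' @param deg angles in degrees, NA where missing
#' @param max_gap longest run to fill
#' @return angles in degrees in \[0, 360)
#' @export
interpolate_angles <- function(t, deg, max_gap = 5) {
  miss <- is.na(deg)
  if (!any(miss)) return(wrap360(deg))
  runs <- rle(miss)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  fill <- rep(FALSE, length(deg))
  for (k in which(runs$values)) {
    if (runs$lengths[k] <= max_gap && starts[k] > 1 && ends[k] < length(deg)) {
      fill[starts[k]:ends[k]] <- TRUE
    }
  }
  ok <- !miss
  if (sum(ok) >= 2 && any(fill)) {
    cs <- stats::approx(t[ok], cos(deg2rad(deg[ok])), t[fill])$y
    sn <- stats::approx(t[ok], sin(deg2rad(deg[ok])), t[fill])$y
    deg[fill] <- rad2deg(atan2(sn, cs))
  }
  out <- wrap360(deg)
  out[is.na(deg)] <- NA_real_
  out
}

#' Head direction from two-diode tracking
#'
#' The head direction is the angle of the vector from the green to the red
#' diode, mapped to \[0, 360) with 0 degrees along +x and counterclockwise
#' positive. Samples where the diodes coincide give a missing direction.
#'
#' @param raw a `raw_tracking` data frame
#' @return head direction in degrees, NA where undefined
#' @export
head_direction <- function(raw) {
  dx <- raw$red_x - raw$green_x
  dy <- raw$red_y - raw$green_y
  hd <- wrap360(rad2deg(atan2(dy, dx)))
  hd[!is.na(dx) & !is.na(dy) & dx == 0 & dy == 0] <- NA_real_
  hd
}

#' Running speed from positions via a Kalman filter
#'
#' A constant-velocity Kalman filter over (x, y) with process noise
#' `process_noise` (cm/s^2 scale) and measurement noise `meas_noise` (cm).
#' Speed is the norm of the filtered velocity; for noiseless straight-line
#' motion the output converges to the true speed within a ~1 s burn-in,
#' and for a stationary animal with tracking jitter it is smaller than the
#' raw finite-difference speed.
#'
#' @param x,y positions, cm
#' @param t sample times, s (approximately uniform)
#' @param process_noise accel noise scale, cm/s^2
#' @param meas_noise position measurement noise SD, cm
#' @return speed, cm/s (same length as x)
#' @export
kalman_speed <- function(x, y, t, process_noise = 10, meas_noise = 0.5) {
  n <- length(x)
  if (n < 10) stop_insufficient("kalman_speed needs at least 10 samples")
  dt <- stats::median(diff(t))
  F_ <- diag(4)
  F_[1, 3] <- dt; F_[2, 4] <- dt
  q <- process_noise^2
  # discrete white-noise acceleration model
  Q <- q * matrix(c(dt^4 / 4, 0, dt^3 / 2, 0,
                    0, dt^4 / 4, 0, dt^3 / 2,
                    dt^3 / 2, 0, dt^2, 0,
                    0, dt^3 / 2, 0, dt^2), 4, 4)
  H <- matrix(0, 2, 4); H[1, 1] <- 1; H[2, 2] <- 1
  R <- diag(meas_noise^2, 2)
  s <- c(x[1], y[1], 0, 0)
  P <- diag(c(meas_noise^2, meas_noise^2, 100, 100))
  speed <- numeric(n)
  for (i in seq_len(n)) {
    if (i > 1) {
      s <- F_ %*% s
      P <- F_ %*% P %*% t(F_) + Q
    }
    z <- c(x[i], y[i])
    if (all(is.finite(z))) {
      S <- H %*% P %*% t(H) + R
      K <- P %*% t(H) %*% solve(S)
      s <- s + K %*% (z - H %*% s)
      P <- (diag(4) - K %*% H) %*% P
    }
    speed[i] <- sqrt(s[3]^2 + s[4]^2)
  }
  speed
}

#' Preprocess raw tracking into a trajectory
#'
#' Interpolates short dropouts, converts pixels to cm if needed, computes
#' the diode-centroid position, head direction (with circular gap
#' filling), and Kalman-filtered running speed.
#'
#' @param raw a `raw_tracking` data frame
#' @param pixels_per_cm scale factor; coordinates are divided by it
#'   (use 1 if already in cm)
#' @param arena optional `arena` to attach
#' @param max_gap dropout run length to fill
#' @param ... passed to [kalman_speed()]
#' @return a `trajectory`; samples still missing after interpolation are
#'   dropped (their count is reported as attribute `n_dropped`)
#' @export
preprocess_tracking <- function(raw, pixels_per_cm = 1, arena = NULL,
                                max_gap = 5, ...) {
  raw <- interpolate_gaps(raw, max_gap = max_gap)
  cx <- (raw$red_x + raw$green_x) / 2 / pixels_per_cm
  cy <- (raw$red_y + raw$green_y) / 2 / pixels_per_cm
  hd <- head_direction(raw)
  hd <- interpolate_angles(raw$t, hd, max_gap = max_gap)
  keep <- is.finite(cx) & is.finite(cy)
  n_dropped <- sum(!keep)
  t <- raw$t[keep]; cx <- cx[keep]; cy <- cy[keep]; hd <- hd[keep]
  speed <- kalman_speed(cx, cy, t, ...)
  traj <- trajectory(t, cx, cy, hd = hd, speed = speed, arena = arena)
  attr(traj, "n_dropped") <- n_dropped
  traj
}

#' Write a session bundle
#'
#' Serializes one recording session to an open on-disk layout:
#' `positions.csv` (t, x, y and diode coordinates when available),
#' `cells/<id>.csv` (spike times with waveform width and region),
#' `lfp.dat` (little-endian float32) with an `lfp.json` header, and
#' `session.yaml` metadata (arena geometry, cell metadata, optional
#' ground-truth generator parameters).
#'
#' @param dir directory to create
#' @param traj a `trajectory`
#' @param cells list of `spike_train`s
#' @param lfp optional `lfp_trace`
#' @param ground_truth optional list stored verbatim in the sidecar
#' @return `dir`, invisibly
#' @export
write_session_bundle <- function(dir, traj, cells = list(), lfp = NULL,
                                 ground_truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "cells"), showWarnings = FALSE)
  utils::write.csv(as.data.frame(traj), file.path(dir, "positions.csv"),
                   row.names = FALSE)
  cell_meta <- list()
  for (cell in cells) {
    utils::write.csv(data.frame(t = cell$times),
                     file.path(dir, "cells", paste0(cell$cell_id, ".csv")),
                     row.names = FALSE)
    cell_meta[[cell$cell_id]] <- list(waveform_width = cell$waveform_width,
                                      region = cell$region)
  }
  if (!is.null(lfp)) {
    con <- file(file.path(dir, "lfp.dat"), "wb")
    writeBin(lfp$samples, con, size = 4, endian = "little")
    close(con)
    jsonlite::write_json(list(rate = lfp$rate, t0 = lfp$t0,
                              n = length(lfp$samples), dtype = "float32le"),
                         file.path(dir, "lfp.json"), auto_unbox = TRUE)
  }
  arena <- traj_arena(traj)
  meta <- list(cells = cell_meta)
  if (!is.null(arena)) meta$arena <- unclass(arena)[setdiff(names(arena), "vertices")]
  if (!is.null(ground_truth)) meta$ground_truth <- ground_truth
  yaml::write_yaml(meta, file.path(dir, "session.yaml"))
  invisible(dir)
}

#' Read a session bundle written by [write_session_bundle()]
#'
#' @param dir bundle directory
#' @return list with `traj`, `cells` (list of `spike_train`), `lfp`
#'   (or NULL), and `meta` (parsed session.yaml)
#' @export
read_session_bundle <- function(dir) {
  pos_file <- file.path(dir, "positions.csv")
  if (!file.exists(pos_file)) {
    stop_invalid(sprintf("missing positions.csv in '%s'", dir))
  }
  pos <- utils::read.csv(pos_file)
  need <- c("t", "x", "y")
  if (!all(need %in% names(pos))) {
    stop_invalid(sprintf("positions.csv must have columns %s",
                         paste(need, collapse = ", ")))
  }
  meta <- if (file.exists(file.path(dir, "session.yaml"))) {
    yaml::read_yaml(file.path(dir, "session.yaml"))
  } else list()
  arena <- NULL
  if (!is.null(meta$arena)) {
    arena <- if (identical(meta$arena$shape, "rectangle")) {
      arena_rect(meta$arena$width, meta$arena$height)
    } else {
      arena_decagon(meta$arena$diameter, meta$arena$refuge_wall)
    }
  }
  traj <- trajectory(pos$t, pos$x, pos$y,
                     hd = if ("hd" %in% names(pos)) pos$hd else NULL,
                     speed = if ("speed" %in% names(pos)) pos$speed else NULL,
                     arena = arena)
  cell_files <- sort(list.files(file.path(dir, "cells"), pattern = "\\.csv$",
                                full.names = TRUE))
  cells <- lapply(cell_files, function(f) {
    id <- sub("\\.csv$", "", basename(f))
    cm <- meta$cells[[id]]
    spike_train(utils::read.csv(f)$t, cell_id = id,
                waveform_width = if (!is.null(cm$waveform_width)) cm$waveform_width else 0.4,
                region = if (!is.null(cm$region)) cm$region else "MEC")
  })
  names(cells) <- vapply(cells, function(cl) cl$cell_id, character(1))
  lfp <- NULL
  if (file.exists(file.path(dir, "lfp.json"))) {
    hdr <- jsonlite::read_json(file.path(dir, "lfp.json"), simplifyVector = TRUE)
    con <- file(file.path(dir, "lfp.dat"), "rb")
    samples <- readBin(con, "numeric", n = hdr$n, size = 4, endian = "little")
    close(con)
    lfp <- lfp_trace(samples, rate = as.numeric(hdr$rate),
                     t0 = as.numeric(hdr$t0))
  }
  list(traj = traj, cells = cells, lfp = lfp, meta = meta)
}
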