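# Radial profile of an autocorrelogram: mean correlation in 1-bin-wide
# rings, used to delimit the central field by its first zero crossing.
.radial_profile <- function(ac) {
  C <- ac$corr
  ctr <- ac$center
  rc <- expand.grid(r = seq_len(nrow(C)), c = seq_len(ncol(C)))
  d <- sqrt((rc$r - ctr[1])^2 + (rc$c - ctr[2])^2)
  ring <- floor(d)
  v <- as.vector(C)
  ok <- is.finite(v)
  prof <- tapply(v[ok], ring[ok], mean)
  list(radius = as.numeric(names(prof)) + 0.5, value = as.numeric(prof))
}

# Central-field radius in bins: first zero crossing of the angularly
# averaged correlation; falls back to half the median peak distance.
central_field_radius <- function(ac, peaks = NULL) {
  prof <- .radial_profile(ac)
  neg <- which(prof$value < 0)
  if (length(neg)) {
    i <- neg[1]
    if (i > 1) {
      # linear interpolation between the straddling rings
      v0 <- prof$value[i - 1]; v1 <- prof$value[i]
      r0 <- prof$radius[i - 1]; r1 <- prof$radius[i]
      return(r0 + (0 - v0) / (v1 - v0) * (r1 - r0))
    }
    return(prof$radius[1])
  }
  if (!is.null(peaks) && nrow(peaks)) {
    return(stats::median(peaks[, "radius"]) / 2)
  }
  max(prof$radius) / 4
}

#' Six inner peaks of a spatial autocorrelogram
#'
#' Finds the six local maxima closest to the central peak, outside the
#' central field (delimited by the first zero crossing of the angularly
#' averaged correlation). Peak detection runs on a lightly smoothed copy
#' of the autocorrelogram; ties are broken by distance then angle.
#'
#' @param ac a `spatial_autocorr`
#' @param smooth_sd light smoothing SD (bins) before peak detection
#' @return matrix with columns row, col, radius (bins), angle (deg),
#'   value; exactly six rows
#' @export
inner_peaks <- function(ac, smooth_sd = 1) {
  C <- ac$corr
  ctr <- ac$center
  Cs <- if (smooth_sd > 0) smooth_map(C, is.finite(C), smooth_sd) else C
  r0 <- central_field_radius(ac)
  nr <- nrow(Cs); nc <- ncol(Cs)
  cand <- NULL
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    v <- Cs[i, j]
    if (!is.finite(v) || v <= 0) next
    d <- sqrt((i - ctr[1])^2 + (j - ctr[2])^2)
    if (d <= r0) next
    nb <- Cs[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (v >= max(nb, na.rm = TRUE)) {
      cand <- rbind(cand, c(row = i, col = j, radius = d,
                            angle = wrap360(rad2deg(atan2(j - ctr[2], i - ctr[1]))),
                            value = v))
    }
  }
  if (is.null(cand) || nrow(cand) < 6) {
    stop_insufficient("fewer than six peaks outside the central field",
                      class = "gridcells_insufficient_peaks")
  }
  # drop adjacent duplicates of the same blob: keep the higher of any two
  # candidates closer than 2 bins apart
  ord <- order(cand[, "value"], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      for (j in (i + 1):nrow(cand)) {
        if (keep[j] &&
            sqrt((cand[i, 1] - cand[j, 1])^2 + (cand[i, 2] - cand[j, 2])^2) < 2) {
          keep[j] <- FALSE
        }
      }
    }
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) < 6) {
    stop_insufficient("fewer than six distinct peaks outside the central field",
                      class = "gridcells_insufficient_peaks")
  }
  ord <- order(cand[, "radius"], cand[, "angle"])
  cand[ord, , drop = FALSE][1:6, , drop = FALSE]
}

# Fit an origin-centered ellipse a x^2 + b xy + c y^2 = 1 to points
# (least squares). Returns axes (bins) and major-axis orientation (deg),
# or NULL on a degenerate fit.
fit_ellipse <- function(xy) {
  D <- cbind(xy[, 1]^2, xy[, 1] * xy[, 2], xy[, 2]^2)
  coefs <- tryCatch(solve(crossprod(D), crossprod(D, rep(1, nrow(xy)))),
                    error = function(e) NULL)
  if (is.null(coefs)) return(NULL)
  Q <- matrix(c(coefs[1], coefs[2] / 2, coefs[2] / 2, coefs[3]), 2, 2)
  eg <- eigen(Q, symmetric = TRUE)
  if (any(eg$values <= 0)) return(NULL)
  axes <- 1 / sqrt(eg$values)         # descending eigenvalue = minor axis
  major <- max(axes); minor <- min(axes)
  major_vec <- eg$vectors[, which.min(eg$values)]
  list(major = major, minor = minor,
       orientation = wrap360(rad2deg(atan2(major_vec[2], major_vec[1]))) %% 180)
}

#' Elliptical-eccentricity correction of an autocorrelogram
#'
#' Fits an origin-centered ellipse to the six inner peaks and, when the
#' eccentricity is moderate (minor axis at least half the major axis),
#' compresses the whole autocorrelogram along the major axis so the major
#' axis equals the minor axis. Large eccentricities are not corrected and
#' the input is returned flagged `corrected = FALSE`.
#'
#' @param ac a `spatial_autocorr`
#' @param peaks six-peak matrix from [inner_peaks()] (computed if NULL)
#' @return the input `spatial_autocorr` with attributes `corrected`
#'   (logical) and `ellipse` (major, minor in cm, orientation deg)
#' @export
ellipse_correct <- function(ac, peaks = NULL) {
  if (is.null(peaks)) peaks <- inner_peaks(ac)
  ctr <- ac$center
  xy <- cbind(peaks[, "row"] - ctr[1], peaks[, "col"] - ctr[2])
  el <- fit_ellipse(xy)
  if (is.null(el)) {
    attr(ac, "corrected") <- FALSE
    attr(ac, "ellipse") <- NULL
    attr(ac, "flag") <- "degenerate ellipse fit"
    return(ac)
  }
  ellipse_cm <- list(major = el$major * ac$lag_size,
                     minor = el$minor * ac$lag_size,
                     orientation = el$orientation)
  if (el$minor < el$major / 2 || el$major / el$minor < 1 + 1e-6) {
    attr(ac, "corrected") <- FALSE
    attr(ac, "ellipse") <- ellipse_cm
    if (el$minor < el$major / 2) attr(ac, "flag") <- "eccentricity too large"
    return(ac)
  }
  f <- el$minor / el$major
  th <- deg2rad(el$orientation)
  C <- ac$corr
  rc <- expand.grid(r = seq_len(nrow(C)), c = seq_len(ncol(C)))
  dx <- rc$r - ctr[1]; dy <- rc$c - ctr[2]
  # target pixel u maps to source R(th) diag(1/f, 1) R(-th) u
  px <- cos(th) * dx + sin(th) * dy
  py <- -sin(th) * dx + cos(th) * dy
  px <- px / f
  sx <- ctr[1] + cos(th) * px - sin(th) * py
  sy <- ctr[2] + sin(th) * px + cos(th) * py
  out <- ac
  out$corr <- matrix(bilinear_sample(C, sx, sy), nrow(C), ncol(C))
  attr(out, "corrected") <- TRUE
  attr(out, "ellipse") <- ellipse_cm
  out
}

#' Gridness score with elliptical correction
#'
#' Quantifies hexagonal spatial periodicity: after optional elliptical
#' correction, an annulus is extracted that encases the six peaks closest
#' to the center but excludes the central peak (inner radius = central
#' field radius from the first zero crossing; outer radius = farthest
#' inner-peak radius + central field radius). The annulus is correlated
#' with rotated copies of itself in 3-degree steps over \[0, 180\]
#' degrees, and the gridness score is the difference between the lowest
#' correlation at 60 or 120 degrees and the highest correlation at 30, 90,
#' or 150 degrees. Scores above 0.54 (the dataset-wide 99th-percentile
#' shuffle threshold) mark grid cells.
#'
#' @param ac a `spatial_autocorr`
#' @param correct_ellipse apply [ellipse_correct()] when six peaks are found
#' @param rotation_step rotational resolution, degrees
#' @param min_pairs minimum valid annulus pixel pairs per rotation
#' @return a `grid_score`: `gridness`, `rotational_corr` data frame
#'   (angle, corr), `ellipse`, `annulus` (inner/outer radius, cm),
#'   `corrected`, `valid`
#' @export
gridness_score <- function(ac, correct_ellipse = TRUE, rotation_step = 3,
                           min_pairs = 50) {
  peaks <- tryCatch(inner_peaks(ac), error = function(e) NULL)
  corrected <- FALSE
  ellipse <- NULL
  if (!is.null(peaks) && correct_ellipse) {
    ac2 <- ellipse_correct(ac, peaks)
    corrected <- isTRUE(attr(ac2, "corrected"))
    ellipse <- attr(ac2, "ellipse")
    if (corrected) {
      ac <- ac2
      peaks <- tryCatch(inner_peaks(ac), error = function(e) peaks)
    }
  }
  r0 <- central_field_radius(ac, peaks)
  r_out <- if (!is.null(peaks)) max(peaks[, "radius"]) + r0 else 2.5 * r0
  ctr <- ac$center
  C <- ac$corr
  nr <- nrow(C); nc <- ncol(C)
  r_out <- min(r_out, min(ctr[1] - 1, nr - ctr[1], ctr[2] - 1, nc - ctr[2]))
  # Resample the annulus once onto a polar grid (radial step 0.5 bin,
  # angular step = rotation_step); a rotation is then an exact circular
  # shift of the angular index, so every angle receives identical
  # interpolation treatment (no bias toward pixel-aligned rotations).
  # Samples are weighted by radius (the polar area element) so the
  # correlation matches the uniform-pixel definition.
  radii <- if (r_out > r0 + 0.5) seq(r0 + 0.25, r_out, by = 0.5) else numeric(0)
  angles <- seq(0, 180, by = rotation_step)
  nphi <- round(360 / rotation_step)
  phis <- deg2rad((seq_len(nphi) - 1) * rotation_step)
  corr <- rep(NA_real_, length(angles))
  valid <- TRUE
  if (length(radii) >= 2) {
    P <- matrix(NA_real_, length(radii), nphi)
    for (j in seq_len(nphi)) {
      P[, j] <- bilinear_sample(C, ctr[1] + radii * cos(phis[j]),
                                ctr[2] + radii * sin(phis[j]))
    }
    W <- matrix(radii, length(radii), nphi)
    wcor <- function(a, b, w) {
      sw <- sum(w)
      ma <- sum(w * a) / sw; mb <- sum(w * b) / sw
      cov <- sum(w * (a - ma) * (b - mb))
      va <- sum(w * (a - ma)^2); vb <- sum(w * (b - mb)^2)
      if (va <= 0 || vb <= 0) return(NA_real_)
      cov / sqrt(va * vb)
    }
    for (k in seq_along(angles)) {
      shift <- round(angles[k] / rotation_step)
      idx <- ((seq_len(nphi) - 1 + shift) %% nphi) + 1
      B <- P[, idx, drop = FALSE]
      ok <- is.finite(P) & is.finite(B)
      if (sum(ok) < min_pairs) { valid <- FALSE; next }
      corr[k] <- wcor(P[ok], B[ok], W[ok])
    }
  } else {
    valid <- FALSE
  }
  pick <- function(a) corr[match(a, angles)]
  gridness <- min(pick(60), pick(120)) - max(pick(30), pick(90), pick(150))
  if (!valid || !is.finite(gridness)) {
    gridness <- NA_real_
    valid <- FALSE
  }
  structure(list(gridness = gridness,
                 rotational_corr = data.frame(angle = angles, corr = corr),
                 ellipse = ellipse,
                 annulus = c(inner = r0 * ac$lag_size,
                             outer = r_out * ac$lag_size),
                 corrected = corrected, valid = valid,
                 peaks = peaks),
            class = "grid_score")
}

#' @export
print.grid_score <- function(x, ...) {
  cat(sprintf("grid_score: gridness %.3f (%s, annulus %.1f-%.1f cm)\n",
              x$gridness, if (x$corrected) "ellipse-corrected" else "uncorrected",
              x$annulus["inner"], x$annulus["outer"]))
  invisible(x)
}

#' Gridness of a cell from its trajectory and spikes
#'
#' Convenience wrapper: rate map -> spatial autocorrelogram -> gridness.
#'
#' @param traj a `trajectory`
#' @param spikes a `spike_train`
#' @param ... passed to [make_ratemap()]
#' @return a `grid_score`
#' @export
grid_score_for_cell <- function(traj, spikes, ...) {
  gridness_score(spatial_autocorr(make_ratemap(traj, spikes, ...)))
}
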