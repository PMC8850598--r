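#' Arena geometries
#'
#' Recording environments: rectangular open fields (coordinates in cm,
#' origin at the lower-left corner) and the ten-sided homing arena
#' (diameter 63.8 cm, coordinates centered on the arena center) with one
#' wall designated as the refuge door.
#'
#' @param width,height rectangle dimensions in cm
#' @param diameter decagon circumscribed diameter in cm
#' @param refuge_wall index (1-10) of the refuge wall
#' @return an object of class `arena`
#' @examples
#' box <- arena_rect(75, 75)
#' maze <- arena_decagon()
#' @export
arena_rect <- function(width, height = width) {
  if (width <= 0 || height <= 0) stop_invalid("arena dimensions must be positive")
  structure(list(shape = "rectangle", width = width, height = height,
                 center = c(width / 2, height / 2)),
            class = "arena")
}

#' @rdname arena_rect
#' @export
arena_decagon <- function(diameter = 63.8, refuge_wall = 1L) {
  if (diameter <= 0) stop_invalid("diameter must be positive")
  refuge_wall <- as.integer(refuge_wall)
  if (refuge_wall < 1L || refuge_wall > 10L) stop_invalid("refuge_wall must be in 1..10")
  R <- diameter / 2
  # vertex k at angle 2*pi*(k-1)/10; wall i joins vertex i to vertex i+1
  ang <- 2 * pi * (0:9) / 10
  vx <- R * cos(ang)
  vy <- R * sin(ang)
  structure(list(shape = "decagon", diameter = diameter, circumradius = R,
                 vertices = cbind(x = vx, y = vy),
                 refuge_wall = refuge_wall, center = c(0, 0)),
            class = "arena")
}

#' @export
print.arena <- function(x, ...) {
  if (x$shape == "rectangle") {
    cat(sprintf("arena: rectangle %g x %g cm\n", x$width, x$height))
  } else {
    cat(sprintf("arena: decagon, diameter %g cm, refuge wall W%d\n",
                x$diameter, x$refuge_wall))
  }
  invisible(x)
}

#' Wall segments of an arena
#'
#' @param arena an `arena` object
#' @return matrix with columns x1, y1, x2, y2, one row per wall
#'   (4 for rectangles, 10 for the decagon, wall i = W-i)
#' @export
wall_segments <- function(arena) {
  if (arena$shape == "rectangle") {
    w <- arena$width; h <- arena$height
    m <- rbind(c(0, 0, w, 0), c(w, 0, w, h), c(w, h, 0, h), c(0, h, 0, 0))
  } else {
    v <- arena$vertices
    nxt <- c(2:10, 1)
    m <- cbind(v[, 1], v[, 2], v[nxt, 1], v[nxt, 2])
  }
  colnames(m) <- c("x1", "y1", "x2", "y2")
  m
}

#' Midpoints of arena walls
#' @param arena an `arena` object
#' @return matrix of wall-center coordinates (cm)
#' @export
wall_centers <- function(arena) {
  s <- wall_segments(arena)
  cbind(x = (s[, "x1"] + s[, "x2"]) / 2, y = (s[, "y1"] + s[, "y2"]) / 2)
}

#' Center of the refuge wall of a decagonal arena
#' @param arena decagon `arena`
#' @return length-2 numeric (cm)
#' @export
refuge_center <- function(arena) {
  stopifnot(arena$shape == "decagon")
  wall_centers(arena)[arena$refuge_wall, ]
}

#' Point-in-arena test (vectorized)
#' @param arena an `arena` object
#' @param x,y coordinates in cm
#' @param margin shrink the arena by this distance (cm) before testing
#' @return logical vector
#' @export
in_arena <- function(arena, x, y, margin = 0) {
  if (arena$shape == "rectangle") {
    x >= margin & x <= arena$width - margin & y >= margin & y <= arena$height - margin
  } else {
    # convex polygon: inside iff left of (or on) every directed edge,
    # offset inward by `margin` along the inward normal
    s <- wall_segments(arena)
    ok <- rep(TRUE, length(x))
    for (i in seq_len(nrow(s))) {
      ex <- s[i, "x2"] - s[i, "x1"]; ey <- s[i, "y2"] - s[i, "y1"]
      len <- sqrt(ex^2 + ey^2)
      # cross product (edge x point-rel); vertices are counterclockwise
      cr <- ex * (y - s[i, "y1"]) - ey * (x - s[i, "x1"])
      ok <- ok & (cr / len >= margin)
    }
    ok
  }
}

# distance from points to one segment (vectorized over points)
.seg_dist <- function(x, y, x1, y1, x2, y2) {
  ex <- x2 - x1; ey <- y2 - y1
  L2 <- ex^2 + ey^2
  t <- pmin(1, pmax(0, ((x - x1) * ex + (y - y1) * ey) / L2))
  px <- x1 + t * ex; py <- y1 + t * ey
  sqrt((x - px)^2 + (y - py)^2)
}

#' Distance to the nearest wall, and which wall it is
#' @param arena an `arena` object
#' @param x,y coordinates in cm
#' @return list with `distance` (cm) and `wall` (index) vectors
#' @export
nearest_wall <- function(arena, x, y) {
  s <- wall_segments(arena)
  d <- sapply(seq_len(nrow(s)), function(i)
    .seg_dist(x, y, s[i, 1], s[i, 2], s[i, 3], s[i, 4]))
  if (is.null(dim(d))) d <- matrix(d, nrow = 1)
  wall <- max.col(-d, ties.method = "first")
  list(distance = d[cbind(seq_along(x), wall)], wall = wall)
}

#' First intersection of a ray with the arena boundary
#'
#' Casts a ray from an interior point and returns the first wall hit and
#' the contact point; used by the homing-trial generator and by geometric
#' oracles for wall-hit probabilities.
#'
#' @param arena an `arena` object
#' @param x0,y0 ray origin (cm), inside the arena
#' @param angle_deg ray direction (degrees, 0 = +x, counterclockwise)
#' @return list(wall, x, y, distance)
#' @export
ray_wall_intersection <- function(arena, x0, y0, angle_deg) {
  th <- deg2rad(angle_deg)
  dx <- cos(th); dy <- sin(th)
  s <- wall_segments(arena)
  best <- list(wall = NA_integer_, x = NA_real_, y = NA_real_, distance = Inf)
  for (i in seq_len(nrow(s))) {
    ex <- s[i, "x2"] - s[i, "x1"]; ey <- s[i, "y2"] - s[i, "y1"]
    den <- dx * ey - dy * ex
    if (abs(den) < 1e-12) next
    # solve x0 + t d = p1 + u e
    rx <- s[i, "x1"] - x0; ry <- s[i, "y1"] - y0
    t <- (rx * ey - ry * ex) / den
    u <- (rx * dy - ry * dx) / den
    if (t > 1e-9 && u >= -1e-9 && u <= 1 + 1e-9 && t < best$distance) {
      best <- list(wall = i, x = x0 + t * dx, y = y0 + t * dy, distance = t)
    }
  }
  best
}
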