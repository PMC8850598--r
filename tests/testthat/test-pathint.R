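maze <- arena_decagon()

# straight return path from a point toward a target, sampled at 30 Hz
straight_path <- function(from, to, arena = maze, n = 60) {
  s <- seq(0, 1, length.out = n)
  return_path(t = s * 2, x = from[1] + s * (to[1] - from[1]),
              y = from[2] + s * (to[2] - from[2]), arena = arena)
}

test_that("decagon geometry: walls, refuge, containment", {
  expect_identical(nrow(wall_segments(maze)), 10L)
  expect_equal(maze$circumradius, 31.9)
  expect_true(in_arena(maze, 0, 0))
  expect_false(in_arena(maze, 40, 0))
  # wall lengths all equal the decagon side
  s <- wall_segments(maze)
  len <- sqrt((s[, 3] - s[, 1])^2 + (s[, 4] - s[, 2])^2)
  expect_equal(len, rep(2 * 31.9 * sin(pi / 10), 10), tolerance = 1e-9)
  ref <- refuge_center(maze)
  expect_equal(unname(nearest_wall(maze, ref[1], ref[2])$wall),
               maze$refuge_wall)
})

test_that("first wall encounter picks the wall actually reached", {
  ref <- refuge_center(maze)
  p <- straight_path(c(0, 0), ref)
  expect_identical(first_wall_encounter(p)$wall, maze$refuge_wall)
  # path aimed at the wall adjacent to the refuge lands there instead
  adj <- wall_centers(maze)[maze$refuge_wall %% 10 + 1, ]
  p2 <- straight_path(c(0, 0), adj)
  expect_identical(first_wall_encounter(p2)$wall,
                   as.integer(maze$refuge_wall %% 10 + 1))
  # a path that stays in the middle is incomplete
  p3 <- return_path(t = 1:3, x = c(0, 1, 2), y = c(0, 1, 0), arena = maze)
  expect_true(is.na(first_wall_encounter(p3)$wall))
})

test_that("wall-hit distribution of random rays matches the ray-casting oracle", {
  set.seed(95)
  n <- 4000
  hits <- integer(n)
  for (k in 1:n) {
    repeat {
      px <- runif(1, -31.9, 31.9); py <- runif(1, -31.9, 31.9)
      if (in_arena(maze, px, py, margin = 3)) break
    }
    hits[k] <- ray_wall_intersection(maze, px, py, runif(1, 0, 360))$wall
  }
  # symmetry oracle: uniform headings from symmetrically drawn points
  # hit each of the ten walls with equal probability
  freq <- tabulate(hits, 10) / n
  expect_true(all(abs(freq - 0.1) < 4 * sqrt(0.1 * 0.9 / n) + 0.01))
})

test_that("metric closed forms: angles, normalized distance, thigmotaxis", {
  ref <- refuge_center(maze)
  p <- straight_path(c(0, 0), ref)
  expect_equal(initial_wall_angle(p), 0, tolerance = 1e-6)
  expect_equal(as.numeric(initial_heading_angle(p)), 0, tolerance = 1e-6)
  expect_equal(normalized_distance(p), 100, tolerance = 1e-6)
  # pellet at center aimed diametrically away from the refuge: 180 deg
  away <- -ref / sqrt(sum(ref^2)) * 31
  paway <- straight_path(c(0, 0), away)
  expect_equal(initial_wall_angle(paway), 180, tolerance = 1)
  # 3-4-5 triangle detour: two legs over the hypotenuse = 140%
  a <- c(0, 0)
  b <- ref * (1 - 5 / sqrt(sum(ref^2)))          # 5 cm short of refuge
  leg <- ref - b
  perp <- c(-leg[2], leg[1]) / sqrt(sum(leg^2))
  corner <- b + perp * 4                         # 3-4-5 with the last 5 cm
  pz <- b + leg * 0                              # start of the triangle
  path_x <- c(seq(a[1], pz[1], length.out = 30),
              seq(pz[1], corner[1], length.out = 30)[-1],
              seq(corner[1], ref[1], length.out = 30)[-1])
  path_y <- c(seq(a[2], pz[2], length.out = 30),
              seq(pz[2], corner[2], length.out = 30)[-1],
              seq(corner[2], ref[2], length.out = 30)[-1])
  ptri <- return_path(seq_along(path_x) / 30, path_x, path_y, maze)
  d0 <- sqrt(sum(ref^2))
  expect_equal(normalized_distance(ptri),
               100 * (d0 - 5 + 4 + 5) / d0, tolerance = 0.1)
  # heading over the first 10 cm is still toward the refuge
  expect_lt(as.numeric(initial_heading_angle(ptri)), 5)
  # perpendicular initial segment gives 90 degrees
  perp_end <- c(0, 0) + c(-ref[2], ref[1]) / sqrt(sum(ref^2)) * 15
  pperp <- straight_path(c(0, 0), perp_end)
  expect_equal(as.numeric(initial_heading_angle(pperp)), 90,
               tolerance = 1e-6)
  # thigmotaxis: wall-hugging path ~1; center-crossing chord computable
  th <- seq(0, pi, length.out = 100)
  hug <- return_path(th, 30.2 * cos(th), 30.2 * sin(th), maze)
  expect_equal(thigmotaxis(hug), 1)
  chord <- straight_path(c(-25, 0), c(25, 0), n = 500)
  band <- 0.15 * 31.9
  # analytic: samples within `band` of the left/right walls
  d <- nearest_wall(maze, chord$x, chord$y)$distance
  expect_equal(thigmotaxis(chord), mean(d <= band))
  expect_lt(thigmotaxis(chord), 0.35)
})

test_that("homing simulator: noiseless perfection and noise monotonicity", {
  tr0 <- simulate_homing_trials(maze, n_trials = 40, heading_noise_sd = 0,
                                seed = 96)
  m0 <- do.call(rbind, lapply(tr0, path_metrics))
  expect_equal(refuge_probability(tr0), 1)
  expect_true(all(m0$initial_wall_angle < 1e-6))
  expect_true(all(m0$initial_heading_angle < 1e-6))
  expect_true(all(abs(m0$normalized_distance - 100) < 0.1))
  # refuge-hit probability strictly decreases with heading noise
  p <- vapply(c(0, 20, 60), function(sd_) {
    refuge_probability(simulate_homing_trials(maze, 300,
                                              heading_noise_sd = sd_,
                                              seed = 97))
  }, numeric(1))
  expect_true(all(diff(p) < 0))
  # uniform headings: refuge probability near 1/10
  tru <- simulate_homing_trials(maze, 600, heading_noise_sd = 180,
                                seed = 98)
  expect_lt(abs(refuge_probability(tru) - 0.1), 4 * sqrt(0.1 * 0.9 / 600))
  # wall likelihood sums to one over walls plus the incomplete bucket
  expect_equal(sum(wall_likelihood(tru)), 1)
  # empty trial list errors
  expect_error(refuge_probability(list()),
               class = "gridcells_invalid_config")
})

test_that("all four metrics are monotone in heading noise; bias raises thigmotaxis", {
  grids <- c(0, 30, 90)
  med <- sapply(grids, function(sd_) {
    tr <- simulate_homing_trials(maze, 150, heading_noise_sd = sd_,
                                 seed = 99)
    m <- do.call(rbind, lapply(tr, path_metrics))
    c(wall = stats::median(m$initial_wall_angle),
      head = stats::median(m$initial_heading_angle),
      dist = stats::median(m$normalized_distance),
      thig = stats::median(m$thigmotaxis))
  })
  for (row in rownames(med)) {
    expect_true(all(diff(med[row, ]) > 0), label = row)
  }
  # thigmotaxis bias raises the wall fraction
  t_lo <- simulate_homing_trials(maze, 150, heading_noise_sd = 10,
                                 thigmotaxis_bias = 0, seed = 100)
  t_hi <- simulate_homing_trials(maze, 150, heading_noise_sd = 10,
                                 thigmotaxis_bias = 0.7, seed = 100)
  f <- function(tr) mean(vapply(tr, thigmotaxis, numeric(1)))
  expect_gt(f(t_hi), f(t_lo))
  # rigid rotation of arena + paths leaves the metrics unchanged
  tr <- simulate_homing_trials(maze, 10, heading_noise_sd = 30, seed = 101)
  rot <- 2 * pi * 3 / 10   # three-wall rotation is a decagon symmetry
  maze_rot <- arena_decagon(refuge_wall = ((maze$refuge_wall - 1 + 3) %% 10) + 1)
  m1 <- do.call(rbind, lapply(tr, path_metrics))
  m2 <- do.call(rbind, lapply(tr, function(p) {
    q <- return_path(p$t, cos(rot) * p$x - sin(rot) * p$y,
                     sin(rot) * p$x + cos(rot) * p$y, maze_rot)
    path_metrics(q)
  }))
  expect_equal(m1$initial_wall_angle, m2$initial_wall_angle,
               tolerance = 1e-6)
  expect_equal(m1$normalized_distance, m2$normalized_distance,
               tolerance = 1e-6)
  expect_equal(m1$thigmotaxis, m2$thigmotaxis, tolerance = 1e-6)
})
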