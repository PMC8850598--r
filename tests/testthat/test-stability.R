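# build a toroidal synthetic map pair: the same periodic field translated
# by whole bins, fully visited, identical geometry
shifted_map_pair <- function(shift_bins = c(2, 0), n = 25) {
  gcell <- grid_cell(spacing = 30, peak_rate = 10, phase = c(0, 0))
  xs <- (seq_len(n) - 0.5) * 3
  M1 <- outer(xs, xs, function(x, y) grid_rate_at(gcell, x, y))
  M2 <- outer(xs, xs, function(x, y)
    grid_rate_at(gcell, x - shift_bins[1] * 3, y - shift_bins[2] * 3))
  list(analytic_map(M1), analytic_map(M2))
}

test_that("epoch partition: counts, conservation, and the length precondition", {
  traj <- fix_traj(1800, seed = 8)
  gcell <- grid_cell(spacing = 40, peak_rate = 12, seed = 3)
  sp <- poisson_spikes(gcell, traj, seed = 60)
  maps <- epoch_maps(traj, sp)
  expect_identical(length(maps), 10L)
  # partition conservation: epoch spike counts sum to the total
  expect_equal(sum(vapply(maps, function(m) sum(m$spikes), numeric(1))),
               length(sp$times))
  # a 29-minute session cannot host 10 x 3 min epochs
  short <- fix_traj(600, seed = 8)
  expect_error(epoch_maps(short, sp), "require",
               class = "gridcells_insufficient_data")
})

test_that("pairwise shift recovers constructed translations exactly", {
  pair <- shifted_map_pair(c(2, 0))
  ps <- pairwise_shift(pair[[1]], pair[[2]])
  expect_equal(ps$displacement, 6)
  expect_equal(abs(c(ps$dx, ps$dy)), c(6, 0))
  # identical maps: zero displacement
  ps0 <- pairwise_shift(pair[[1]], pair[[1]])
  expect_identical(ps0$displacement, 0)
  # antisymmetry: swapping maps reflects the shift through the origin
  psr <- pairwise_shift(pair[[2]], pair[[1]])
  expect_equal(c(psr$dx, psr$dy), -c(ps$dx, ps$dy))
  expect_equal(psr$displacement, ps$displacement)
  # displacement bounded by the lag window
  expect_lte(ps$displacement, sqrt(2) * 15)
})

test_that("central-patch rule beats the periodic side lobes", {
  # period-5-bin field: side lobes at 15 cm lag rival the center
  gcell <- grid_cell(spacing = 15, peak_rate = 10)
  xs <- (1:25 - 0.5) * 3
  M1 <- outer(xs, xs, function(x, y) grid_rate_at(gcell, x, y))
  M2 <- outer(xs, xs, function(x, y) grid_rate_at(gcell, x - 3, y))
  ps <- pairwise_shift(analytic_map(M1), analytic_map(M2))
  # exhaustive-search oracle restricted to the central patch: the true
  # 1-bin shift, not a 5-bin side lobe
  expect_equal(ps$displacement, 3)
  # patch rule on 50 random smooth map pairs agrees with an oracle that
  # flood-fills the qualifying region from the center-nearest seed
  patch_oracle <- function(W) {
    n <- nrow(W); ctr <- (n + 1) / 2
    qual <- is.finite(W) & W >= 0.5 * max(W, na.rm = TRUE)
    idx <- which(qual, arr.ind = TRUE)
    dd <- sqrt((idx[, 1] - ctr)^2 + (idx[, 2] - ctr)^2)
    aa <- ((atan2(idx[, 2] - ctr, idx[, 1] - ctr) * 180 / pi) %% 360)
    seed <- idx[order(dd, aa)[1], ]
    patch <- matrix(FALSE, n, n); patch[seed[1], seed[2]] <- TRUE
    repeat {
      grown <- patch
      for (i in 1:n) for (j in 1:n) {
        if (!patch[i, j]) next
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          a <- i + d[1]; b <- j + d[2]
          if (a >= 1 && a <= n && b >= 1 && b <= n && qual[a, b]) {
            grown[a, b] <- TRUE
          }
        }
      }
      if (identical(grown, patch)) break
      patch <- grown
    }
    Wp <- ifelse(patch, W, NA)
    pk <- which(Wp == max(Wp, na.rm = TRUE), arr.ind = TRUE)[1, ]
    sqrt(sum((pk - ctr)^2)) * 3
  }
  set.seed(61)
  for (k in 1:50) {
    A <- smooth_map(matrix(rnorm(625), 25, 25), matrix(TRUE, 25, 25), 1.5)
    B <- smooth_map(matrix(rnorm(625), 25, 25), matrix(TRUE, 25, 25), 1.5)
    ps_k <- pairwise_shift(analytic_map(A), analytic_map(B))
    expect_equal(ps_k$displacement, patch_oracle(ps_k$corr_window))
  }
})

test_that("pairwise rotation recovers constructed rotations", {
  M <- hex_matrix(25, spacing = 40, orientation = 5, phase = c(6, 3))
  m1 <- analytic_map(M)
  expect_equal(pairwise_rotation(m1, m1)$rotation, 0)
  m2 <- analytic_map(rotate_matrix(M, 12))
  expect_equal(pairwise_rotation(m1, m2)$rotation, 12)
})

test_that("displacement grows with lag under phase drift and stays near zero without", {
  traj <- fix_traj(1800, seed = 9)
  g0 <- grid_cell(spacing = 40, peak_rate = 15, drift_rate = 0,
                  duration = 1800)
  s0 <- poisson_spikes(g0, traj, seed = 62)
  ds0 <- displacement_summary(epoch_maps(traj, s0))
  expect_lt(ds0$mean_displacement, 3)
  # drifting twin (paired trajectory and spiking seed)
  g1 <- grid_cell(spacing = 40, peak_rate = 15, drift_rate = 10,
                  duration = 1800, seed = 63)
  s1 <- poisson_spikes(g1, traj, seed = 62)
  ds1 <- displacement_summary(epoch_maps(traj, s1))
  expect_gt(ds1$mean_displacement, ds0$mean_displacement)
  # by-lag displacement increases with lag under a phase random walk
  rho <- stats::cor(ds1$by_lag$lag, ds1$by_lag$mean_displacement,
                    method = "spearman")
  expect_gt(rho, 0)
  # matrices are symmetric with zero diagonal
  expect_equal(ds1$pair_shift, t(ds1$pair_shift))
  expect_true(all(diag(ds1$pair_shift) == 0))
})
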