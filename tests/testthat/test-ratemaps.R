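test_that("rate maps conserve spikes and recover homogeneous rates", {
  traj <- fix_traj(600, seed = 1)
  sp <- poisson_spikes(function(x, y, t, hd) rep(5, length(t)), traj,
                       seed = 20)
  m <- make_ratemap(traj, sp)
  # spike-count conservation before smoothing: exact integer identity
  expect_identical(round(sum(m$rate_unsmoothed * m$occupancy, na.rm = TRUE)),
                   as.numeric(length(sp$times)))
  expect_identical(sum(m$spikes), as.numeric(length(sp$times)))
  # homogeneous 5 Hz: every well-visited bin near 5 Hz after smoothing
  well <- m$occupancy > 0.5 & m$visited
  expect_lt(max(abs(m$rate[well] - 5)), 1.5)
  expect_lt(abs(mean(m$rate[well]) - 5), 0.25)
})

test_that("single spike in a single bin gives 1 Hz unsmoothed", {
  t <- seq(0, 1, by = 1 / 30)
  traj <- trajectory(t, rep(1.5, length(t)), rep(1.5, length(t)),
                     arena = arena_rect(9, 9))
  m <- make_ratemap(traj, spike_train(0.5), smooth_sd = 0)
  occupied <- which(m$occupancy > 0)
  expect_identical(length(occupied), 1L)
  expect_equal(m$occupancy[occupied], 1, tolerance = 0.05)
  expect_equal(m$rate_unsmoothed[occupied], 1, tolerance = 0.05)
  # empty spike train: all-zero map, not an error
  m0 <- make_ratemap(traj, spike_train(numeric(0)), smooth_sd = 0)
  expect_true(all(m0$rate_unsmoothed[m0$occupancy > 0] == 0))
  # empty trajectory is an error
  expect_error(make_ratemap(traj[0, ], spike_train(0.5)))
})

test_that("smoothing preserves mass for interior-supported rates", {
  # rate supported far from the mask edge: occupancy-renormalized
  # smoothing is exactly mass-preserving there
  M <- matrix(0, 41, 41)
  M[17:25, 17:25] <- matrix(runif(81), 9, 9)
  vis <- matrix(TRUE, 41, 41)
  sm <- smooth_map(M, vis, smooth_sd = 2)
  expect_equal(sum(sm), sum(M), tolerance = 1e-6)
})

test_that("spatial autocorrelogram matches the loop oracle and is symmetric", {
  traj <- fix_traj(600, seed = 2)
  gc <- grid_cell(spacing = 35, peak_rate = 12, seed = 5)
  sp <- poisson_spikes(gc, traj, seed = 21)
  m <- make_ratemap(traj, sp)
  ac <- spatial_autocorr(m)
  # center is exactly 1
  expect_equal(ac$corr[ac$center[1], ac$center[2]], 1, tolerance = 1e-9)
  # corr(tau) = corr(-tau)
  flip <- ac$corr[rev(seq_len(nrow(ac$corr))), rev(seq_len(ncol(ac$corr)))]
  expect_equal(ac$corr, flip)
  # FFT-based masked correlation equals the brute-force loop oracle
  Mm <- m$rate; Mm[!m$visited] <- NA
  oracle <- xcorr_oracle(Mm, Mm)
  expect_equal(unname(masked_crosscorr(Mm, Mm)$corr), unname(oracle),
               tolerance = 1e-8)
})

test_that("hexagonal autocorrelograms show six inner peaks at 60-degree gaps", {
  map <- analytic_map(hex_matrix(25, spacing = 40))
  ac <- spatial_autocorr(map)
  pk <- inner_peaks(ac)
  expect_identical(nrow(pk), 6L)
  gaps <- sort(diff(sort(pk[, "angle"])))
  expect_true(all(abs(gaps - 60) < 12))
  # six inner peak radii recover the spacing within 10%
  expect_true(all(abs(pk[, "radius"] * 3 - 40) / 40 < 0.10))
})

test_that("spatial information matches closed forms and the brute-force oracle", {
  # uniform map -> 0 bits/spike
  u <- analytic_map(matrix(4, 10, 10))
  expect_equal(spatial_information(u), 0)
  # all spikes in one of N equi-occupied bins -> log2(N)
  N <- 25
  m1 <- matrix(0, 5, 5); m1[3, 3] <- N   # mean rate 1
  expect_equal(spatial_information(analytic_map(m1)), log2(N))
  # random maps equal the brute-force summation oracle to 1e-10
  set.seed(31)
  for (k in 1:5) {
    R <- matrix(rexp(100), 10, 10)
    occ <- matrix(runif(100, 0.5, 2), 10, 10)
    map <- analytic_map(R)
    map$occupancy <- occ
    p <- occ / sum(occ)
    lam <- sum(p * R)
    oracle <- sum(ifelse(R > 0, p * (R / lam) * log2(R / lam), 0))
    expect_equal(spatial_information(map), oracle, tolerance = 1e-10)
  }
  # zero map is flagged undefined
  z <- analytic_map(matrix(0, 5, 5))
  expect_warning(si <- spatial_information(z))
  expect_true(is.na(si))
})

test_that("split-half reliability separates stable cells from remapping cells", {
  traj <- fix_traj(1200, seed = 1)
  pc <- place_cell(center = c(25, 50), sd = 8, peak_rate = 12)
  sp <- poisson_spikes(pc, traj, seed = 22)
  expect_gt(split_half_reliability(traj, sp), 0.9)
  # remapping at half-time: two independent fields -> near zero
  tmid <- 600
  rate_remap <- function(x, y, t, hd) {
    ifelse(t < tmid, place_rate_at(place_cell(c(20, 20), 7, 12), x, y),
           place_rate_at(place_cell(c(55, 60), 7, 12), x, y))
  }
  spr <- poisson_spikes(rate_remap, traj, seed = 23)
  expect_lt(abs(split_half_reliability(traj, spr)), 0.35)
})

test_that("field detection matches the analytic half-max disc area", {
  # Gaussian field of SD sigma thresholded at half max: disc of
  # area 2 ln 2 pi sigma^2
  sigma <- 9
  pc <- place_cell(center = c(37.5, 37.5), sd = sigma, peak_rate = 10,
                   base_rate = 0)
  xs <- seq(1.5, 73.5, 3)
  M <- outer(xs, xs, function(x, y) place_rate_at(pc, x, y))
  fs <- field_size(analytic_map(M), spacing = 40)
  expect_identical(nrow(fs$fields), 1L)
  analytic <- 2 * log(2) * pi * sigma^2
  expect_lt(abs(fs$fields$area_cm2 - analytic) / analytic, 0.15)
  expect_equal(fs$fields$centroid_x, 37.5, tolerance = 1.5)
  # doubling field size and spacing leaves the normalized size unchanged
  pc2 <- place_cell(center = c(37.5, 37.5), sd = 2 * sigma, peak_rate = 10,
                    base_rate = 0)
  xs2 <- seq(1.5, 148.5, 3)
  M2 <- outer(xs2, xs2, function(x, y) place_rate_at(pc2, x, y))
  fs2 <- field_size(analytic_map(M2), spacing = 80)
  expect_equal(fs2$normalized_field_size, fs$normalized_field_size,
               tolerance = 0.1)
})

test_that("grid drift inflates the normalized field size", {
  traj <- fix_traj(1200, seed = 6)
  base <- list(spacing = 40, peak_rate = 15, phase = c(5, 10))
  g0 <- grid_cell(spacing = 40, peak_rate = 15, phase = c(5, 10),
                  drift_rate = 0, duration = 1200)
  g1 <- grid_cell(spacing = 40, peak_rate = 15, phase = c(5, 10),
                  drift_rate = 15, duration = 1200, seed = 77)
  m0 <- make_ratemap(traj, poisson_spikes(g0, traj, seed = 24))
  m1 <- make_ratemap(traj, poisson_spikes(g1, traj, seed = 24))
  f0 <- field_size(m0, spacing = 40)
  f1 <- field_size(m1, spacing = 40)
  expect_gt(f1$normalized_field_size, f0$normalized_field_size)
})
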