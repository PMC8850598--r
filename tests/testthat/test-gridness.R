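# Literal-transcription reference scorer, independent of the package
# implementation: nearest-neighbor rotation of annulus pixels, cor() of
# paired values, gridness from the defining difference.
gridness_oracle <- function(ac, r_in, r_out) {
  C <- ac$corr
  ctr <- ac$center
  rc <- expand.grid(r = seq_len(nrow(C)), c = seq_len(ncol(C)))
  d <- sqrt((rc$r - ctr[1])^2 + (rc$c - ctr[2])^2)
  sel <- d > r_in & d <= r_out
  rr <- rc$r[sel]; cc <- rc$c[sel]
  base <- C[cbind(rr, cc)]
  rot_corr <- function(theta) {
    th <- theta * pi / 180
    sr <- round(ctr[1] + cos(th) * (rr - ctr[1]) + sin(th) * (cc - ctr[2]))
    sc <- round(ctr[2] - sin(th) * (rr - ctr[1]) + cos(th) * (cc - ctr[2]))
    ok <- sr >= 1 & sr <= nrow(C) & sc >= 1 & sc <= ncol(C)
    v <- rep(NA_real_, length(rr))
    v[ok] <- C[cbind(sr[ok], sc[ok])]
    use <- is.finite(base) & is.finite(v)
    stats::cor(base[use], v[use])
  }
  min(rot_corr(60), rot_corr(120)) -
    max(rot_corr(30), rot_corr(90), rot_corr(150))
}

test_that("six inner peaks are found on clean and stretched hexagonal fields", {
  ac <- spatial_autocorr(analytic_map(hex_matrix(25, spacing = 40)))
  pk <- inner_peaks(ac)
  expect_identical(nrow(pk), 6L)
  expect_lt(diff(range(pk[, "radius"])), 1)
  # affine-stretched hexagon: same six peaks at stretched positions
  gc <- grid_cell(spacing = 40, ellipticity = 1.3)
  xs <- seq(1.5, 73.5, 3)
  Ms <- outer(xs, xs, function(x, y) grid_rate_at(gc, x, y))
  acs <- spatial_autocorr(analytic_map(Ms))
  pks <- inner_peaks(acs)
  expect_identical(nrow(pks), 6L)
  # radii now span a ratio approaching the stretch factor
  expect_gt(max(pks[, "radius"]) / min(pks[, "radius"]), 1.15)
  # aperiodic map (one Gaussian bump): only a central peak, no six fields
  xs <- seq(1.5, 73.5, 3)
  bump <- outer(xs, xs, function(x, y)
    exp(-((x - 37.5)^2 + (y - 37.5)^2) / (2 * 15^2)))
  acb <- spatial_autocorr(analytic_map(bump))
  expect_error(inner_peaks(acb),
               class = "gridcells_insufficient_peaks")
})

test_that("ellipse correction equalizes peak radii and skips extreme stretches", {
  # circularly symmetric hexagon: compression factor ~1, scores agree
  ac0 <- spatial_autocorr(analytic_map(hex_matrix(25, spacing = 40)))
  g_corr <- gridness_score(ac0, correct_ellipse = TRUE)
  g_raw <- gridness_score(ac0, correct_ellipse = FALSE)
  expect_equal(g_corr$gridness, g_raw$gridness, tolerance = 0.05)
  # x1.3 stretch: corrected peak radii equal within 5%
  gc <- grid_cell(spacing = 40, ellipticity = 1.3)
  xs <- seq(1.5, 73.5, 3)
  acs <- spatial_autocorr(analytic_map(
    outer(xs, xs, function(x, y) grid_rate_at(gc, x, y))))
  corrected <- ellipse_correct(acs)
  expect_true(attr(corrected, "corrected"))
  pkc <- inner_peaks(corrected)
  expect_lt((max(pkc[, "radius"]) - min(pkc[, "radius"])) /
              mean(pkc[, "radius"]), 0.05)
  # x2.5 stretch (minor < major/2): passthrough, flagged uncorrected.
  # Peaks laid out analytically on a 2.5:1 ellipse about the center.
  ac0b <- spatial_autocorr(analytic_map(hex_matrix(25, spacing = 40)))
  th <- seq(0, 300, by = 60) * pi / 180
  pk25 <- cbind(row = ac0b$center[1] + 10 * 2.5 * cos(th),
                col = ac0b$center[2] + 10 * sin(th),
                radius = 10 * sqrt(2.5^2 * cos(th)^2 + sin(th)^2),
                angle = 0, value = 1)
  out2 <- ellipse_correct(ac0b, pk25)
  expect_false(attr(out2, "corrected"))
  expect_equal(out2$corr, ac0b$corr)
  expect_gt(attr(out2, "ellipse")$major / attr(out2, "ellipse")$minor, 2)
})

test_that("gridness agrees with the literal-transcription oracle", {
  ac <- spatial_autocorr(analytic_map(hex_matrix(25, spacing = 40)))
  gs <- gridness_score(ac, correct_ellipse = FALSE)
  oracle <- gridness_oracle(ac, gs$annulus["inner"] / 3,
                            gs$annulus["outer"] / 3)
  expect_equal(gs$gridness, oracle, tolerance = 0.05)
  expect_true(gs$gridness >= -2 && gs$gridness <= 2)
  expect_true(all(abs(gs$rotational_corr$corr) <= 1, na.rm = TRUE))
})

test_that("concentric-ring autocorrelograms score near zero", {
  # rotation-invariant input: 60- and 90-degree correlations coincide
  ii <- seq_len(49)
  r <- sqrt(outer((ii - 25)^2, (ii - 25)^2, "+"))
  ac <- structure(list(corr = cos(2 * pi * r / 13) * exp(-r / 30),
                       n_overlap = matrix(625, 49, 49), lag_size = 3,
                       center = c(25L, 25L)),
                  class = "spatial_autocorr")
  gs <- gridness_score(ac, correct_ellipse = FALSE)
  expect_lt(abs(gs$gridness), 0.05)
})

test_that("gridness is invariant under 60-degree rotation and mirroring", {
  M <- hex_matrix(25, spacing = 40, orientation = 7, phase = c(4, 9))
  g0 <- gridness_score(spatial_autocorr(analytic_map(M)))$gridness
  # +60 degrees is a lattice symmetry: the rotated field is identical
  M60 <- hex_matrix(25, spacing = 40, orientation = 67, phase = c(4, 9))
  g60 <- gridness_score(spatial_autocorr(analytic_map(M60)))$gridness
  expect_equal(g0, g60, tolerance = 0.02)
  # a non-symmetry rotation of the lattice changes the pixel sampling
  # but the statistic is rotation-invariant up to discretization
  M22 <- hex_matrix(25, spacing = 40, orientation = 22, phase = c(4, 9))
  g22 <- gridness_score(spatial_autocorr(analytic_map(M22)))$gridness
  expect_equal(g0, g22, tolerance = 0.1)
  # mirror image: exact within interpolation tolerance
  Mmir <- M[rev(seq_len(nrow(M))), ]
  gm <- gridness_score(spatial_autocorr(analytic_map(Mmir)))$gridness
  expect_equal(g0, gm, tolerance = 0.02)
})

test_that("synthetic drift-free grid cells exceed the 0.54 grid threshold", {
  traj <- fix_traj(1800, seed = 7)
  gc <- grid_cell(spacing = 40, peak_rate = 15, orientation = 12,
                  phase = c(8, 22))
  sp <- poisson_spikes(gc, traj, seed = 30)
  gs <- grid_score_for_cell(traj, sp)
  expect_gt(gs$gridness, 0.54)
})
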