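test_that("FFT cross-correlation equals the brute-force spatial oracle", {
  set.seed(11)
  for (d in list(c(8, 8, 8), c(16, 16, 16), c(8, 12, 16))) {
    f <- array(rnorm(prod(d)), d)
    g <- array(rnorm(prod(d)), d)
    cc <- cross_correlate_subsets(f, g)
    oracle <- brute_correlate(f, g)
    expect_lt(max(abs(cc$values - oracle)) / max(abs(oracle)), 1e-10)
  }
})

test_that("autocorrelation peaks at zero lag and circular shifts land on the shift theorem's lag", {
  set.seed(12)
  f <- array(rnorm(16^3), c(16, 16, 16))
  cc <- cross_correlate_subsets(f, f)
  idx <- arrayInd(which.max(cc$values), dim(cc$values))
  expect_equal(c(cc$lags[[1]][idx[1]], cc$lags[[2]][idx[2]],
                 cc$lags[[3]][idx[3]]), c(0, 0, 0))
  g <- circshift3(f, c(2, 1, 0))
  cc2 <- cross_correlate_subsets(f, g)
  idx2 <- arrayInd(which.max(cc2$values), dim(cc2$values))
  expect_equal(c(cc2$lags[[1]][idx2[1]], cc2$lags[[2]][idx2[2]],
                 cc2$lags[[3]][idx2[3]]), c(2, 1, 0))
})

test_that("constant subsets are flagged degenerate and report no peak", {
  f <- array(1, c(16, 16, 16))
  g <- array(rnorm(16^3), c(16, 16, 16))
  cc <- cross_correlate_subsets(f, g)
  expect_true(cc$degenerate)
  pk <- locate_peak_subvoxel(cc)
  expect_true(all(is.na(pk$lag)))
  expect_match(pk$flag, "degenerate")
})

test_that("the compiled correlation window agrees with the R path", {
  set.seed(13)
  f <- array(rnorm(32^3), c(32, 32, 32))
  g <- array(rnorm(32^3), c(32, 32, 32))
  cc <- cross_correlate_subsets(f, g)
  L <- 8L
  ctr <- 17L
  win <- (ctr - L):(ctr + L)
  w <- tfm3d:::.correlate_window_cpp(f, g, dim(f), L)
  expect_lt(max(abs(w - cc$values[win, win, win])) / max(abs(w)), 1e-12)
})

test_that("subvoxel peak fitting recovers an analytic quadratic maximum to 1e-6 voxels", {
  r <- -2:2
  H <- -diag(c(1, 2, 0.5))
  m0 <- c(0.30, -0.20, 0.10)
  grid <- as.matrix(expand.grid(r, r, r))
  vals <- apply(grid, 1, function(p) {
    d <- p - m0
    5 + 0.5 * t(d) %*% H %*% d
  })
  cv <- structure(list(values = array(vals, c(5, 5, 5)),
                       lags = list(r, r, r), degenerate = FALSE),
                  class = "correlation_volume")
  pk <- locate_peak_subvoxel(cv, fit_radius = 1)
  expect_lt(max(abs(pk$lag - m0)), 1e-6)
  expect_equal(pk$flag, "")

  # discrete delta at zero lag localizes to exactly zero
  delta <- array(0, c(5, 5, 5)); delta[3, 3, 3] <- 1
  cv0 <- structure(list(values = delta, lags = list(r, r, r),
                        degenerate = FALSE), class = "correlation_volume")
  expect_equal(locate_peak_subvoxel(cv0)$lag, c(0, 0, 0))
})

test_that("exact peak ties resolve to the lexicographically smallest lag and are flagged", {
  r <- -3:3
  v <- array(0, c(7, 7, 7))
  v[r == 1, r == 0, r == 0] <- 2
  v[r == -2, r == 0, r == 0] <- 2
  cv <- structure(list(values = v, lags = list(r, r, r), degenerate = FALSE),
                  class = "correlation_volume")
  pk <- locate_peak_subvoxel(cv)
  expect_equal(pk$integer_lag, c(-2, 0, 0))
  expect_match(pk$flag, "tie")
})

test_that("peaks on the lag-lattice boundary are flagged instead of fitted", {
  r <- -3:3
  v <- array(0, c(7, 7, 7))
  v[1, 4, 4] <- 1
  cv <- structure(list(values = v, lags = list(r, r, r), degenerate = FALSE),
                  class = "correlation_volume")
  pk <- locate_peak_subvoxel(cv)
  expect_match(pk$flag, "boundary")
  expect_equal(pk$lag, c(-3, 0, 0))
})

test_that("whole-volume periodic subsets recover integer translations at machine precision", {
  sc <- periodic_scene(c(64, 64, 64), seed = 6)
  ref <- render_volume(sc$pf, sc$im, seed = 1)
  def <- render_volume(
    apply_deformation(sc$pf, deformation_map("translation",
                                             t = c(3, -2, 1) * sc$d)),
    sc$im, seed = 1)
  cfg <- dvc_config(subset_size = 64, grid_spacing = 100)
  disp <- compute_displacement_field(ref, def, cfg)
  expect_equal(nrow(disp), 1L)
  expect_true(all(disp$valid))
  expect_lt(max(abs(c(disp$u1 / sc$d - 3, disp$u2 / sc$d + 2,
                      disp$u3 / sc$d - 1))), 0.02)
  # swap symmetry: correlating (def, ref) negates the displacement
  rev <- compute_displacement_field(def, ref, cfg)
  expect_lt(max(abs(c(rev$u1 + disp$u1, rev$u2 + disp$u2,
                      rev$u3 + disp$u3))) / sc$d, 0.02)
})

test_that("identical volumes give a zero displacement field with consistent magnitudes", {
  sc <- periodic_scene(c(48, 48, 48), seed = 7)
  ref <- render_volume(sc$pf, sc$im, seed = 1)
  disp <- compute_displacement_field(ref, ref,
                                     dvc_config(subset_size = 32,
                                                grid_spacing = 4))
  expect_true(all(disp$valid))
  expect_lt(max(disp$magnitude), 1e-10)
  ok <- disp$valid
  expect_equal(disp$magnitude[ok],
               sqrt(disp$u1[ok]^2 + disp$u2[ok]^2 + disp$u3[ok]^2))
})

test_that("windowed subsets track sub-voxel translations within the documented tolerance", {
  sc <- windowed_scene()
  def <- render_volume(
    apply_deformation(sc$pf, deformation_map("translation",
                                             t = c(0.40 * sc$d, 0, 0))),
    sc$im, seed = 1)
  cfg <- dvc_config(subset_size = 64, grid_spacing = 5.6)
  disp <- compute_displacement_field(sc$ref, def, cfg)
  ok <- disp$valid
  expect_gt(sum(ok), 50)
  expect_lt(abs(mean(disp$u1[ok]) / sc$d - 0.40), 0.1)
  expect_lt(abs(mean(disp$u2[ok]) / sc$d), 0.05)
  expect_lt(abs(mean(disp$u3[ok]) / sc$d), 0.05)
})

test_that("noiseless affine deformations are recovered below 0.1 voxel RMS", {
  d <- 0.35
  dims <- c(96, 96, 96)
  im <- imaging_model(voxel_size = rep(d, 3), dims = dims,
                      noise = list(kind = "none"), bit_depth = NULL)
  pf <- generate_particle_field(dims * d, 0.003, 0.25, seed = 14)
  A <- matrix(c(0.015, 0, 0.005,
                0, -0.01, 0,
                0.004, 0, 0.008), 3, 3, byrow = TRUE)
  map <- deformation_map("affine", A = A)
  ref <- render_volume(pf, im, seed = 1)
  def <- render_volume(apply_deformation(pf, map), im, seed = 1)
  disp <- compute_displacement_field(ref, def,
                                     dvc_config(subset_size = 64,
                                                grid_spacing = 5.6))
  ok <- disp$valid
  truth <- map$u(cbind(disp$x[ok], disp$y[ok], disp$z[ok]))
  err <- (cbind(disp$u1[ok], disp$u2[ok], disp$u3[ok]) - truth) / d
  expect_lt(sqrt(mean(err^2)), 0.1)
})

test_that("configuration contracts reject invalid geometry", {
  expect_error(dvc_config(subset_size = 15), class = "tfm3d_parameter_error")
  expect_error(dvc_config(subset_size = 10), class = "tfm3d_parameter_error")
  expect_error(dvc_config(grid_spacing = 0), class = "tfm3d_parameter_error")
  v1 <- volume_image(array(runif(16^3), c(16, 16, 16)), rep(0.35, 3))
  v2 <- volume_image(array(runif(8^3), c(8, 8, 8)), rep(0.35, 3))
  expect_error(compute_displacement_field(v1, v2, dvc_config()),
               class = "tfm3d_parameter_error")
  expect_error(compute_displacement_field(v1, v1, dvc_config(subset_size = 32)),
               class = "tfm3d_parameter_error")
})
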