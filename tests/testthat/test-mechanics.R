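test_that("gradient estimator is exact on constant and affine displacement fields", {
  const <- lattice_disp(function(x) cbind(1.5, -0.3, 0.2))
  gc_ <- estimate_displacement_gradient(const)
  expect_lt(max(abs(as.matrix(gc_[, paste0("g", c(11, 12, 13, 21, 22, 23,
                                                  31, 32, 33))]))), 1e-10)
  expect_lt(max(gc_$residual), 1e-10)

  A <- matrix(c(0.01, -0.004, 0.002,
                0.003, 0.008, -0.006,
                0.005, 0.001, -0.009), 3, 3, byrow = TRUE)
  aff <- lattice_disp(function(x) x %*% t(A))
  ga <- estimate_displacement_gradient(aff)
  for (i in 1:3) for (j in 1:3) {
    expect_lt(max(abs(ga[[paste0("g", i, j)]] - A[i, j])), 1e-10)
  }
  expect_lt(max(ga$residual), 1e-10)
  # boundary points are fitted one-sided, so every point is valid here
  expect_true(all(ga$valid))
})

test_that("least-squares gradients beat central differences under displacement noise", {
  A <- matrix(c(0.01, 0, 0.004,
                0, -0.008, 0,
                0.002, 0, 0.006), 3, 3, byrow = TRUE)
  n <- 5; h <- 2
  base <- lattice_disp(function(x) x %*% t(A), n = n, h = h)
  # central-difference oracle at the centre point of the lattice
  ctr <- c(3, 3, 3)
  lin <- function(i, j, k) (k - 1) * n^2 + (j - 1) * n + i
  set.seed(99)
  reps <- 200
  err_ls <- err_cd <- matrix(NA_real_, reps, 9)
  for (r in seq_len(reps)) {
    noisy <- base
    noise <- matrix(rnorm(3 * nrow(base), sd = 0.05), ncol = 3)
    noisy$u1 <- base$u1 + noise[, 1]
    noisy$u2 <- base$u2 + noise[, 2]
    noisy$u3 <- base$u3 + noise[, 3]
    g <- estimate_displacement_gradient(noisy)
    q <- which(g$x == base$x[lin(3, 3, 3)] & g$y == base$y[lin(3, 3, 3)] &
                 g$z == base$z[lin(3, 3, 3)])[1]
    est <- matrix(as.numeric(g[q, paste0("g", c(11, 12, 13, 21, 22, 23,
                                                31, 32, 33))]), 3, 3,
                  byrow = TRUE)
    cd <- matrix(NA_real_, 3, 3)
    for (ax in 1:3) {
      up <- ctr; up[ax] <- up[ax] + 1
      dn <- ctr; dn[ax] <- dn[ax] - 1
      iu <- lin(up[1], up[2], up[3]); id <- lin(dn[1], dn[2], dn[3])
      cd[, ax] <- c(noisy$u1[iu] - noisy$u1[id],
                    noisy$u2[iu] - noisy$u2[id],
                    noisy$u3[iu] - noisy$u3[id]) / (2 * h)
    }
    err_ls[r, ] <- as.vector(est - A)
    err_cd[r, ] <- as.vector(cd - A)
  }
  expect_lt(sqrt(mean(err_ls^2)), sqrt(mean(err_cd^2)))
})

test_that("rank-deficient neighborhoods are masked with insufficient support", {
  # a single plane of points cannot support a 3D linear fit
  g <- expand.grid(x = c(0, 2, 4), y = c(0, 2, 4), z = 0)
  disp <- tibble::tibble(x = g$x, y = g$y, z = g$z,
                         u1 = 0.1, u2 = 0, u3 = 0, valid = TRUE)
  gr <- estimate_displacement_gradient(disp)
  expect_false(any(gr$valid))
})

test_that("strain construction symmetrizes the gradient and flags the linear range", {
  # pure rotation: antisymmetric gradient, zero strain
  W <- matrix(c(0, 0.01, 0, -0.01, 0, 0, 0, 0, 0), 3, 3, byrow = TRUE)
  rot <- lattice_disp(function(x) x %*% t(W))
  eps <- strain_from_gradient(estimate_displacement_gradient(rot))
  expect_lt(max(abs(as.matrix(eps[, c("e11", "e22", "e33",
                                      "e12", "e13", "e23")]))), 1e-12)

  # simple shear gamma = 0.01: e13 = e31 = 0.005, everything else zero
  sh <- lattice_disp(function(x) cbind(0.01 * x[, 3], 0, 0))
  es <- strain_from_gradient(estimate_displacement_gradient(sh))
  expect_equal(unique(round(es$e13, 12)), 0.005)
  expect_lt(max(abs(as.matrix(es[, c("e11", "e22", "e33", "e12", "e23")]))),
            1e-12)
  expect_true(all(es$linear_range))

  # symmetrization oracle on a random gradient via an affine field
  set.seed(5)
  G <- matrix(rnorm(9, sd = 0.01), 3, 3)
  af <- lattice_disp(function(x) x %*% t(G))
  ea <- strain_from_gradient(estimate_displacement_gradient(af))
  E_oracle <- (G + t(G)) / 2
  expect_lt(max(abs(ea$e12 - E_oracle[1, 2])), 1e-10)
  expect_lt(max(abs(ea$e13 - E_oracle[1, 3])), 1e-10)
  expect_lt(max(abs(ea$e23 - E_oracle[2, 3])), 1e-10)

  # beyond 5% strain the linear-range flag drops
  big <- lattice_disp(function(x) cbind(0.2 * x[, 3], 0, 0))
  eb <- strain_from_gradient(estimate_displacement_gradient(big))
  expect_false(any(eb$linear_range))
})

test_that("the incompressible law scales strain by twice the shear modulus", {
  mat <- material(E = 9640, nu = 0.5)
  expect_equal(mat$mu, 9640 / 3)
  sh <- lattice_disp(function(x) cbind(0.01 * x[, 3], 0, 0))
  eps <- strain_from_gradient(estimate_displacement_gradient(sh))
  sig <- stress_from_strain(eps, mat)
  expect_equal(unique(round(sig$s13, 8)), round(2 * (9640 / 3) * 0.005, 8))
  expect_lt(abs(unique(round(sig$s13, 6))[1] - 32.13), 0.01)

  # zero strain maps to zero stress
  z <- strain_from_gradient(estimate_displacement_gradient(
    lattice_disp(function(x) cbind(0, 0, 0))))
  expect_lt(max(abs(as.matrix(stress_from_strain(z, mat)[
    , c("s11", "s22", "s33", "s12", "s13", "s23")]))), 1e-12)

  # traceless strain stays traceless and proportional with factor 2 mu
  G <- matrix(c(0.01, 0.003, 0, 0.003, -0.004, 0.002, 0, 0.002, -0.006),
              3, 3, byrow = TRUE)
  ea <- strain_from_gradient(estimate_displacement_gradient(
    lattice_disp(function(x) x %*% t(G))))
  sa <- stress_from_strain(ea, mat)
  expect_lt(max(abs(sa$s11 + sa$s22 + sa$s33)), 1e-9)
  expect_equal(sa$s12, 2 * mat$mu * ea$e12, tolerance = 1e-12)

  # compressible Lame form adds the volumetric term for nu < 0.5
  mat2 <- material(E = 9640, nu = 0.45)
  lam <- 9640 * 0.45 / ((1.45) * (0.1))
  ec <- strain_from_gradient(estimate_displacement_gradient(
    lattice_disp(function(x) cbind(0.01 * x[, 1], 0, 0))))
  sc_ <- stress_from_strain(ec, mat2, form = "compressible")
  expect_equal(unique(round(sc_$s22, 8)),
               round(lam * 0.01, 8))
  expect_error(stress_from_strain(ec, material(9640, 0.5),
                                  form = "compressible"),
               class = "tfm3d_parameter_error")
})

test_that("Cauchy tractions match the componentwise oracle for random stresses and normals", {
  set.seed(21)
  S <- matrix(rnorm(6) * 10, ncol = 6)
  stress <- analytic_stress(function(x) matrix(S, nrow(x), 6, byrow = TRUE),
                            n = 3)
  for (r in 1:5) {
    n <- rnorm(3); n <- n / sqrt(sum(n^2))
    tr <- traction_on_plane(stress, n)
    Smat <- matrix(c(S[1], S[4], S[5],
                     S[4], S[2], S[6],
                     S[5], S[6], S[3]), 3, 3)
    T_oracle <- as.numeric(Smat %*% n)
    expect_equal(unique(round(tr$t1, 10)), round(T_oracle[1], 10))
    expect_equal(unique(round(tr$t2, 10)), round(T_oracle[2], 10))
    expect_equal(unique(round(tr$t3, 10)), round(T_oracle[3], 10))
    expect_equal(tr$magnitude, sqrt(tr$t1^2 + tr$t2^2 + tr$t3^2))
  }
  # hydrostatic stress pushes purely along the normal
  hyd <- analytic_stress(function(x) cbind(7, 7, 7, 0, 0, 0), n = 3)
  th <- traction_on_plane(hyd, c(0, 0, 1))
  expect_equal(unique(th$t1), 0)
  expect_equal(unique(th$t3), 7)
  # magnitude arithmetic
  expect_equal(sqrt(3^2 + 4^2), 5)
  one <- analytic_stress(function(x) cbind(0, 0, 0, 0, 3, 4), n = 3)
  t1 <- traction_on_plane(one, c(0, 0, 1))
  expect_equal(unique(t1$magnitude), 5)
})

test_that("plane selection slices the lattice and rejects out-of-range planes", {
  stress <- analytic_stress(function(x) cbind(x[, 3], 0, 0, 0, 0, 0), n = 4)
  top <- traction_on_plane(stress, c(0, 0, 1), plane = list(axis = 3, index = 4))
  expect_equal(unique(top$z), max(stress$z))
  expect_equal(nrow(top), 16L)
  near <- traction_on_plane(stress, c(0, 0, 1),
                            plane = list(axis = 3, value = 3.9))
  expect_equal(unique(near$z), 4)
  expect_error(traction_on_plane(stress, c(0, 0, 1),
                                 plane = list(axis = 3, index = 9)),
               class = "tfm3d_bounds_error")
  expect_error(traction_on_plane(stress, c(0, 0, 1),
                                 plane = list(axis = 3, value = 99)),
               class = "tfm3d_bounds_error")

  # surface map wrapper: uniform s13 gives T = (tau, 0, 0) on the top plane
  uni <- analytic_stress(function(x) cbind(0, 0, 0, 0, 11, 0), n = 4)
  sm <- surface_traction_map(uni)
  expect_equal(unique(sm$z), max(uni$z))
  expect_equal(unique(sm$t1), 11)
  expect_equal(unique(sm$t3), 0)
})

test_that("the displacement-to-traction map is linear", {
  sh <- lattice_disp(function(x) cbind(0.008 * x[, 3], 0, 0))
  dbl <- sh
  dbl$u1 <- 2 * sh$u1
  mat <- material(9640, 0.5)
  tr1 <- surface_traction_map(stress_from_strain(strain_from_gradient(
    estimate_displacement_gradient(sh)), mat))
  tr2 <- surface_traction_map(stress_from_strain(strain_from_gradient(
    estimate_displacement_gradient(dbl)), mat))
  expect_equal(tr2$t1, 2 * tr1$t1, tolerance = 1e-9)
  expect_equal(tr2$t3, 2 * tr1$t3, tolerance = 1e-9)
})

test_that("rotating the scene 90 degrees about the depth axis permutes traction components", {
  # u1 = a * x3 rotated by 90 deg about x3 becomes u2 = a * x3
  a <- 0.01
  mat <- material(9640, 0.5)
  t_orig <- surface_traction_map(stress_from_strain(strain_from_gradient(
    estimate_displacement_gradient(
      lattice_disp(function(x) cbind(a * x[, 3], 0, 0)))), mat))
  t_rot <- surface_traction_map(stress_from_strain(strain_from_gradient(
    estimate_displacement_gradient(
      lattice_disp(function(x) cbind(0, a * x[, 3], 0)))), mat))
  expect_equal(t_rot$t2, t_orig$t1, tolerance = 1e-10)
  expect_equal(t_rot$t1, t_orig$t2, tolerance = 1e-10)
})

test_that("material invariants hold", {
  expect_error(material(-1, 0.5), class = "tfm3d_parameter_error")
  expect_error(material(9640, 0.6), class = "tfm3d_parameter_error")
  m <- material(9640, 0.45)
  expect_equal(m$mu, 9640 / (2 * 1.45))
})
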