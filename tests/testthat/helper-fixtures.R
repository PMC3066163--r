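# Shared fixtures, built lazily and cached for the session so expensive
# renders happen once.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(fixture_cache[[key]])) fixture_cache[[key]] <- builder()
  fixture_cache[[key]]
}

# Circular shift of a 3D array by integer voxels (positive = content moves
# toward higher indices), the oracle counterpart of a periodic translation.
circshift3 <- function(a, s) {
  d <- dim(a)
  idx <- lapply(1:3, function(ax) ((seq_len(d[ax]) - 1 - s[ax]) %% d[ax]) + 1)
  a[idx[[1]], idx[[2]], idx[[3]]]
}

# Brute-force spatial-domain circular cross-correlation (mean-subtracted),
# the independent oracle for the FFT path.
brute_correlate <- function(f, g) {
  fc <- f - mean(f)
  gc <- g - mean(g)
  d <- dim(f)
  out <- array(0, d)
  l1 <- lag_seq(d[1]); l2 <- lag_seq(d[2]); l3 <- lag_seq(d[3])
  for (a in seq_along(l1)) for (b in seq_along(l2)) for (cc in seq_along(l3)) {
    sh <- gc[((seq_len(d[1]) - 1 + l1[a]) %% d[1]) + 1,
             ((seq_len(d[2]) - 1 + l2[b]) %% d[2]) + 1,
             ((seq_len(d[3]) - 1 + l3[cc]) %% d[3]) + 1]
    out[a, b, cc] <- sum(fc * sh)
  }
  out
}
lag_seq <- function(n) seq.int(-floor(n / 2), length.out = n)

# A clean periodic scene whose whole volume is one DVC subset: circular
# correlation is exact there, giving machine-precision shift oracles.
periodic_scene <- function(dims = c(64, 64, 64), seed = 6, d = 0.35) {
  im <- imaging_model(voxel_size = rep(d, 3), dims = dims,
                      noise = list(kind = "none"), bit_depth = NULL,
                      periodic = TRUE)
  pf <- generate_particle_field(dims * d, 0.003, 0.25, seed = seed)
  list(pf = pf, im = im, d = d, dims = dims)
}

# Standard test-scale scene for realistic (windowed-subset) DVC checks.
windowed_scene <- function() {
  cached("windowed_scene", function() {
    d <- 0.35
    dims <- c(128, 128, 128)
    im <- imaging_model(voxel_size = rep(d, 3), dims = dims,
                        noise = list(kind = "none"), bit_depth = NULL,
                        periodic = TRUE)
    pf <- generate_particle_field(dims * d, 0.003, 0.25, seed = 5)
    list(pf = pf, im = im, d = d, dims = dims,
         ref = render_volume(pf, im, seed = 1))
  })
}

# A periodic scene whose bead pattern repeats with the DVC subset period:
# every subset window is itself periodic, so circular correlation (and hence
# rigid-shift recovery) is exact while the displacement grid still has many
# points.
tiled_periodic_scene <- function(cell = c(32, 32, 32), reps = 2, seed = 23,
                                 d = 0.35) {
  base <- generate_particle_field(cell * d, 0.003, 0.25, seed = seed)
  offs <- expand.grid(ox = seq_len(reps) - 1, oy = seq_len(reps) - 1,
                      oz = seq_len(reps) - 1)
  pos <- do.call(rbind, lapply(seq_len(nrow(offs)), function(r) {
    cbind(base$x + offs$ox[r] * cell[1] * d,
          base$y + offs$oy[r] * cell[2] * d,
          base$z + offs$oz[r] * cell[3] * d)
  }))
  dims <- cell * reps
  pf <- particle_field(pos, radius = 0.25, domain = dims * d, seed = seed)
  im <- imaging_model(voxel_size = rep(d, 3), dims = dims,
                      noise = list(kind = "none"), bit_depth = NULL,
                      periodic = TRUE)
  list(pf = pf, im = im, d = d, dims = dims, cell = cell)
}

# Regular synthetic displacement lattice for mechanics tests (no DVC).
lattice_disp <- function(u_fun, n = 6, h = 2) {
  g <- expand.grid(x = seq(0, by = h, length.out = n),
                   y = seq(0, by = h, length.out = n),
                   z = seq(0, by = h, length.out = n))
  u <- u_fun(as.matrix(g))
  tibble::tibble(x = g$x, y = g$y, z = g$z,
                 u1 = u[, 1], u2 = u[, 2], u3 = u[, 3], valid = TRUE)
}

# Analytic stress lattice (tensor_field) from componentwise functions of
# position; used by balance and traction tests.
analytic_stress <- function(fun, n = 6, h = 2) {
  g <- expand.grid(x = seq(0, by = h, length.out = n),
                   y = seq(0, by = h, length.out = n),
                   z = seq(0, by = h, length.out = n))
  s <- fun(as.matrix(g))   # n x 6 matrix: s11 s22 s33 s12 s13 s23
  out <- tibble::tibble(x = g$x, y = g$y, z = g$z,
                        s11 = s[, 1], s22 = s[, 2], s33 = s[, 3],
                        s12 = s[, 4], s13 = s[, 5], s23 = s[, 6],
                        eps_trace = 0, valid = TRUE)
  structure(out, class = c("tensor_field", class(tibble::tibble())),
            kind = "stress", units = "Pa")
}
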