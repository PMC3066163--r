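# Synthetic scene generation: random bead fields in a hydrogel-like box,
# analytic deformation maps standing in for cell-induced displacement, and a
# confocal-style renderer. Every downstream stage (DVC, strain, traction) is
# validated against the analytic ground truth these scenes carry.

#' Generate a random fluorescent particle field
#'
#' Places `N = round(volume_fraction * V / ((4/3) pi radius^3))` particle
#' centres uniformly at random in an axis-aligned box, emulating the
#' fluorescent microspheres dispersed in a polyacrylamide substrate
#' (0.5 um diameter beads at a nominal 0.3% volume fraction). No overlap
#' constraint is applied; at dilute fractions overlaps are rare and the
#' renderer sums intensities.
#'
#' @param domain Box extents `c(Lx, Ly, Lz)` in micrometers (lower corner at
#'   the origin), or a 2x3 matrix of lower/upper corners.
#' @param volume_fraction Target particle volume fraction (0, 0.05).
#' @param radius Particle radius in micrometers (default 0.25, i.e. 0.5 um
#'   diameter beads).
#' @param seed Integer seed; the same seed reproduces the same field.
#' @return A `particle_field` tibble with columns x, y, z (micrometers) and
#'   attributes `radius`, `domain`, `seed`, `volume_fraction`.
#' @export
generate_particle_field <- function(domain, volume_fraction = 0.003,
                                    radius = 0.25, seed = 1L) {
  dom <- as_domain(domain)
  ext <- dom[2, ] - dom[1, ]
  if (any(ext <= 0)) {
    abort("domain is degenerate.", class = "tfm3d_parameter_error")
  }
  if (!is.numeric(volume_fraction) || volume_fraction <= 0 ||
      volume_fraction >= 0.05) {
    abort("`volume_fraction` must lie in (0, 0.05).",
          class = "tfm3d_parameter_error")
  }
  if (radius <= 0) abort("`radius` must be positive.",
                         class = "tfm3d_parameter_error")
  vol <- prod(ext)
  n <- round(volume_fraction * vol / ((4 / 3) * pi * radius^3))
  # sanity bounds: spheres must stay well below dense random packing, and
  # the count must be realizable in memory
  if (n * (4 / 3) * pi * radius^3 > 0.32 * vol || n > 5e7) {
    abort(sprintf("requested particle count (%g) exceeds the packing sanity bound.",
                  n), class = "tfm3d_parameter_error")
  }
  pos <- with_seed(seed, {
    matrix(runif(3 * n), ncol = 3)
  })
  pos <- sweep(sweep(pos, 2, ext, `*`), 2, dom[1, ], `+`)
  out <- tibble(x = pos[, 1], y = pos[, 2], z = pos[, 3])
  new_particle_field(out, radius = radius, domain = dom, seed = seed,
                     volume_fraction = volume_fraction)
}

#' Construct a particle field from explicit positions
#'
#' Low-level constructor used when bead positions come from somewhere other
#' than the random generator (tiled fixtures, imported localizations).
#'
#' @param positions Data frame or matrix with columns/cols x, y, z
#'   (micrometers).
#' @param radius Particle radius, micrometers.
#' @param domain Box extents `c(Lx, Ly, Lz)` or a 2x3 corner matrix.
#' @param seed Provenance seed recorded in metadata.
#' @return A `particle_field` tibble.
#' @export
particle_field <- function(positions, radius = 0.25, domain, seed = NA_integer_) {
  pos <- as.matrix(as.data.frame(positions)[, 1:3])
  new_particle_field(tibble(x = pos[, 1], y = pos[, 2], z = pos[, 3]),
                     radius = radius, domain = as_domain(domain),
                     seed = seed, volume_fraction = NA_real_)
}

as_domain <- function(domain) {
  if (is.matrix(domain)) {
    stopifnot(identical(dim(domain), c(2L, 3L)))
    return(domain)
  }
  stopifnot(is.numeric(domain), length(domain) == 3L)
  rbind(c(0, 0, 0), as.numeric(domain))
}

new_particle_field <- function(tbl, radius, domain, seed, volume_fraction,
                               map = NULL) {
  structure(tbl,
            class = c("particle_field", class(tibble())),
            radius = radius, domain = domain, seed = seed,
            volume_fraction = volume_fraction, map = map)
}

#' Analytic deformation maps
#'
#' A deformation map supplies the displacement `u(x)` and its gradient
#' `grad u(x)` in closed form, providing exact ground truth for the DVC and
#' strain stages. Available kinds:
#' \describe{
#'   \item{identity}{`u = 0`.}
#'   \item{translation}{`u = t`; parameter `t`, micrometers.}
#'   \item{affine}{`u = A x + t`; `A` is the (constant) displacement
#'     gradient, `t` an optional offset.}
#'   \item{simple_shear}{`u1 = gamma * x3`; parameter `gamma`.}
#'   \item{gaussian_indentation}{`u3 = -amplitude * exp(-|x - center|^2 /
#'     (2 width^2))`, a smooth localized push along the depth axis.}
#'   \item{composite}{sum of the displacements (and gradients) of a list of
#'     maps.}
#' }
#'
#' @param kind Map kind, see Details.
#' @param t Translation vector (micrometers).
#' @param A 3x3 displacement gradient matrix.
#' @param gamma Engineering shear applied as `u1 = gamma * x3`.
#' @param amplitude,width,center Gaussian indentation parameters
#'   (micrometers).
#' @param maps List of maps for `kind = "composite"`.
#' @return A `deformation_map` with functions `u(x)` and `grad(x)`; `x` is an
#'   n x 3 matrix of positions, `u` returns n x 3 displacements, `grad`
#'   returns an n x 3 x 3 array with `[p, i, j] = d u_i / d x_j`.
#' @export
deformation_map <- function(kind = c("identity", "translation", "affine",
                                     "simple_shear", "gaussian_indentation",
                                     "composite"),
                            t = c(0, 0, 0), A = NULL, gamma = 0,
                            amplitude = 1, width = 10, center = c(0, 0, 0),
                            maps = list()) {
  kind <- match.arg(kind)
  zero_grad <- function(n) array(0, c(n, 3, 3))
  obj <- switch(kind,
    identity = list(
      u = function(x) matrix(0, nrow(x), 3),
      grad = function(x) zero_grad(nrow(x))),
    translation = list(
      u = function(x) matrix(t, nrow(x), 3, byrow = TRUE),
      grad = function(x) zero_grad(nrow(x))),
    affine = {
      stopifnot(is.matrix(A), identical(dim(A), c(3L, 3L)))
      list(
        u = function(x) sweep(x %*% t(A), 2, t, `+`),
        grad = function(x) {
          g <- zero_grad(nrow(x))
          for (i in 1:3) for (j in 1:3) g[, i, j] <- A[i, j]
          g
        })
    },
    simple_shear = list(
      u = function(x) cbind(gamma * x[, 3], 0, 0),
      grad = function(x) {
        g <- zero_grad(nrow(x))
        g[, 1, 3] <- gamma
        g
      }),
    gaussian_indentation = list(
      u = function(x) {
        d2 <- rowSums(sweep(x, 2, center)^2)
        cbind(0, 0, -amplitude * exp(-d2 / (2 * width^2)))
      },
      grad = function(x) {
        dc <- sweep(x, 2, center)
        u3 <- -amplitude * exp(-rowSums(dc^2) / (2 * width^2))
        g <- zero_grad(nrow(x))
        for (j in 1:3) g[, 3, j] <- u3 * (-dc[, j] / width^2)
        g
      }),
    composite = {
      stopifnot(length(maps) >= 1)
      list(
        u = function(x) Reduce(`+`, lapply(maps, function(m) m$u(x))),
        grad = function(x) Reduce(`+`, lapply(maps, function(m) m$grad(x))))
    })
  structure(c(obj, list(kind = kind,
                        parameters = list(t = t, A = A, gamma = gamma,
                                          amplitude = amplitude, width = width,
                                          center = center))),
            class = "deformation_map")
}

#' Apply a deformation map to a particle field
#'
#' Each particle position `x` is replaced by `x + u(x)`. Positions may leave
#' the domain; the renderer clips (or wraps, for periodic scenes).
#'
#' @param field A `particle_field`.
#' @param map A [deformation_map()].
#' @return The deformed `particle_field`, with the map recorded in metadata.
#' @export
apply_deformation <- function(field, map) {
  stopifnot(inherits(field, "particle_field"), inherits(map, "deformation_map"))
  pos <- cbind(field$x, field$y, field$z)
  newpos <- pos + map$u(pos)
  out <- tibble(x = newpos[, 1], y = newpos[, 2], z = newpos[, 3])
  new_particle_field(out, radius = attr(field, "radius"),
                     domain = attr(field, "domain"), seed = attr(field, "seed"),
                     volume_fraction = attr(field, "volume_fraction"),
                     map = map$kind)
}

#' Imaging model for the synthetic renderer
#'
#' Describes how a bead field turns into a confocal-style intensity volume:
#' voxel geometry, a Gaussian point-spread approximation, additive or Poisson
#' noise, and intensity quantization.
#'
#' @param voxel_size `c(dx, dy, dz)` micrometers per voxel.
#' @param dims Volume dimensions in voxels, `c(nx, ny, nz)`.
#' @param psf_sigma Gaussian PSF standard deviations `c(sx, sy, sz)` in
#'   micrometers; 0 disables blur beyond the particle's own extent.
#' @param noise `list(kind = "gaussian"|"poisson"|"none", level = ...)`;
#'   for Gaussian noise `level` is the standard deviation as a fraction of
#'   the peak single-particle intensity (default 0.05); for Poisson it is the
#'   expected photon count at that peak.
#' @param bit_depth Intensities are quantized to `2^bit_depth - 1` levels in
#'   [0, 1]; `NULL` keeps exact floating point (useful for oracle tests).
#' @param periodic Wrap deposits around the volume instead of clipping
#'   (used by shift-invariance oracles).
#' @return An `imaging_model` list.
#' @export
imaging_model <- function(voxel_size = c(0.35, 0.35, 0.35),
                          dims = c(128, 128, 64),
                          psf_sigma = c(0.2, 0.2, 0.6),
                          noise = list(kind = "gaussian", level = 0.05),
                          bit_depth = 16, periodic = FALSE) {
  voxel_size <- check_positive3(voxel_size, "voxel_size")
  if (any(psf_sigma < 0)) abort("`psf_sigma` must be >= 0.",
                                class = "tfm3d_parameter_error")
  stopifnot(length(dims) == 3L, all(dims >= 2))
  structure(list(voxel_size = voxel_size, dims = as.integer(dims),
                 psf_sigma = as.numeric(psf_sigma), noise = noise,
                 bit_depth = bit_depth, periodic = isTRUE(periodic)),
            class = "imaging_model")
}

#' Render a particle field into a volumetric image
#'
#' Each particle deposits a separable Gaussian spot at its sub-voxel position
#' with per-axis variance `radius^2 + psf_sigma^2` (the particle's own
#' Gaussian footprint convolved with the Gaussian PSF), normalized to unit
#' peak intensity for a single particle. Noise is then added and intensities
#' are clamped to [0, 1] and quantized to the model's bit depth.
#'
#' @param field A `particle_field`.
#' @param imaging An [imaging_model()].
#' @param seed Integer seed driving the noise realization.
#' @return A [volume_image()].
#' @export
render_volume <- function(field, imaging, seed = 1L) {
  stopifnot(inherits(field, "particle_field"), inherits(imaging, "imaging_model"))
  d <- imaging$voxel_size
  dims <- imaging$dims
  radius <- attr(field, "radius")
  sig_um <- sqrt(radius^2 + imaging$psf_sigma^2)
  sig <- sig_um / d                      # spot sigma in voxels, per axis
  hw <- pmax(1L, as.integer(ceiling(4 * sig)))
  vol <- array(0, dims)
  # particle centre in (fractional, 1-based) voxel index coordinates
  px <- (field$x - 0) / d[1] + 1
  py <- (field$y - 0) / d[2] + 1
  pz <- (field$z - 0) / d[3] + 1
  gauss1 <- function(idx, centre, s) exp(-(idx - centre)^2 / (2 * s^2))
  for (p in seq_along(px)) {
    c3 <- c(px[p], py[p], pz[p])
    i0 <- floor(c3)
    rng <- lapply(1:3, function(a) seq.int(i0[a] - hw[a], i0[a] + hw[a]))
    if (imaging$periodic) {
      widx <- lapply(1:3, function(a) ((rng[[a]] - 1L) %% dims[a]) + 1L)
      keep <- lapply(1:3, function(a) rep(TRUE, length(rng[[a]])))
    } else {
      keep <- lapply(1:3, function(a) rng[[a]] >= 1L & rng[[a]] <= dims[a])
      if (!all(vapply(keep, any, TRUE))) next
      widx <- lapply(1:3, function(a) rng[[a]][keep[[a]]])
    }
    gx <- gauss1(rng[[1]][keep[[1]]], c3[1], sig[1])
    gy <- gauss1(rng[[2]][keep[[2]]], c3[2], sig[2])
    gz <- gauss1(rng[[3]][keep[[3]]], c3[3], sig[3])
    spot <- outer(outer(gx, gy), gz)
    vol[widx[[1]], widx[[2]], widx[[3]]] <-
      vol[widx[[1]], widx[[2]], widx[[3]]] + spot
  }
  kind <- imaging$noise$kind %||% "none"
  if (kind == "gaussian" && (imaging$noise$level %||% 0) > 0) {
    vol <- vol + with_seed(seed, array(rnorm(length(vol),
                                             sd = imaging$noise$level),
                                       dims))
  } else if (kind == "poisson") {
    peak <- imaging$noise$level %||% 100
    vol <- with_seed(seed, array(rpois(length(vol), pmax(vol, 0) * peak),
                                 dims)) / peak
  }
  vol[vol < 0] <- 0
  vol[vol > 1] <- 1
  if (!is.null(imaging$bit_depth) && is.finite(imaging$bit_depth)) {
    levels <- 2^imaging$bit_depth - 1
    vol <- round(vol * levels) / levels
  }
  volume_image(vol, d, origin = c(0, 0, 0),
               label = sprintf("synthetic seed=%d n=%d", as.integer(seed),
                               nrow(field)))
}
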