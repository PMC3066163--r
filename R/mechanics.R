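# Continuum mechanics stages: displacement gradients by pointwise least
# squares, small-strain tensors, linear-elastic stress, Cauchy tractions.

#' Linear-elastic material description
#'
#' Shear modulus is always derived as `mu = E / (2 (1 + nu))`. The
#' polyacrylamide substrates this pipeline targets are well described as
#' linearly elastic, isotropic and (at nu = 0.5) incompressible.
#'
#' @param E Young's modulus in pascals.
#' @param nu Poisson's ratio in [0, 0.5].
#' @return A `material` list with fields `E`, `nu`, `mu`.
#' @export
material <- function(E, nu = 0.5) {
  if (!is.numeric(E) || E <= 0) abort("`E` must be positive (Pa).",
                                      class = "tfm3d_parameter_error")
  if (!is.numeric(nu) || nu < 0 || nu > 0.5) {
    abort("`nu` must lie in [0, 0.5].", class = "tfm3d_parameter_error")
  }
  structure(list(E = E, nu = nu, mu = E / (2 * (1 + nu))),
            class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> E = %g Pa, nu = %g, mu = %g Pa\n", x$E, x$nu, x$mu))
  invisible(x)
}

#' Estimate the displacement gradient field by pointwise least squares
#'
#' Around every grid point the local displacement field is approximated by
#' the linear expansion `u(x) ~= c + G (x - x0)` and the constants `c`
#' (3-vector) and `G` (3x3 gradient) are obtained by least squares over the
#' `stencil^3` neighborhood of grid points (physical micrometers
#' coordinates, so anisotropic grids are handled). Averaging over the
#' neighborhood makes this estimator markedly less noise-sensitive than
#' direct finite differencing. Boundary points use the clipped (one-sided)
#' neighborhood when it still has full rank; rank-deficient or
#' under-populated neighborhoods are masked.
#'
#' @param disp A `displacement_field` (or any tibble with x, y, z, u1, u2,
#'   u3 and optionally `valid`).
#' @param stencil Odd neighborhood edge length in grid points (default 3).
#' @return A `gradient_field` tibble: x, y, z, gradient components `gij`
#'   (= d u_i / d x_j, dimensionless), fitted centre displacement
#'   `c1, c2, c3` (micrometers), `residual` (root-mean-square fit residual,
#'   micrometers), `n_used`, `valid`.
#' @export
estimate_displacement_gradient <- function(disp, stencil = 3) {
  if (stencil %% 2 != 1 || stencil < 3) {
    abort("`stencil` must be odd and >= 3.", class = "tfm3d_parameter_error")
  }
  lat <- field_lattice(disp)
  dims <- lat$dims
  hw <- (stencil - 1L) %/% 2L
  ok_in <- if ("valid" %in% names(disp)) disp$valid else rep(TRUE, nrow(disp))
  ok_in[is.na(disp$u1) | is.na(disp$u2) | is.na(disp$u3)] <- FALSE

  # dense cubes of displacement and validity for fast neighborhood lookup
  lin <- cbind(lat$index$i, lat$index$j, lat$index$k)
  u1c <- array(NA_real_, dims); u1c[lin] <- disp$u1
  u2c <- array(NA_real_, dims); u2c[lin] <- disp$u2
  u3c <- array(NA_real_, dims); u3c[lin] <- disp$u3
  vcube <- array(FALSE, dims)
  vcube[lin] <- ok_in

  n <- nrow(disp)
  G <- matrix(NA_real_, n, 9)
  C <- matrix(NA_real_, n, 3)
  resid <- rep(NA_real_, n)
  n_used <- integer(n)
  valid <- logical(n)

  ax <- lat$axes
  for (q in seq_len(n)) {
    i <- lat$index$i[q]; j <- lat$index$j[q]; k <- lat$index$k[q]
    ii <- max(1L, i - hw):min(dims[1], i + hw)
    jj <- max(1L, j - hw):min(dims[2], j + hw)
    kk <- max(1L, k - hw):min(dims[3], k + hw)
    vv <- vcube[ii, jj, kk]
    m <- sum(vv)
    n_used[q] <- m
    if (m < 4L) next
    nb <- as.matrix(expand.grid(i = ii, j = jj, k = kk))[as.vector(vv), ,
                                                         drop = FALSE]
    X <- cbind(1,
               ax$x[nb[, 1]] - ax$x[i],
               ax$y[nb[, 2]] - ax$y[j],
               ax$z[nb[, 3]] - ax$z[k])
    qrX <- qr(X)
    if (qrX$rank < 4L) next
    Y <- cbind(u1c[nb], u2c[nb], u3c[nb])
    cf <- qr.coef(qrX, Y)            # 4 x 3: row 1 = c, rows 2:4 = dui/dxj
    C[q, ] <- cf[1, ]
    # cf[1 + j, i] = d u_i / d x_j; column-major vectorization of cf[2:4, ]
    # yields g11, g12, g13, g21, ... (u index outer, x index inner)
    G[q, ] <- as.vector(cf[2:4, ])
    resid[q] <- sqrt(sum((Y - X %*% cf)^2) / (3 * m))
    valid[q] <- TRUE
  }
  out <- tibble(
    x = disp$x, y = disp$y, z = disp$z,
    g11 = G[, 1], g12 = G[, 2], g13 = G[, 3],
    g21 = G[, 4], g22 = G[, 5], g23 = G[, 6],
    g31 = G[, 7], g32 = G[, 8], g33 = G[, 9],
    c1 = C[, 1], c2 = C[, 2], c3 = C[, 3],
    residual = resid, n_used = n_used, valid = valid)
  structure(out, class = c("gradient_field", class(tibble())),
            stencil = stencil)
}

#' Small-strain tensor from a displacement gradient field
#'
#' `epsilon = (G + G^T) / 2` at every valid point. Each point is flagged as
#' inside the material's linear range when every component magnitude stays
#' below 5%.
#'
#' @param grad A `gradient_field`.
#' @return A strain `tensor_field` tibble with components e11, e22, e33,
#'   e12, e13, e23 (dimensionless), `linear_range`, `valid`.
#' @export
strain_from_gradient <- function(grad) {
  e11 <- grad$g11; e22 <- grad$g22; e33 <- grad$g33
  e12 <- (grad$g12 + grad$g21) / 2
  e13 <- (grad$g13 + grad$g31) / 2
  e23 <- (grad$g23 + grad$g32) / 2
  mx <- pmax(abs(e11), abs(e22), abs(e33), abs(e12), abs(e13), abs(e23))
  out <- tibble(x = grad$x, y = grad$y, z = grad$z,
                e11 = e11, e22 = e22, e33 = e33,
                e12 = e12, e13 = e13, e23 = e23,
                max_abs = mx,
                linear_range = !is.na(mx) & mx < 0.05,
                valid = grad$valid)
  structure(out, class = c("tensor_field", class(tibble())),
            kind = "strain", units = "dimensionless")
}

#' Stress tensor from strain under linear elasticity
#'
#' Default (incompressible, nu = 0.5) form is the deviatoric law
#' `sigma = 2 mu epsilon` with `mu = E / (2 (1 + nu))`; the hydrostatic
#' pressure of a truly incompressible solid is statically indeterminate from
#' strain alone and is set to zero. For nu < 0.5 the compressible Lame form
#' `sigma = 2 mu epsilon + lambda tr(epsilon) I` is available. The absolute
#' strain trace is carried along as an incompressibility diagnostic.
#'
#' @param strain A strain `tensor_field`.
#' @param mat A [material()].
#' @param form `"incompressible"` (sigma = 2 mu epsilon) or `"compressible"`
#'   (adds the lambda tr(epsilon) I term; requires nu < 0.5).
#' @return A stress `tensor_field` tibble (components s11 ... s23, Pa) with
#'   an `eps_trace` diagnostic column.
#' @export
stress_from_strain <- function(strain, mat,
                               form = c("incompressible", "compressible")) {
  form <- match.arg(form)
  stopifnot(inherits(mat, "material"))
  if (!identical(attr(strain, "kind"), "strain")) {
    abort("`strain` must be a strain tensor_field.",
          class = "tfm3d_parameter_error")
  }
  mu <- mat$mu
  tr <- strain$e11 + strain$e22 + strain$e33
  lam <- 0
  if (form == "compressible") {
    if (mat$nu >= 0.5) {
      abort("compressible form requires nu < 0.5.",
            class = "tfm3d_parameter_error")
    }
    lam <- mat$E * mat$nu / ((1 + mat$nu) * (1 - 2 * mat$nu))
  }
  out <- tibble(x = strain$x, y = strain$y, z = strain$z,
                s11 = 2 * mu * strain$e11 + lam * tr,
                s22 = 2 * mu * strain$e22 + lam * tr,
                s33 = 2 * mu * strain$e33 + lam * tr,
                s12 = 2 * mu * strain$e12,
                s13 = 2 * mu * strain$e13,
                s23 = 2 * mu * strain$e23,
                eps_trace = abs(tr),
                valid = strain$valid)
  structure(out, class = c("tensor_field", class(tibble())),
            kind = "stress", units = "Pa", material = mat, form = form)
}

#' Traction vectors on a plane through the grid (Cauchy relation)
#'
#' Evaluates `T = sigma n` at every lattice point of a selected planar slice.
#' Components are reported in the fixed global frame; for the standard
#' surface normal `n = (0, 0, 1)`, `t1` and `t2` are the in-plane (shear)
#' tractions and `t3` the out-of-plane (normal) traction. 1 Pa = 1 pN/um^2.
#'
#' @param stress A stress `tensor_field`.
#' @param n Plane normal (normalized internally).
#' @param plane Slice specification `list(axis =, index =)` with `axis` in
#'   1:3 and `index` the lattice index along that axis, or
#'   `list(axis =, value =)` with a physical coordinate (matched to the
#'   nearest lattice plane). `NULL` evaluates T on every grid point.
#' @return A `traction_field` tibble: x, y, z, t1, t2, t3 (Pa),
#'   `magnitude = sqrt(t1^2 + t2^2 + t3^2)`, `valid`; the unit normal is
#'   stored in the `normal` attribute.
#' @export
traction_on_plane <- function(stress, n = c(0, 0, 1), plane = NULL) {
  if (!identical(attr(stress, "kind"), "stress")) {
    abort("`stress` must be a stress tensor_field.",
          class = "tfm3d_parameter_error")
  }
  nn <- as.numeric(n)
  nrm <- sqrt(sum(nn^2))
  if (nrm == 0) abort("`n` must be nonzero.", class = "tfm3d_parameter_error")
  nn <- nn / nrm
  sl <- stress
  if (!is.null(plane)) {
    ax_col <- c("x", "y", "z")[plane$axis]
    vals <- sort(unique(stress[[ax_col]]))
    target <- if (!is.null(plane$index)) {
      if (plane$index < 1 || plane$index > length(vals)) {
        abort(sprintf("plane index %d outside grid (1..%d along %s).",
                      plane$index, length(vals), ax_col),
              class = "tfm3d_bounds_error")
      }
      vals[plane$index]
    } else {
      if (plane$value < min(vals) - 1e-9 || plane$value > max(vals) + 1e-9) {
        abort(sprintf("plane %s = %g outside grid range [%g, %g].",
                      ax_col, plane$value, min(vals), max(vals)),
              class = "tfm3d_bounds_error")
      }
      vals[which.min(abs(vals - plane$value))]
    }
    sl <- stress[abs(stress[[ax_col]] - target) < 1e-9, ]
  }
  t1 <- sl$s11 * nn[1] + sl$s12 * nn[2] + sl$s13 * nn[3]
  t2 <- sl$s12 * nn[1] + sl$s22 * nn[2] + sl$s23 * nn[3]
  t3 <- sl$s13 * nn[1] + sl$s23 * nn[2] + sl$s33 * nn[3]
  out <- tibble(x = sl$x, y = sl$y, z = sl$z,
                t1 = t1, t2 = t2, t3 = t3,
                magnitude = sqrt(t1^2 + t2^2 + t3^2),
                valid = sl$valid)
  structure(out, class = c("traction_field", class(tibble())),
            normal = nn)
}

#' Surface traction map
#'
#' Convenience wrapper for the map of tractions the cell exerts across the
#' gel's free surface: evaluates the Cauchy relation with the outward
#' surface normal `n = (0, 0, 1)` on a constant-depth lattice plane.
#'
#' @param stress A stress `tensor_field`.
#' @param surface_index Lattice index along the depth axis; default is the
#'   topmost plane containing any valid point.
#' @return A `traction_field` tibble (see [traction_on_plane()]).
#' @export
surface_traction_map <- function(stress, surface_index = NULL) {
  zs <- sort(unique(stress$z))
  if (is.null(surface_index)) {
    has_valid <- vapply(zs, function(zv) {
      any(stress$valid[abs(stress$z - zv) < 1e-9], na.rm = TRUE)
    }, TRUE)
    if (!any(has_valid)) {
      abort("no valid stress plane found.", class = "tfm3d_bounds_error")
    }
    surface_index <- max(which(has_valid))
  }
  traction_on_plane(stress, n = c(0, 0, 1),
                    plane = list(axis = 3, index = surface_index))
}
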