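# Measurement sensitivity (zero-load noise floor) and control-volume
# force/moment balance checks.

#' Sensitivity of the full pipeline from a zero-load volume pair
#'
#' Runs DVC, displacement gradients, strain, stress and the surface traction
#' map on two acquisitions of the same undeformed scene. Every resulting
#' displacement, strain and traction is measurement noise by construction,
#' so the summary statistics bound what the technique can detect under the
#' given imaging conditions.
#'
#' @param refA,refB [volume_image()]s of the same undeformed sample
#'   (independent acquisitions or noise realizations).
#' @param config A [dvc_config()].
#' @param mat A [material()] used for the stress/traction propagation.
#' @param stencil Gradient stencil (grid points per edge).
#' @return A `sensitivity_report`: list with `displacement` (RMS and 95th
#'   percentile of |u|, micrometers), `strain` (RMS and 95th percentile of
#'   max |eps_ij|, dimensionless), `traction` (RMS and max |T| on the top
#'   valid surface plane, Pa), `degenerate_pair` flag, the fields
#'   themselves, and config provenance.
#' @export
noise_floor <- function(refA, refB, config = dvc_config(),
                        mat = material(E = 9640, nu = 0.5), stencil = 3) {
  stopifnot(is_volume_image(refA), is_volume_image(refB))
  degenerate <- identical(refA$intensities, refB$intensities)
  if (degenerate) {
    warn("refA and refB are identical arrays: the pair measures algorithmic round-off, not acquisition noise.")
  }
  disp <- compute_displacement_field(refA, refB, config)
  grad <- estimate_displacement_gradient(disp, stencil = stencil)
  strain <- strain_from_gradient(grad)
  stress <- stress_from_strain(strain, mat)
  traction <- surface_traction_map(stress)
  dmag <- disp$magnitude[disp$valid]
  smax <- strain$max_abs[strain$valid]
  tmag <- traction$magnitude[traction$valid]
  structure(list(
    displacement = c(rms = rms(dmag), p95 = unname(quantile(dmag, 0.95))),
    strain = c(rms = rms(smax), p95 = unname(quantile(smax, 0.95))),
    traction = c(rms = rms(tmag), max = max(tmag)),
    degenerate_pair = degenerate,
    fields = list(displacement = disp, strain = strain, stress = stress,
                  traction = traction),
    config = config, material = mat, stencil = stencil),
    class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("<sensitivity_report>\n")
  cat(sprintf("  displacement: RMS %.4g um, p95 %.4g um\n",
              x$displacement["rms"], x$displacement["p95"]))
  cat(sprintf("  strain:       RMS %.4g (%.3g%%), p95 %.4g\n",
              x$strain["rms"], 100 * x$strain["rms"], x$strain["p95"]))
  cat(sprintf("  traction:     RMS %.4g Pa, max %.4g Pa\n",
              x$traction["rms"], x$traction["max"]))
  if (x$degenerate_pair) cat("  [degenerate: identical input arrays]\n")
  invisible(x)
}

#' Net force and moment on a control volume
#'
#' Integrates surface tractions `T = sigma n` over the six faces of an
#' axis-aligned box of lattice points (outward normals; tensor-product
#' trapezoid quadrature over the face nodes, equivalent to a midpoint rule
#' on bilinearly interpolated cell centres). In static equilibrium both
#' the net force and the net moment about the box centroid vanish up to
#' noise and quadrature error. Stress in Pa (= pN/um^2) and lengths in
#' micrometers give forces in pN and moments in pN um; these are reported in
#' mN (1 pN = 1e-9 mN) and mN mm (1 pN um = 1e-12 mN mm).
#'
#' @param stress A stress `tensor_field` on a complete regular lattice.
#' @param box Lattice index ranges `list(i = c(i0, i1), j = c(j0, j1),
#'   k = c(k0, k1))` selecting the control volume's corner grid points.
#' @return A `balance_report`: net force (mN), net moment about the centroid
#'   (mN mm), per-face force breakdown, box geometry.
#' @export
force_moment_balance <- function(stress, box) {
  lat <- field_lattice(stress)
  dims <- lat$dims
  for (a in seq_along(c("i", "j", "k"))) {
    rng <- box[[c("i", "j", "k")[a]]]
    if (is.null(rng) || length(rng) != 2L || rng[1] < 1 || rng[2] > dims[a] ||
        rng[1] >= rng[2]) {
      abort(sprintf("box range along %s must lie within 1..%d.",
                    c("i", "j", "k")[a], dims[a]),
            class = "tfm3d_bounds_error")
    }
  }
  # dense component cubes
  comp <- c("s11", "s22", "s33", "s12", "s13", "s23")
  lin <- cbind(lat$index$i, lat$index$j, lat$index$k)
  cubes <- lapply(comp, function(cc) {
    a <- array(NA_real_, dims); a[lin] <- stress[[cc]]; a
  })
  names(cubes) <- comp
  ax <- lat$axes
  sp <- vapply(ax, function(a) if (length(a) > 1) a[2] - a[1] else 1, 0)
  ii <- box$i[1]:box$i[2]; jj <- box$j[1]:box$j[2]; kk <- box$k[1]:box$k[2]
  centroid <- c(mean(ax$x[ii]), mean(ax$y[jj]), mean(ax$z[kk]))

  face_force <- matrix(0, 6, 3)
  face_moment <- matrix(0, 6, 3)
  face_names <- c("x-", "x+", "y-", "y+", "z-", "z+")
  abs_t_sum <- 0; abs_t_n <- 0L
  f <- 0L
  for (axis in 1:3) {
    for (side in 1:2) {
      f <- f + 1L
      n <- c(0, 0, 0)
      n[axis] <- if (side == 1) -1 else 1
      fi <- if (axis == 1) if (side == 1) ii[1] else ii[length(ii)] else ii
      fj <- if (axis == 2) if (side == 1) jj[1] else jj[length(jj)] else jj
      fk <- if (axis == 3) if (side == 1) kk[1] else kk[length(kk)] else kk
      pts <- expand.grid(i = fi, j = fj, k = fk)
      pm <- as.matrix(pts)
      S <- cbind(cubes$s11[pm], cubes$s22[pm], cubes$s33[pm],
                 cubes$s12[pm], cubes$s13[pm], cubes$s23[pm])
      if (any(is.na(S))) {
        abort("stress is not defined on the whole control surface.",
              class = "tfm3d_bounds_error")
      }
      Tx <- S[, 1] * n[1] + S[, 4] * n[2] + S[, 5] * n[3]
      Ty <- S[, 4] * n[1] + S[, 2] * n[2] + S[, 6] * n[3]
      Tz <- S[, 5] * n[1] + S[, 6] * n[2] + S[, 3] * n[3]
      # tensor-product trapezoid quadrature over the face (equivalent to a
      # midpoint rule on bilinearly interpolated cell centres): edge nodes
      # carry half weight, so the weights sum to the exact face area
      inplane <- setdiff(1:3, axis)
      idxs <- list(fi, fj, fk)
      wts <- lapply(inplane, function(a) {
        m <- length(idxs[[a]])
        w <- rep(1, m); w[c(1, m)] <- 0.5
        w * sp[a]
      })
      dA <- as.vector(outer(wts[[1]], wts[[2]]))
      r <- cbind(ax$x[pts$i], ax$y[pts$j], ax$z[pts$k])
      rc <- sweep(r, 2, centroid)
      Tm <- cbind(Tx, Ty, Tz)
      abs_t_sum <- abs_t_sum + sum(sqrt(rowSums(Tm^2)))
      abs_t_n <- abs_t_n + nrow(Tm)
      face_force[f, ] <- colSums(Tm * dA)
      face_moment[f, ] <- colSums(cbind(
        rc[, 2] * Tm[, 3] - rc[, 3] * Tm[, 2],
        rc[, 3] * Tm[, 1] - rc[, 1] * Tm[, 3],
        rc[, 1] * Tm[, 2] - rc[, 2] * Tm[, 1]) * dA)
    }
  }
  rownames(face_force) <- rownames(face_moment) <- face_names
  pn_to_mn <- 1e-9          # pN -> mN
  pnum_to_mnmm <- 1e-12     # pN um -> mN mm
  structure(list(
    net_force_mN = colSums(face_force) * pn_to_mn,
    net_moment_mN_mm = colSums(face_moment) * pnum_to_mnmm,
    face_force_mN = face_force * pn_to_mn,
    total_face_area_um2 = 2 * sum(
      diff(range(ax$x[ii])) * diff(range(ax$y[jj])),
      diff(range(ax$y[jj])) * diff(range(ax$z[kk])),
      diff(range(ax$x[ii])) * diff(range(ax$z[kk]))),
    mean_abs_traction_Pa = abs_t_sum / abs_t_n,
    centroid_um = centroid, box = box),
    class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat("<balance_report>\n")
  cat(sprintf("  net force  (mN):    % .3e % .3e % .3e\n",
              x$net_force_mN[1], x$net_force_mN[2], x$net_force_mN[3]))
  cat(sprintf("  net moment (mN mm): % .3e % .3e % .3e\n",
              x$net_moment_mN_mm[1], x$net_moment_mN_mm[2],
              x$net_moment_mN_mm[3]))
  invisible(x)
}
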