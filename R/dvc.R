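# Digital volume correlation: FFT cross-correlation of cubic subsets with
# 3D quadratic subvoxel peak localization.

#' DVC configuration
#'
#' @param subset_size Cubic subset edge in voxels; even, >= 16. 64 gives
#'   robust correlation for typical tracer densities.
#' @param grid_spacing Spacing of the displacement grid in micrometers
#'   (converted to an integer voxel stride per axis, rounded, minimum 1).
#' @param fit_radius Half-width of the quadratic peak-fit neighborhood in
#'   voxels (1 = a 3x3x3 stencil).
#' @param max_lag Peak search bound in voxels (default `subset_size / 4`,
#'   keeping circular wrap-around bias negligible).
#' @param min_peak_ratio Primary/secondary correlation peak ratio below which
#'   a point is flagged (not invalidated) as low-confidence.
#' @param pad Zero-pad subsets to twice their size before correlating,
#'   trading speed for the removal of circular wrap-around.
#' @return A `dvc_config` list.
#' @export
dvc_config <- function(subset_size = 64, grid_spacing = 2, fit_radius = 1,
                       max_lag = NULL, min_peak_ratio = 1.2, pad = FALSE) {
  if (subset_size < 16 || subset_size %% 2 != 0) {
    abort("`subset_size` must be even and >= 16.",
          class = "tfm3d_parameter_error")
  }
  if (grid_spacing <= 0) abort("`grid_spacing` must be > 0.",
                               class = "tfm3d_parameter_error")
  if (fit_radius < 1) abort("`fit_radius` must be >= 1.",
                            class = "tfm3d_parameter_error")
  structure(list(subset_size = as.integer(subset_size),
                 grid_spacing = grid_spacing,
                 fit_radius = as.integer(fit_radius),
                 max_lag = as.integer(max_lag %||% (subset_size / 4)),
                 min_peak_ratio = min_peak_ratio,
                 pad = isTRUE(pad)),
            class = "dvc_config")
}

#' Cross-correlate two image subsets via FFT
#'
#' Computes the circular cross-correlation `m(s) = sum_x f(x) g(x + s)` of
#' two equally sized intensity blocks through the Fourier transform (both
#' blocks are mean-subtracted first, suppressing the DC pedestal). The two
#' real transforms are obtained from a single complex FFT of `f + i g`. The
#' result is reordered so that zero lag sits at the centre of a
#' `-L .. L-1` lag lattice; with this convention the peak lag is the
#' displacement carrying features of `f` onto `g` (reference to deformed).
#'
#' @param f_subset,g_subset 3D numeric arrays of identical dimensions
#'   (reference and deformed intensity blocks).
#' @param pad Zero-pad to double size, removing circular wrap-around.
#' @return A `correlation_volume`: list with `values` (3D array over the lag
#'   lattice), `lags` (per-axis lag integer vectors) and `degenerate`
#'   (TRUE when either block has zero intensity variance, in which case no
#'   peak is meaningful).
#' @export
cross_correlate_subsets <- function(f_subset, g_subset, pad = FALSE) {
  if (!identical(dim(f_subset), dim(g_subset)) ||
      length(dim(f_subset)) != 3L) {
    abort("subsets must be 3D arrays of identical dimensions.",
          class = "tfm3d_parameter_error")
  }
  fc <- f_subset - mean(f_subset)
  gc <- g_subset - mean(g_subset)
  degenerate <- sum(fc * fc) == 0 || sum(gc * gc) == 0
  if (degenerate) {
    dims <- dim(f_subset)
    return(structure(list(values = array(0, dims),
                          lags = lapply(dims, lag_values),
                          degenerate = TRUE),
                     class = "correlation_volume"))
  }
  if (pad) {
    d0 <- dim(fc)
    fp <- array(0, 2L * d0); gp <- array(0, 2L * d0)
    fp[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3])] <- fc
    gp[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3])] <- gc
    fc <- fp; gc <- gp
  }
  dims <- dim(fc)
  # one complex FFT carries both real transforms: Z = F + i G
  z <- fft(fc + (0+1i) * gc)
  rev1 <- c(1L, rev(seq_len(dims[1])[-1]))
  rev2 <- c(1L, rev(seq_len(dims[2])[-1]))
  rev3 <- c(1L, rev(seq_len(dims[3])[-1]))
  zr <- Conj(z[rev1, rev2, rev3])          # conj(Z(-k))
  ff <- (z + zr) / 2                       # F(k)
  gg <- (z - zr) / (0+2i)                  # G(k)
  # peak of IFFT(conj(F) G) sits at the f -> g displacement
  cc <- Re(fft(Conj(ff) * gg, inverse = TRUE)) / prod(dims)
  i1 <- fftshift_index(dims[1])
  i2 <- fftshift_index(dims[2])
  i3 <- fftshift_index(dims[3])
  structure(list(values = cc[i1, i2, i3],
                 lags = lapply(dims, lag_values),
                 degenerate = FALSE),
            class = "correlation_volume")
}

# Cache of quadratic-fit solve operators keyed by fit radius.
quad_fit_cache <- new.env(parent = emptyenv())

quad_fit_operator <- function(fit_radius) {
  key <- as.character(fit_radius)
  if (!is.null(quad_fit_cache[[key]])) return(quad_fit_cache[[key]])
  r <- seq.int(-fit_radius, fit_radius)
  g <- expand.grid(d1 = r, d2 = r, d3 = r)
  X <- with(g, cbind(1, d1, d2, d3, d1^2, d2^2, d3^2,
                     d1 * d2, d1 * d3, d2 * d3))
  op <- list(pinv = solve(crossprod(X), t(X)), offsets = as.matrix(g))
  quad_fit_cache[[key]] <- op
  op
}

#' Locate the correlation peak with subvoxel precision
#'
#' Finds the integer-lattice maximum of a correlation volume and refines it
#' by a least-squares fit of a full 3D quadratic polynomial (10 coefficients:
#' constant, 3 linear, 6 quadratic) over the `(2 fit_radius + 1)^3`
#' neighborhood; the fitted stationary point is returned. When the fitted
#' Hessian is not negative definite, or the refinement exceeds one voxel in
#' any component, the integer peak is kept and the point flagged. Exactly
#' tied maxima resolve to the lexicographically smallest lag and are flagged.
#'
#' @param corr A `correlation_volume`.
#' @param fit_radius Neighborhood half-width in voxels (default 1).
#' @return List with `lag` (fractional voxels), `integer_lag`, `peak_value`,
#'   `peak_ratio` (primary over secondary peak outside a 3-voxel exclusion
#'   zone; `Inf` when no secondary exists) and `flag` (character; "" when
#'   clean, else comma-separated from "boundary", "nonconcave", "tie",
#'   "degenerate").
#' @export
locate_peak_subvoxel <- function(corr, fit_radius = 1) {
  stopifnot(inherits(corr, "correlation_volume"))
  if (isTRUE(corr$degenerate)) {
    return(list(lag = c(NA_real_, NA_real_, NA_real_),
                integer_lag = c(NA_integer_, NA_integer_, NA_integer_),
                peak_value = NA_real_, peak_ratio = NA_real_,
                flag = "degenerate"))
  }
  v <- corr$values
  dims <- dim(v)
  mx <- max(v)
  hits <- which(v == mx)
  flag <- character()
  if (length(hits) > 1L) {
    ai <- arrayInd(hits, dims)
    lagm <- cbind(corr$lags[[1]][ai[, 1]], corr$lags[[2]][ai[, 2]],
                  corr$lags[[3]][ai[, 3]])
    pick <- order(lagm[, 1], lagm[, 2], lagm[, 3])[1]
    idx <- ai[pick, ]
    flag <- c(flag, "tie")
  } else {
    idx <- arrayInd(hits, dims)[1, ]
  }
  int_lag <- c(corr$lags[[1]][idx[1]], corr$lags[[2]][idx[2]],
               corr$lags[[3]][idx[3]])

  # secondary peak outside an L-inf exclusion zone of 3 voxels
  excl <- 3L
  lo <- pmax(idx - excl, 1L); hi <- pmin(idx + excl, dims)
  vv <- v
  vv[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- -Inf
  secondary <- max(vv)
  peak_ratio <- if (is.finite(secondary) && secondary > 0) mx / secondary else Inf

  if (any(idx - fit_radius < 1L) || any(idx + fit_radius > dims)) {
    return(list(lag = as.numeric(int_lag), integer_lag = int_lag,
                peak_value = mx, peak_ratio = peak_ratio,
                flag = paste(c(flag, "boundary"), collapse = ",")))
  }
  op <- quad_fit_operator(fit_radius)
  nb <- v[(idx[1] - fit_radius):(idx[1] + fit_radius),
          (idx[2] - fit_radius):(idx[2] + fit_radius),
          (idx[3] - fit_radius):(idx[3] + fit_radius)]
  beta <- drop(op$pinv %*% as.vector(nb))
  b <- beta[2:4]
  H <- matrix(c(2 * beta[5], beta[8],     beta[9],
                beta[8],     2 * beta[6], beta[10],
                beta[9],     beta[10],    2 * beta[7]), 3, 3)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev >= 0)) {
    return(list(lag = as.numeric(int_lag), integer_lag = int_lag,
                peak_value = mx, peak_ratio = peak_ratio,
                flag = paste(c(flag, "nonconcave"), collapse = ",")))
  }
  delta <- -solve(H, b)
  if (any(abs(delta) > 1)) {
    return(list(lag = as.numeric(int_lag), integer_lag = int_lag,
                peak_value = mx, peak_ratio = peak_ratio,
                flag = paste(c(flag, "nonconcave"), collapse = ",")))
  }
  list(lag = int_lag + delta, integer_lag = int_lag,
       peak_value = mx, peak_ratio = peak_ratio,
       flag = paste(flag, collapse = ","))
}

#' Compute a full-field 3D displacement field by DVC
#'
#' Lays a regular grid over the shared volume (stride = `grid_spacing`
#' converted to voxels per axis, rounded, minimum 1; only grid points whose
#' subset fits entirely inside the volume are used), extracts centred cubic
#' subsets from the reference and deformed volumes, cross-correlates each
#' pair, localizes the correlation peak to subvoxel precision, and converts
#' the fractional voxel lag to micrometers through the voxel size. The
#' displacement convention is reference to deformed: `u = x_def - x_ref`.
#'
#' @param ref,def [volume_image()]s with identical dimensions and voxel size.
#' @param config A [dvc_config()].
#' @return A `displacement_field` tibble: grid indices `gi, gj, gk`, physical
#'   subset-centre coordinates `x, y, z` (micrometers), displacement
#'   components `u1, u2, u3` (micrometers), `magnitude = sqrt(u1^2 + u2^2 +
#'   u3^2)`, and quality columns `peak_value`, `peak_ratio`, `valid`, `flag`.
#'   Voxel size, stride and the configuration ride along as attributes.
#' @export
compute_displacement_field <- function(ref, def, config = dvc_config()) {
  stopifnot(is_volume_image(ref), is_volume_image(def))
  if (!identical(dim(ref$intensities), dim(def$intensities))) {
    abort("reference and deformed volumes differ in dimensions.",
          class = "tfm3d_parameter_error")
  }
  if (max(abs(ref$voxel_size - def$voxel_size)) > 1e-12) {
    abort("reference and deformed volumes differ in voxel size.",
          class = "tfm3d_parameter_error")
  }
  dims <- dim(ref$intensities)
  s <- config$subset_size
  half <- s %/% 2L
  if (any(dims < s)) {
    abort("subset larger than volume.", class = "tfm3d_parameter_error")
  }
  stride <- pmax(1L, as.integer(round(config$grid_spacing / ref$voxel_size)))
  centers <- lapply(1:3, function(a) seq.int(half, dims[a] - half, by = stride[a]))
  L <- min(config$max_lag, half - 1L)
  win_lags <- seq.int(-L, L)

  grid <- expand.grid(gi = seq_along(centers[[1]]),
                      gj = seq_along(centers[[2]]),
                      gk = seq_along(centers[[3]]))
  n <- nrow(grid)
  u <- matrix(NA_real_, n, 3)
  peak_value <- peak_ratio <- rep(NA_real_, n)
  flag <- character(n)
  fv <- ref$intensities
  gv <- def$intensities
  for (q in seq_len(n)) {
    c1 <- centers[[1]][grid$gi[q]]
    c2 <- centers[[2]][grid$gj[q]]
    c3 <- centers[[3]][grid$gk[q]]
    rs <- list((c1 - half + 1L):(c1 + half),
               (c2 - half + 1L):(c2 + half),
               (c3 - half + 1L):(c3 + half))
    fs <- fv[rs[[1]], rs[[2]], rs[[3]]]
    gs <- gv[rs[[1]], rs[[2]], rs[[3]]]
    if (config$pad) {
      corr <- cross_correlate_subsets(fs, gs, pad = TRUE)
    } else if (sum((fs - mean(fs))^2) == 0 || sum((gs - mean(gs))^2) == 0) {
      corr <- structure(list(values = NULL, lags = NULL, degenerate = TRUE),
                        class = "correlation_volume")
    } else {
      # compiled path: correlate and extract the +-L lag window in one step
      corr <- structure(
        list(values = .correlate_window_cpp(fs, gs, dim(fs), L),
             lags = list(win_lags, win_lags, win_lags),
             degenerate = FALSE),
        class = "correlation_volume")
    }
    pk <- locate_peak_subvoxel(corr, config$fit_radius)
    u[q, ] <- pk$lag
    peak_value[q] <- pk$peak_value
    peak_ratio[q] <- pk$peak_ratio
    flag[q] <- pk$flag
  }
  low <- !is.na(peak_ratio) & is.finite(peak_ratio) &
    peak_ratio < config$min_peak_ratio
  flag[low] <- ifelse(nzchar(flag[low]), paste0(flag[low], ",low_ratio"),
                      "low_ratio")
  valid <- !is.na(u[, 1]) & !grepl("boundary|degenerate", flag)
  u[!valid, ] <- NA_real_
  d <- ref$voxel_size
  um <- sweep(u, 2, d, `*`)
  out <- tibble(
    gi = grid$gi, gj = grid$gj, gk = grid$gk,
    x = ref$origin[1] + (centers[[1]][grid$gi] - 0.5) * d[1],
    y = ref$origin[2] + (centers[[2]][grid$gj] - 0.5) * d[2],
    z = ref$origin[3] + (centers[[3]][grid$gk] - 0.5) * d[3],
    u1 = um[, 1], u2 = um[, 2], u3 = um[, 3],
    magnitude = sqrt(um[, 1]^2 + um[, 2]^2 + um[, 3]^2),
    peak_value = peak_value, peak_ratio = peak_ratio,
    valid = valid, flag = flag)
  structure(out,
            class = c("displacement_field", class(tibble())),
            voxel_size = d, stride = stride, config = config,
            grid_centers = centers)
}
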