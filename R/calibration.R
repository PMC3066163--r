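# Material calibration from compression testing of cylindrical gel samples.

#' Young's modulus from an unconfined compression record
#'
#' Fits the loading branch of a nominal (engineering) stress-strain record
#' with an origin-anchored straight line, `E = sum(sigma eps) / sum(eps^2)`;
#' stress and strain are both zero at platen contact, so the line is forced
#' through the origin by default (a free-intercept fit is reported
#' alongside). Loading and unloading slopes are fitted separately so
#' hysteresis shows up as a slope difference.
#'
#' @param data Data frame with columns `strain` (dimensionless, in [0, 0.2]),
#'   `stress_pa` (Pa) and `phase` (`"loading"` / `"unloading"`). Needs at
#'   least 3 loading points with monotonically non-decreasing strain.
#' @param anchor_origin Force the fit through the origin (default TRUE).
#' @return A `compression_fit` object: `E` (Pa), `se` (standard error of the
#'   slope), `E_loading`, `E_unloading` (NA without unloading data),
#'   `intercept_fit` (free-intercept slope and intercept), `n`.
#' @export
young_modulus_unconfined <- function(data, anchor_origin = TRUE) {
  req <- c("strain", "stress_pa")
  if (!all(req %in% names(data))) {
    abort("`data` needs columns strain, stress_pa (and optionally phase).",
          class = "tfm3d_data_error")
  }
  if (!"phase" %in% names(data)) data$phase <- "loading"
  if (any(data$strain < 0 | data$strain > 0.2)) {
    abort("strains must lie within [0, 0.2].", class = "tfm3d_data_error")
  }
  load <- data[data$phase == "loading", ]
  if (nrow(load) < 3L) {
    abort("need at least 3 loading points.", class = "tfm3d_data_error")
  }
  if (is.unsorted(load$strain, strictly = FALSE)) {
    abort("loading strain sequence is not monotonic.",
          class = "tfm3d_data_error")
  }
  fit_slope <- function(d) {
    if (nrow(d) < 3L) return(list(E = NA_real_, se = NA_real_))
    # exact synthetic records fit perfectly; the lm summary warning about
    # that is expected, not actionable
    if (anchor_origin) {
      f <- lm(stress_pa ~ strain + 0, data = d)
      list(E = unname(coef(f)[1]),
           se = suppressWarnings(unname(sqrt(diag(vcov(f)))[1])))
    } else {
      f <- lm(stress_pa ~ strain, data = d)
      list(E = unname(coef(f)["strain"]),
           se = suppressWarnings(unname(sqrt(diag(vcov(f)))["strain"])))
    }
  }
  ld <- fit_slope(load)
  ul <- fit_slope(data[data$phase == "unloading", ])
  free <- lm(stress_pa ~ strain, data = load)
  structure(list(E = ld$E, se = ld$se,
                 E_loading = ld$E, E_unloading = ul$E,
                 intercept_fit = list(E = unname(coef(free)["strain"]),
                                      intercept = unname(coef(free)[1])),
                 n = nrow(load), anchor_origin = anchor_origin),
            class = "compression_fit")
}

#' @export
print.compression_fit <- function(x, ...) {
  cat(sprintf("<compression_fit> E = %.4g Pa (se %.3g, n = %d)\n",
              x$E, x$se, x$n))
  if (!is.na(x$E_unloading)) {
    cat(sprintf("  loading %.4g Pa / unloading %.4g Pa\n",
                x$E_loading, x$E_unloading))
  }
  invisible(x)
}

#' @importFrom stats vcov
NULL

#' Poisson's ratio from the confined compression modulus
#'
#' Inverts `M = E (1 - nu) / ((1 + nu)(1 - 2 nu))` for `nu` on [0, 0.5) by
#' bracketed root finding. The map is strictly increasing in `nu`, so the
#' solution is unique; `M = E` gives `nu = 0`, and `M -> Inf` drives
#' `nu -> 0.5` (the confined modulus diverges for an incompressible solid —
#' experimentally, further confined compression becomes impossible). When
#' `M / E` exceeds `ratio_cap` the asymptote 0.5 is returned directly.
#'
#' @param M Confined (constrained) compression modulus, Pa.
#' @param E Young's modulus from the unconfined test, Pa.
#' @param ratio_cap `M / E` above which `nu = 0.5` is returned.
#' @param tol Root-finding tolerance on `nu`.
#' @return Poisson's ratio in [0, 0.5].
#' @export
poisson_from_confined_modulus <- function(M, E, ratio_cap = 1e8,
                                          tol = 1e-12) {
  if (!is.numeric(E) || E <= 0) abort("`E` must be positive.",
                                      class = "tfm3d_parameter_error")
  if (!is.numeric(M) || M < E) {
    abort("no solution in [0, 0.5): the confined modulus M must be >= E.",
          class = "tfm3d_domain_error")
  }
  if (M / E >= ratio_cap) return(0.5)
  f <- function(nu) E * (1 - nu) / ((1 + nu) * (1 - 2 * nu)) - M
  if (f(0) >= 0) return(0)
  upper <- 0.5 - 1e-14
  while (f(upper) < 0) upper <- 0.5 - (0.5 - upper) / 10  # cannot in exact math
  stats::uniroot(f, c(0, upper), tol = tol)$root
}

#' Confined modulus from E and nu (forward map)
#'
#' `M = E (1 - nu) / ((1 + nu)(1 - 2 nu))`, the uniaxial-strain stiffness of
#' a laterally confined sample.
#'
#' @param E Young's modulus, Pa.
#' @param nu Poisson's ratio in [0, 0.5).
#' @return Confined compression modulus, Pa.
#' @export
confined_modulus <- function(E, nu) {
  stopifnot(E > 0, nu >= 0, nu < 0.5)
  E * (1 - nu) / ((1 + nu) * (1 - 2 * nu))
}
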