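# broom-style tidiers for field tables and fitted objects.

#' @method tidy displacement_field
#' @export
tidy.displacement_field <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x)[, c("x", "y", "z", "u1", "u2", "u3")],
                      cols = c("u1", "u2", "u3"),
                      names_to = "component", values_to = "displacement_um")
}

#' @method glance displacement_field
#' @export
glance.displacement_field <- function(x, ...) {
  ok <- x$valid
  tibble(n_points = nrow(x), n_valid = sum(ok),
         masked_fraction = mean(!ok),
         rms_magnitude_um = rms(x$magnitude[ok]),
         max_magnitude_um = if (any(ok)) max(x$magnitude[ok]) else NA_real_,
         median_peak_ratio = stats::median(x$peak_ratio[ok & is.finite(x$peak_ratio)]))
}

#' @method tidy tensor_field
#' @export
tidy.tensor_field <- function(x, ...) {
  pref <- if (identical(attr(x, "kind"), "stress")) "s" else "e"
  cols <- paste0(pref, c("11", "22", "33", "12", "13", "23"))
  tidyr::pivot_longer(as_tibble(x)[, c("x", "y", "z", cols)],
                      cols = tidyr::all_of(cols),
                      names_to = "component", values_to = "value")
}

#' @method glance tensor_field
#' @export
glance.tensor_field <- function(x, ...) {
  pref <- if (identical(attr(x, "kind"), "stress")) "s" else "e"
  cols <- paste0(pref, c("11", "22", "33", "12", "13", "23"))
  mx <- do.call(pmax, c(lapply(cols, function(cc) abs(x[[cc]])), na.rm = TRUE))
  tibble(kind = attr(x, "kind"), n_points = nrow(x),
         n_valid = sum(x$valid), rms_max_component = rms(mx[x$valid]),
         max_component = if (any(x$valid)) max(mx[x$valid]) else NA_real_)
}

#' @method tidy traction_field
#' @export
tidy.traction_field <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x)[, c("x", "y", "z", "t1", "t2", "t3")],
                      cols = c("t1", "t2", "t3"),
                      names_to = "component", values_to = "traction_pa")
}

#' @method glance traction_field
#' @export
glance.traction_field <- function(x, ...) {
  ok <- x$valid
  tibble(n_points = nrow(x), n_valid = sum(ok),
         rms_magnitude_pa = rms(x$magnitude[ok]),
         max_magnitude_pa = if (any(ok)) max(x$magnitude[ok]) else NA_real_)
}

#' @method tidy compression_fit
#' @export
tidy.compression_fit <- function(x, ...) {
  tibble(term = c("E_loading", "E_unloading", "E_free_intercept", "intercept"),
         estimate = c(x$E_loading, x$E_unloading, x$intercept_fit$E,
                      x$intercept_fit$intercept),
         std.error = c(x$se, NA_real_, NA_real_, NA_real_))
}

#' @method glance compression_fit
#' @export
glance.compression_fit <- function(x, ...) {
  tibble(E_pa = x$E, se_pa = x$se, n = x$n,
         hysteresis_pa = x$E_loading - x$E_unloading,
         anchor_origin = x$anchor_origin)
}

#' @method glance sensitivity_report
#' @export
glance.sensitivity_report <- function(x, ...) {
  tibble(displacement_rms_um = unname(x$displacement["rms"]),
         displacement_p95_um = unname(x$displacement["p95"]),
         strain_rms = unname(x$strain["rms"]),
         strain_rms_pct = 100 * unname(x$strain["rms"]),
         traction_rms_pa = unname(x$traction["rms"]),
         traction_max_pa = unname(x$traction["max"]),
         degenerate_pair = x$degenerate_pair)
}

#' @method glance balance_report
#' @export
glance.balance_report <- function(x, ...) {
  tibble(net_force_mN = sqrt(sum(x$net_force_mN^2)),
         net_moment_mN_mm = sqrt(sum(x$net_moment_mN_mm^2)),
         mean_abs_traction_Pa = x$mean_abs_traction_Pa,
         total_face_area_um2 = x$total_face_area_um2)
}
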