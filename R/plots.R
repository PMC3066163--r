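# ggplot2 views of field tables. Each plot shows a constant-depth slice:
# a magnitude heat map with an optional decimated arrow overlay, the
# standard way surface traction and displacement maps are presented.

slice_at <- function(field, z) {
  zs <- sort(unique(field$z))
  zv <- if (is.null(z)) zs[length(zs)] else zs[which.min(abs(zs - z))]
  field[abs(field$z - zv) < 1e-9 & field$valid, ]
}

#' Plot a displacement-field slice
#'
#' @param object A `displacement_field`.
#' @param z Slice depth in micrometers (default: topmost plane).
#' @param arrows Overlay in-plane displacement arrows.
#' @param arrow_scale Arrow length multiplier (plot micrometers per
#'   micrometer of displacement).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot displacement_field
#' @export
autoplot.displacement_field <- function(object, z = NULL, arrows = TRUE,
                                        arrow_scale = 5, ...) {
  sl <- slice_at(object, z)
  p <- ggplot2::ggplot(sl, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$magnitude)) +
    ggplot2::scale_fill_viridis_c(name = "|u| (µm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x1 (µm)", y = "x2 (µm)",
                  title = sprintf("Displacement magnitude, x3 = %.2f µm",
                                  sl$z[1]))
  if (arrows && nrow(sl) > 1) {
    p <- p + ggplot2::geom_segment(
      ggplot2::aes(xend = .data$x + arrow_scale * .data$u1,
                   yend = .data$y + arrow_scale * .data$u2),
      arrow = ggplot2::arrow(length = ggplot2::unit(1.2, "mm")),
      linewidth = 0.25, colour = "white")
  }
  p
}

#' Plot a traction-field slice
#'
#' @param object A `traction_field`.
#' @param z Slice depth in micrometers (default: the plane the field was
#'   evaluated on, if single-plane).
#' @param arrows Overlay in-plane traction arrows.
#' @param arrow_scale Arrow length multiplier (plot micrometers per Pa).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot traction_field
#' @export
autoplot.traction_field <- function(object, z = NULL, arrows = TRUE,
                                    arrow_scale = 0.05, ...) {
  sl <- slice_at(object, z)
  p <- ggplot2::ggplot(sl, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$magnitude)) +
    ggplot2::scale_fill_viridis_c(name = "|T| (Pa)", option = "magma") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x1 (µm)", y = "x2 (µm)",
                  title = sprintf("Traction magnitude, x3 = %.2f µm",
                                  sl$z[1]))
  if (arrows && nrow(sl) > 1) {
    p <- p + ggplot2::geom_segment(
      ggplot2::aes(xend = .data$x + arrow_scale * .data$t1,
                   yend = .data$y + arrow_scale * .data$t2),
      arrow = ggplot2::arrow(length = ggplot2::unit(1.2, "mm")),
      linewidth = 0.25, colour = "white")
  }
  p
}

#' Plot a tensor-field component slice
#'
#' @param field A strain or stress `tensor_field`.
#' @param component Component name, e.g. `"e13"` or `"s33"`.
#' @param z Slice depth in micrometers (default: topmost plane).
#' @return A ggplot object.
#' @export
plot_tensor_component <- function(field, component, z = NULL) {
  if (!component %in% names(field)) {
    abort(sprintf("component %s not present.", component),
          class = "tfm3d_parameter_error")
  }
  sl <- slice_at(field, z)
  unit <- if (identical(attr(field, "kind"), "stress")) "(Pa)" else ""
  ggplot2::ggplot(sl, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data[[component]])) +
    ggplot2::scale_fill_gradient2(name = paste(component, unit)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x1 (µm)", y = "x2 (µm)",
                  title = sprintf("%s, x3 = %.2f µm", component, sl$z[1]))
}

#' Plot a compression stress-strain record with its fitted modulus
#'
#' @param data Compression record (columns strain, stress_pa, phase).
#' @param fit Optional `compression_fit` to overlay.
#' @return A ggplot object.
#' @export
plot_compression <- function(data, fit = NULL) {
  if (!"phase" %in% names(data)) data$phase <- "loading"
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$strain,
                                          y = .data$stress_pa,
                                          colour = .data$phase)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "engineering strain", y = "engineering stress (Pa)")
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_abline(slope = fit$E, intercept = 0,
                                  linetype = 2) +
      ggplot2::labs(subtitle = sprintf("E = %.3g Pa", fit$E))
  }
  p
}
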