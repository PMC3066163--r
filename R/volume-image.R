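#' Volumetric intensity image
#'
#' Container for a 3D scalar intensity grid, the basic record produced by a
#' confocal z-stack acquisition (or the synthetic renderer). Axes follow the
#' convention x1, x2, x3 with x3 the depth axis increasing from the gel bottom
#' toward the free surface; the physical position of voxel (i, j, k) (1-based)
#' is `origin + (c(i, j, k) - 1) * voxel_size` (voxel-centre convention).
#'
#' @param intensities 3D numeric array of non-negative, finite intensities.
#' @param voxel_size Voxel edge lengths `c(dx, dy, dz)` in micrometers.
#' @param origin Physical position of voxel (1,1,1) in micrometers.
#' @param label Free-text label carried through to metadata.
#' @return A `volume_image` object.
#' @export
volume_image <- function(intensities, voxel_size, origin = c(0, 0, 0),
                         label = "") {
  if (!is.array(intensities) || length(dim(intensities)) != 3L) {
    abort("`intensities` must be a 3D array.", class = "tfm3d_parameter_error")
  }
  if (any(dim(intensities) < 2L)) {
    abort("volume must have at least 2 voxels per axis.",
          class = "tfm3d_parameter_error")
  }
  if (any(!is.finite(intensities)) || any(intensities < 0)) {
    abort("intensities must be finite and non-negative.",
          class = "tfm3d_parameter_error")
  }
  voxel_size <- check_positive3(voxel_size, "voxel_size")
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3L)
  structure(
    list(intensities = intensities, voxel_size = voxel_size,
         origin = origin, label = as.character(label)[1]),
    class = "volume_image"
  )
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<volume_image> %d x %d x %d voxels @ (%.3g, %.3g, %.3g) um/voxel\n",
              d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  extent %.4g x %.4g x %.4g um, origin (%g, %g, %g)",
              d[1] * x$voxel_size[1], d[2] * x$voxel_size[2],
              d[3] * x$voxel_size[3],
              x$origin[1], x$origin[2], x$origin[3]))
  if (nzchar(x$label)) cat("  [", x$label, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
dim.volume_image <- function(x) dim(x$intensities)

is_volume_image <- function(x) inherits(x, "volume_image")
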