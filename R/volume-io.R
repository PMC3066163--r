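#' Read a volumetric image from TIFF
#'
#' Accepts a multi-page TIFF (z as pages) or a directory of single-page TIFF
#' slices in lexicographic z-order. Voxel size is taken from the JSON sidecar
#' written by [write_volume()] (`<path>.json`), else from
#' `voxel_size_override`, else reading fails: displacements are reported in
#' micrometers, so unit metadata is mandatory.
#'
#' @param path Multi-page TIFF file or directory of per-slice TIFFs.
#' @param voxel_size_override Optional `c(dx, dy, dz)` in micrometers, used
#'   when no sidecar metadata is present.
#' @return A [volume_image()].
#' @export
read_volume <- function(path, voxel_size_override = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("file or directory not found: %s", path),
          class = "tfm3d_io_error")
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                             ignore.case = TRUE))
    if (length(files) < 2L) {
      abort(sprintf("directory %s holds fewer than 2 TIFF slices.", path),
            class = "tfm3d_io_error")
    }
    pages <- lapply(files, function(f) {
      p <- tiff::readTIFF(f, all = TRUE)
      if (length(p) != 1L) {
        abort(sprintf("slice file %s is multi-page; expected one page per slice.",
                      basename(f)), class = "tfm3d_format_error")
      }
      p[[1]]
    })
    names(pages) <- basename(files)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    names(pages) <- paste0("page ", seq_along(pages))
  }
  shp <- dim(pages[[1]])
  for (i in seq_along(pages)) {
    if (length(dim(pages[[i]])) != 2L || !identical(dim(pages[[i]]), shp)) {
      abort(sprintf("slice shape mismatch at %s: got %s, expected %s.",
                    names(pages)[i],
                    paste(dim(pages[[i]]), collapse = "x"),
                    paste(shp, collapse = "x")),
            class = "tfm3d_format_error")
    }
  }
  # readTIFF returns row = image row; store as [x, y, z] with x the first
  # (fastest) index: transpose so columns of the page run along x.
  vol <- array(0, c(shp[2], shp[1], length(pages)))
  for (k in seq_along(pages)) vol[, , k] <- t(pages[[k]])

  meta_path <- paste0(sub("/$", "", path), ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path, simplifyVector = TRUE)
  voxel_size <- meta$voxel_size_um %||% voxel_size_override
  if (is.null(voxel_size)) {
    abort("no voxel size in metadata and no `voxel_size_override` given.",
          class = "tfm3d_io_error")
  }
  scale <- meta$intensity_scale %||% 1
  volume_image(vol * scale, voxel_size,
               origin = meta$origin_um %||% c(0, 0, 0),
               label = meta$label %||% "")
}

#' Write a volumetric image as multi-page TIFF
#'
#' Intensities are stored as 16-bit samples; a JSON sidecar (`<path>.json`)
#' records the voxel size, origin, label and the intensity scale so that a
#' subsequent [read_volume()] restores the volume exactly. Volumes produced by
#' [render_volume()] are already quantized to 16-bit levels, making the
#' roundtrip bit-identical.
#'
#' @param volume A [volume_image()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(is_volume_image(volume))
  v <- volume$intensities
  scale <- max(v, 1e-300)
  if (scale <= 1) scale <- 1  # keep renderer output (already in [0,1]) as-is
  v <- v / scale
  pages <- lapply(seq_len(dim(v)[3]), function(k) t(v[, , k]))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(
    list(voxel_size_um = volume$voxel_size, origin_um = volume$origin,
         label = volume$label, intensity_scale = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
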