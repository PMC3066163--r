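# End-to-end orchestration: volumes -> displacements -> strain -> stress ->
# tractions, with a manifest recording configuration and provenance.

#' Parse a plain-text key = value configuration file
#'
#' Minimal TOML-style syntax: one `key = value` per line, `#` comments,
#' values parsed as numbers, `true`/`false`, comma-separated numeric vectors
#' or bare strings. Section headers `[name]` prefix keys as `name.key`.
#'
#' @param path Config file path.
#' @return Named list of values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config not found: %s", path),
                                class = "tfm3d_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  out <- list()
  section <- ""
  for (ln in lines[nzchar(lines)]) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    kv <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(kv) != 3) {
      abort(sprintf("cannot parse config line: %s", ln),
            class = "tfm3d_format_error")
    }
    key <- trimws(kv[2]); val <- trimws(kv[3])
    val <- gsub('^"|"$', "", val)
    parsed <- if (grepl("^(true|false)$", val, ignore.case = TRUE)) {
      tolower(val) == "true"
    } else if (grepl("^[-+0-9.eE, ]+$", val) && grepl("[0-9]", val)) {
      as.numeric(strsplit(val, ",")[[1]])
    } else val
    if (nzchar(section)) key <- paste(section, key, sep = ".")
    out[[key]] <- parsed
  }
  out
}

#' Run the full 3D TFM pipeline
#'
#' For a time series of volumetric bead images, computes for each analysis
#' pair the displacement field (DVC), displacement gradients, strain, stress
#' and the surface traction map, writes every field as CSV (optionally VTK)
#' into `out_dir`, and records a JSON manifest with the configuration,
#' package version and mask statistics. Identical configuration and inputs
#' give byte-identical outputs.
#'
#' @param volumes List of [volume_image()]s or character vector of TIFF
#'   paths (>= 2: reference plus deformed time points).
#' @param out_dir Output directory (created if needed).
#' @param config A [dvc_config()].
#' @param mat A [material()].
#' @param mode `"first_reference"` correlates every time point against the
#'   first volume (cell-free reference concept); `"consecutive"` correlates
#'   successive pairs (incremental displacements).
#' @param stencil Gradient stencil size in grid points.
#' @param surface_index Depth lattice index for the surface traction map
#'   (default: topmost valid plane).
#' @param formats Output formats, subset of `c("csv", "vtk")`.
#' @param voxel_size_override Passed to [read_volume()] for path inputs.
#' @return Invisibly, a list with the per-pair field objects and the
#'   manifest (also written to `out_dir/manifest.json`).
#' @export
run_pipeline <- function(volumes, out_dir, config = dvc_config(),
                         mat = material(E = 9640, nu = 0.5),
                         mode = c("first_reference", "consecutive"),
                         stencil = 3, surface_index = NULL,
                         formats = "csv", voxel_size_override = NULL) {
  mode <- match.arg(mode)
  if (is.character(volumes)) {
    missing <- volumes[!file.exists(volumes)]
    if (length(missing)) {
      abort(paste("input volume(s) not found:",
                  paste(missing, collapse = ", ")),
            class = "tfm3d_io_error")
    }
    volumes <- lapply(volumes, read_volume,
                      voxel_size_override = voxel_size_override)
  }
  if (length(volumes) < 2L) {
    abort("need at least 2 volumes (reference + deformed).",
          class = "tfm3d_parameter_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pairs <- if (mode == "first_reference") {
    lapply(seq.int(2L, length(volumes)), function(t) c(1L, t))
  } else {
    lapply(seq.int(2L, length(volumes)), function(t) c(t - 1L, t))
  }
  results <- vector("list", length(pairs))
  manifest_pairs <- vector("list", length(pairs))
  for (p in seq_along(pairs)) {
    ridx <- pairs[[p]][1]; didx <- pairs[[p]][2]
    tag <- sprintf("t%03d", didx)
    stage <- function(name, expr) {
      tryCatch(expr, error = function(e) {
        abort(sprintf("pipeline stage '%s' failed at time point %d: %s",
                      name, didx, conditionMessage(e)),
              class = "tfm3d_pipeline_error")
      })
    }
    t0 <- proc.time()[["elapsed"]]
    disp <- stage("dvc", compute_displacement_field(volumes[[ridx]],
                                                    volumes[[didx]], config))
    grad <- stage("gradient", estimate_displacement_gradient(disp, stencil))
    strain <- stage("strain", strain_from_gradient(grad))
    stress <- stage("stress", stress_from_strain(strain, mat))
    traction <- stage("traction", surface_traction_map(stress, surface_index))
    elapsed <- proc.time()[["elapsed"]] - t0
    mask_frac <- mean(!disp$valid)
    if (mask_frac > 0.10) {
      warn(sprintf("time point %d: %.1f%% of grid points masked.",
                   didx, 100 * mask_frac))
    }
    for (fmt in formats) {
      ext <- fmt
      write_fields(disp, file.path(out_dir, sprintf("disp_%s.%s", tag, ext)),
                   format = fmt, include_quality = TRUE)
      write_fields(strain, file.path(out_dir, sprintf("strain_%s.%s", tag, ext)),
                   format = fmt)
      write_fields(stress, file.path(out_dir, sprintf("stress_%s.%s", tag, ext)),
                   format = fmt)
      write_fields(traction,
                   file.path(out_dir, sprintf("traction_%s.%s", tag, ext)),
                   format = fmt)
    }
    results[[p]] <- list(pair = pairs[[p]], displacement = disp,
                         strain = strain, stress = stress,
                         traction = traction)
    manifest_pairs[[p]] <- list(reference = ridx, deformed = didx,
                                masked_fraction = mask_frac,
                                elapsed_s = elapsed)
  }
  manifest <- list(
    package = "tfm3d",
    version = as.character(utils::packageVersion("tfm3d")),
    mode = mode,
    config = unclass(config),
    material = unclass(mat),
    stencil = stencil,
    units = list(length = "um", stress = "Pa (= pN/um^2)"),
    n_volumes = length(volumes),
    pairs = manifest_pairs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(results = results, manifest = manifest))
}
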