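# Field tables (displacement, strain/stress, traction) are tibbles with one
# row per lattice point; x, y, z columns in micrometers come first, component
# columns follow. Symmetric tensors are stored once per component pair
# (11, 22, 33, 12, 13, 23), never duplicated.

field_component_cols <- function(field) {
  known <- list(
    displacement_field = c("u1", "u2", "u3", "magnitude"),
    tensor_field = NULL,  # resolved from kind attribute below
    traction_field = c("t1", "t2", "t3", "magnitude"),
    gradient_field = c("g11", "g12", "g13", "g21", "g22", "g23",
                       "g31", "g32", "g33", "residual")
  )
  cls <- intersect(class(field), names(known))
  if (length(cls) == 0) {
    abort("not a recognized field table.", class = "tfm3d_usage_error")
  }
  if (cls[1] == "tensor_field") {
    p <- if (identical(attr(field, "kind"), "stress")) "s" else "e"
    return(paste0(p, c("11", "22", "33", "12", "13", "23")))
  }
  known[[cls[1]]]
}

#' Write field tables to CSV or legacy VTK
#'
#' One or more fields sharing the same lattice are written to a single file.
#' CSV columns are `x, y, z` (micrometers) followed by the components of each
#' field in its own units (displacement micrometers, strain dimensionless,
#' stress/traction pascals; 1 Pa = 1 pN/um^2). VTK output is a legacy ASCII
#' STRUCTURED_POINTS dataset loadable by standard viewers; masked points are
#' written as 0 alongside a `valid` mask array.
#'
#' @param fields A single field tibble or a named list of field tibbles on a
#'   common lattice.
#' @param path Output file path.
#' @param format `"csv"` or `"vtk"`.
#' @param include_quality For CSV, also write per-point quality columns
#'   (peak ratio, flags, ...) when present.
#' @return `path`, invisibly.
#' @export
write_fields <- function(fields, path, format = c("csv", "vtk"),
                         include_quality = FALSE) {
  format <- match.arg(format)
  if (is_tibble(fields) || is.data.frame(fields)) fields <- list(fields)
  if (is.null(names(fields))) names(fields) <- paste0("field", seq_along(fields))
  key0 <- fields[[1]][, c("x", "y", "z")]
  for (f in fields) {
    if (!isTRUE(all.equal(as.data.frame(f[, c("x", "y", "z")]),
                          as.data.frame(key0), tolerance = 1e-12,
                          check.attributes = FALSE))) {
      abort("fields do not share a common grid.", class = "tfm3d_usage_error")
    }
  }
  comp <- lapply(fields, function(f) {
    cols <- field_component_cols(f)
    if (include_quality) {
      cols <- c(cols, intersect(c("peak_value", "peak_ratio", "valid", "flag",
                                  "eps_trace", "linear_range"), names(f)))
    }
    f[, cols]
  })
  out <- dplyr::bind_cols(key0, comp, .name_repair = "minimal")
  if (format == "csv") {
    readr::write_csv(out, path, progress = FALSE)
  } else {
    write_vtk_structured(out, fields, path)
  }
  invisible(path)
}

#' Read a field CSV written by [write_fields()]
#'
#' Restores the field class when the column set identifies one
#' (displacement, traction, strain or stress tensor).
#'
#' @param path CSV path.
#' @return A tibble with x, y, z and component columns.
#' @export
read_field_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  cls <- if (all(c("u1", "u2", "u3") %in% names(out))) "displacement_field"
         else if (all(c("t1", "t2", "t3") %in% names(out))) "traction_field"
         else if (all(paste0("e", c("11", "12")) %in% names(out))) "tensor_field"
         else if (all(paste0("s", c("11", "12")) %in% names(out))) "tensor_field"
  if (!is.null(cls)) {
    class(out) <- c(cls, class(out))
    if (cls == "tensor_field") {
      attr(out, "kind") <- if ("s11" %in% names(out)) "stress" else "strain"
    }
  }
  out
}

# Legacy VTK STRUCTURED_POINTS writer (ASCII). Expects a complete regular
# lattice; vector fields become VECTORS arrays, everything else SCALARS.
write_vtk_structured <- function(flat, fields, path) {
  lat <- field_lattice(flat)
  n <- prod(lat$dims)
  if (nrow(flat) != n) {
    abort("VTK output needs a complete regular lattice (every lattice point present).",
          class = "tfm3d_usage_error")
  }
  sp <- vapply(lat$axes, function(a) if (length(a) > 1) a[2] - a[1] else 1, 0)
  ord <- order(lat$index$k, lat$index$j, lat$index$i)  # x fastest for VTK
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "tfm3d field export", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", lat$dims[1], lat$dims[2], lat$dims[3]),
               sprintf("ORIGIN %.9g %.9g %.9g",
                       lat$axes$x[1], lat$axes$y[1], lat$axes$z[1]),
               sprintf("SPACING %.9g %.9g %.9g", sp[1], sp[2], sp[3]),
               sprintf("POINT_DATA %d", n)), con)
  for (nm in names(fields)) {
    f <- fields[[nm]]
    cols <- field_component_cols(f)
    dat <- as.data.frame(f[ord, cols])
    dat[is.na(dat)] <- 0
    is_vec <- identical(cols[1:3], c("u1", "u2", "u3")) ||
      identical(cols[1:3], c("t1", "t2", "t3"))
    if (is_vec) {
      writeLines(sprintf("VECTORS %s float", nm), con)
      utils::write.table(format(dat[, 1:3], scientific = TRUE, digits = 9),
                         con, row.names = FALSE, col.names = FALSE,
                         quote = FALSE)
      cols <- cols[-(1:3)]
    }
    for (cc in cols) {
      writeLines(c(sprintf("SCALARS %s_%s float 1", nm, cc),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(dat[[cc]], scientific = TRUE, digits = 9), con)
    }
  }
  if ("valid" %in% names(fields[[1]])) {
    writeLines(c("SCALARS valid int 1", "LOOKUP_TABLE default"), con)
    writeLines(as.character(as.integer(fields[[1]]$valid[ord])), con)
  }
  invisible(path)
}
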