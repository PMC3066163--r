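#!/usr/bin/env Rscript
# tfm3d command-line interface: thin wrappers over the package functions.
# Usage: tfm3d <simulate|dvc|strain|traction|noise-floor|balance|calibrate|run> [options]

suppressPackageStartupMessages({
  library(optparse)
  library(tfm3d)
})

args <- commandArgs(trailingOnly = TRUE)
cmd <- if (length(args)) args[1] else "help"
rest <- args[-1]

die <- function(msg) { message(msg); quit(status = 1) }

opt_of <- function(spec) parse_args(OptionParser(option_list = spec), rest)

mat_of <- function(opt) material(E = opt$E, nu = opt$nu)
cfg_of <- function(opt) dvc_config(subset_size = opt$subset,
                                   grid_spacing = opt$`grid-um`)
vs_of <- function(opt) if (!is.null(opt$`voxel-um`))
  as.numeric(strsplit(opt$`voxel-um`, ",")[[1]])

run_cmd <- switch(cmd,
  simulate = function() {
    opt <- opt_of(list(
      make_option("--config", type = "character", help = "scene config (key = value)"),
      make_option("--out", type = "character", default = "scene")))
    cf <- read_config(opt$config)
    dims <- as.integer(cf[["imaging.dims"]] %||% c(128, 128, 64))
    vs <- cf[["imaging.voxel_um"]] %||% c(0.35, 0.35, 0.35)
    im <- imaging_model(
      voxel_size = vs, dims = dims,
      psf_sigma = cf[["imaging.psf_um"]] %||% c(0.2, 0.2, 0.6),
      noise = list(kind = cf[["imaging.noise_kind"]] %||% "gaussian",
                   level = cf[["imaging.noise_level"]] %||% 0.05))
    pf <- generate_particle_field(
      domain = dims * vs,
      volume_fraction = cf[["scene.volume_fraction"]] %||% 0.003,
      radius = cf[["scene.radius_um"]] %||% 0.25,
      seed = cf[["scene.seed"]] %||% 1)
    map <- deformation_map(cf[["deformation.kind"]] %||% "identity",
                           t = cf[["deformation.translation_um"]] %||% c(0, 0, 0),
                           gamma = cf[["deformation.gamma"]] %||% 0)
    ref <- render_volume(pf, im, seed = (cf[["scene.seed"]] %||% 1) + 1)
    def <- render_volume(apply_deformation(pf, map), im,
                         seed = (cf[["scene.seed"]] %||% 1) + 2)
    write_volume(ref, paste0(opt$out, "_ref.tif"))
    write_volume(def, paste0(opt$out, "_def.tif"))
    pos <- cbind(pf$x, pf$y, pf$z)
    u <- map$u(pos)
    readr::write_csv(tibble::tibble(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                                    u1 = u[, 1], u2 = u[, 2], u3 = u[, 3]),
                     paste0(opt$out, "_truth.csv"), progress = FALSE)
    message("wrote ", opt$out, "_{ref,def}.tif and ground-truth CSV")
  },
  dvc = function() {
    opt <- opt_of(list(
      make_option("--ref", type = "character"),
      make_option("--def", type = "character"),
      make_option("--subset", type = "integer", default = 64),
      make_option("--grid-um", type = "double", default = 2),
      make_option("--voxel-um", type = "character", default = NULL,
                  help = "dx,dy,dz override if TIFF lacks metadata"),
      make_option("--out", type = "character", default = "disp.csv")))
    disp <- compute_displacement_field(
      read_volume(opt$ref, vs_of(opt)), read_volume(opt$def, vs_of(opt)),
      cfg_of(opt))
    write_fields(disp, opt$out, include_quality = TRUE)
    print(glance(disp))
  },
  strain = function() {
    opt <- opt_of(list(
      make_option("--disp", type = "character"),
      make_option("--stencil", type = "integer", default = 3),
      make_option("--out", type = "character", default = "strain.csv")))
    disp <- read_field_csv(opt$disp)
    if (!"valid" %in% names(disp)) disp$valid <- TRUE
    strain <- strain_from_gradient(
      estimate_displacement_gradient(disp, stencil = opt$stencil))
    write_fields(strain, opt$out)
    print(glance(strain))
  },
  traction = function() {
    opt <- opt_of(list(
      make_option("--strain", type = "character"),
      make_option("--E", type = "double", default = 9640),
      make_option("--nu", type = "double", default = 0.5),
      make_option("--normal", type = "character", default = "0,0,1"),
      make_option("--plane", type = "character", default = "z=top",
                  help = "z=top | z=<index> | all"),
      make_option("--out", type = "character", default = "traction.csv")))
    strain <- read_field_csv(opt$strain)
    if (!"valid" %in% names(strain)) strain$valid <- TRUE
    stress <- stress_from_strain(strain, mat_of(opt))
    n <- as.numeric(strsplit(opt$normal, ",")[[1]])
    tr <- if (opt$plane == "all") {
      traction_on_plane(stress, n)
    } else if (opt$plane == "z=top") {
      surface_traction_map(stress)
    } else {
      traction_on_plane(stress, n,
                        plane = list(axis = 3,
                                     index = as.integer(sub("z=", "", opt$plane))))
    }
    write_fields(tr, opt$out)
    print(glance(tr))
  },
  `noise-floor` = function() {
    opt <- opt_of(list(
      make_option("--a", type = "character"), make_option("--b", type = "character"),
      make_option("--subset", type = "integer", default = 64),
      make_option("--grid-um", type = "double", default = 2),
      make_option("--voxel-um", type = "character", default = NULL),
      make_option("--E", type = "double", default = 9640),
      make_option("--nu", type = "double", default = 0.5),
      make_option("--out", type = "character", default = "sensitivity.csv")))
    rep <- noise_floor(read_volume(opt$a, vs_of(opt)),
                       read_volume(opt$b, vs_of(opt)),
                       cfg_of(opt), mat_of(opt))
    print(rep)
    readr::write_csv(glance(rep), opt$out, progress = FALSE)
  },
  balance = function() {
    opt <- opt_of(list(
      make_option("--stress", type = "character"),
      make_option("--box", type = "character",
                  help = "i0,i1,j0,j1,k0,k1 lattice index ranges")))
    stress <- read_field_csv(opt$stress)
    b <- as.integer(strsplit(opt$box, ",")[[1]])
    rep <- force_moment_balance(stress, list(i = b[1:2], j = b[3:4], k = b[5:6]))
    print(rep)
  },
  calibrate = function() {
    opt <- opt_of(list(
      make_option("--data", type = "character",
                  help = "CSV with strain, stress_pa, phase"),
      make_option("--mode", type = "character", default = "unconfined"),
      make_option("--E", type = "double", default = NULL,
                  help = "unconfined E (Pa), needed for confined mode")))
    d <- readr::read_csv(opt$data, show_col_types = FALSE)
    fit <- young_modulus_unconfined(d)
    if (opt$mode == "unconfined") {
      print(fit)
    } else {
      if (is.null(opt$E)) die("confined mode needs --E from the unconfined test")
      nu <- poisson_from_confined_modulus(M = fit$E, E = opt$E)
      cat(sprintf("confined modulus M = %.4g Pa -> Poisson ratio nu = %.4f\n",
                  fit$E, nu))
    }
  },
  run = function() {
    opt <- opt_of(list(
      make_option("--config", type = "character", help = "pipeline config")))
    cf <- read_config(opt$config)
    res <- run_pipeline(
      volumes = cf[["volumes"]],
      out_dir = cf[["out_dir"]] %||% "tfm_out",
      config = dvc_config(subset_size = cf[["dvc.subset"]] %||% 64,
                          grid_spacing = cf[["dvc.grid_um"]] %||% 2),
      mat = material(E = cf[["material.E_pa"]] %||% 9640,
                     nu = cf[["material.nu"]] %||% 0.5),
      mode = cf[["mode"]] %||% "first_reference",
      stencil = cf[["stencil"]] %||% 3,
      voxel_size_override = cf[["voxel_um"]])
    message("pipeline complete: ", length(res$results), " pair(s)")
  },
  help = function() {
    message("usage: tfm3d <simulate|dvc|strain|traction|noise-floor|balance|calibrate|run> [--help]")
  })

if (is.null(run_cmd)) die(sprintf("unknown subcommand '%s'", cmd))
`%||%` <- function(a, b) if (is.null(a)) b else a
run_cmd()
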