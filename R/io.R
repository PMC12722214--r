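#' Write or read a NIfTI stack with a YAML sidecar
#'
#' Voxel data are stored at double precision so that the round-trip is
#' bit-exact; the sidecar records the dimensions plus arbitrary metadata
#' and is verified on read.
#'
#' @param data Numeric array (2-D map or 3-D/4-D stack). `NA` background
#'   is preserved.
#' @param path Output path (`.nii` or `.nii.gz`); the sidecar is written
#'   next to it with extension `.yaml`.
#' @param metadata Named list stored in the sidecar.
#' @return `write_nifti_stack` returns `path` invisibly;
#'   `read_nifti_stack` returns `list(data, meta)`.
#' @export
write_nifti_stack <- function(data, path, metadata = list()) {
  img <- RNifti::asNifti(data, datatype = "double")
  RNifti::writeNifti(img, path)
  side <- .sidecar_path(path)
  yaml::write_yaml(c(list(dim = as.integer(dim(data))), metadata), side,
                   precision = 15)
  invisible(path)
}

#' @rdname write_nifti_stack
#' @export
read_nifti_stack <- function(path) {
  img <- RNifti::readNifti(path)
  data <- array(as.numeric(img), dim = dim(img))
  side <- .sidecar_path(path)
  meta <- list()
  if (file.exists(side)) {
    meta <- yaml::read_yaml(side)
    sdim <- as.integer(meta$dim)
    if (prod(sdim) != length(data))
      stop("NIfTI shape ", paste(dim(data), collapse = "x"),
           " does not match its sidecar (",
           paste(sdim, collapse = "x"), ")")
    # NIfTI writers may drop trailing singleton dimensions; restore them
    data <- array(data, sdim)
    meta$dim <- NULL
  }
  list(data = data, meta = meta)
}

.sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".yaml", path)
}

#' Stable content hash of a configuration object
#'
#' MD5 digest of the canonical YAML serialization; embedded in artifacts
#' so that a re-run with an identical configuration is identifiable.
#'
#' @param x Any YAML-serializable object.
#' @return Character MD5 hash.
#' @export
config_hash <- function(x) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(x, f, precision = 15)
  unname(tools::md5sum(f))
}

#' Save or load a phantom dataset directory
#'
#' The directory holds NIfTI truth maps, the four NIfTI trajectory stacks,
#' T1/T2 maps and the vial-id image, plus a YAML metadata file (spec
#' values, noise sigma, seed, schedule hashes).
#'
#' @param phantom A [make_digital_phantom()] dataset.
#' @param dir Output directory (created if needed).
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "cest_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(phantom$truth))
    write_nifti_stack(phantom$truth[[nm]],
                      file.path(dir, paste0("truth_", nm, ".nii.gz")))
  for (pn in names(phantom$traj))
    write_nifti_stack(phantom$traj[[pn]],
                      file.path(dir, paste0("traj_", pn, ".nii.gz")))
  write_nifti_stack(phantom$t1_map, file.path(dir, "t1_map.nii.gz"))
  write_nifti_stack(phantom$t2_map, file.path(dir, "t2_map.nii.gz"))
  write_nifti_stack(phantom$vial_id + 0, file.path(dir, "vial_id.nii.gz"))
  spec <- phantom$spec
  meta <- list(amide_fractions = spec$amide_fractions,
               glu_concentrations = spec$glu_concentrations,
               mt_fractions = spec$mt_fractions,
               image_size = spec$image_size,
               vial_radius = spec$vial_radius,
               noise_sigma = phantom$noise_sigma, seed = phantom$seed,
               schedule_hash = as.list(phantom$schedule_hash),
               vial_amide = phantom$vial_amide,
               vial_glu = phantom$vial_glu)
  meta$config_hash <- config_hash(meta)
  yaml::write_yaml(meta, file.path(dir, "phantom.yaml"), precision = 15)
  invisible(dir)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "phantom.yaml"))
  truth <- lapply(stats::setNames(nm = c("f_ss", "f_amide", "glu_mM")),
                  function(nm) read_nifti_stack(
                    file.path(dir, paste0("truth_", nm, ".nii.gz")))$data)
  traj <- lapply(stats::setNames(nm = c("mt", "rnoe", "amide", "glu")),
                 function(pn) read_nifti_stack(
                   file.path(dir, paste0("traj_", pn, ".nii.gz")))$data)
  spec <- phantom_spec(as.numeric(meta$amide_fractions),
                       as.numeric(meta$glu_concentrations),
                       as.numeric(meta$mt_fractions),
                       meta$image_size, meta$vial_radius)
  structure(list(
    truth = truth, traj = traj,
    t1_map = read_nifti_stack(file.path(dir, "t1_map.nii.gz"))$data,
    t2_map = read_nifti_stack(file.path(dir, "t2_map.nii.gz"))$data,
    vial_id = matrix(as.integer(
      read_nifti_stack(file.path(dir, "vial_id.nii.gz"))$data),
      meta$image_size, meta$image_size),
    spec = spec, vial_amide = as.numeric(meta$vial_amide),
    vial_glu = as.numeric(meta$vial_glu),
    noise_sigma = meta$noise_sigma, seed = meta$seed,
    schedule_hash = unlist(meta$schedule_hash)),
    class = "cest_phantom")
}

#' Save quantified parameter maps as NIfTI
#'
#' @param quant A [run_pipeline()] result.
#' @param dir Output directory.
#' @export
write_quantmaps <- function(quant, dir) {
  stopifnot(inherits(quant, "cest_quantmaps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(quant$maps))
    write_nifti_stack(quant$maps[[nm]],
                      file.path(dir, paste0(nm, ".nii.gz")))
  invisible(dir)
}

#' Save a recovery report as CSV (and JSON when available)
#'
#' @param report A `cest_recovery_report`.
#' @param dir Output directory.
#' @export
write_recovery_report <- function(report, dir) {
  stopifnot(inherits(report, "cest_recovery_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$table, file.path(dir, "recovery.csv"),
                   row.names = FALSE)
  utils::write.csv(report$per_background,
                   file.path(dir, "recovery_per_background.csv"),
                   row.names = FALSE)
  utils::write.csv(report$vials, file.path(dir, "vial_means.csv"),
                   row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(table = report$table, per_background = report$per_background,
           seed = report$seed, noise_sigma = report$noise_sigma,
           icc_variant = report$icc_variant),
      file.path(dir, "recovery.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
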