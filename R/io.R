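# On-disk containers. Image and k-space stacks are stored as NIfTI volumes
# (offsets along the third dimension; complex k-space as paired _re/_im
# volumes) with a JSON sidecar carrying the frequency schedule, pool
# metadata, noise level and seed. Pixel coordinates are 0-based, row-major.

grid_to_list <- function(grid) {
  list(offsets_hz = grid$offsets_hz, ref_index = grid$ref_index,
       water_offset_hz = grid$water_offset_hz,
       pool_offsets_hz = grid$pool_offsets_hz)
}

grid_from_list <- function(x) {
  freq_grid(unlist(x$offsets_hz), x$ref_index, x$water_offset_hz,
            unlist(x$pool_offsets_hz %||% numeric(0)))
}

#' Write / read a k-space series
#'
#' `write_kspace` writes `<prefix>_re.nii.gz`, `<prefix>_im.nii.gz` and
#' `<prefix>_meta.json`; `read_kspace` reads them back; the round trip is
#' exact.
#'
#' @param ks a [kspace_series()].
#' @param prefix file path prefix.
#' @return `read_kspace` returns the [kspace_series()]; `write_kspace`
#'   returns `prefix` invisibly.
#' @export
write_kspace <- function(ks, prefix) {
  RNifti::writeNifti(RNifti::asNifti(Re(ks$data)),
                     paste0(prefix, "_re.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(Im(ks$data)),
                     paste0(prefix, "_im.nii.gz"))
  meta <- c(grid_to_list(ks$grid),
            list(noise_level = ks$noise_level,
                 format = "cestrecon-kspace-1"))
  seed <- ks$rng_seed
  if (length(seed) == 1L && is.numeric(seed) && !is.na(seed))
    meta$rng_seed <- seed
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_kspace
#' @export
read_kspace <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"))
  if (is.null(meta$pool_offsets_hz)) meta$pool_offsets_hz <- numeric(0)
  re <- array(as.numeric(RNifti::readNifti(paste0(prefix, "_re.nii.gz"))),
              dim(RNifti::readNifti(paste0(prefix, "_re.nii.gz"))))
  im <- array(as.numeric(RNifti::readNifti(paste0(prefix, "_im.nii.gz"))),
              dim(re))
  seed <- unlist(meta$rng_seed)
  kspace_series(array(complex(real = re, imaginary = im), dim(re)),
                grid_from_list(meta),
                noise_level = meta$noise_level %||% 0,
                rng_seed = if (length(seed) == 1L && is.numeric(seed))
                  as.integer(seed) else NA_integer_)
}

#' Write / read an amplitude image series
#'
#' `<prefix>.nii.gz` plus `<prefix>_meta.json`.
#'
#' @param images an [image_series()].
#' @param prefix file path prefix.
#' @export
write_image_series <- function(images, prefix) {
  RNifti::writeNifti(RNifti::asNifti(images$data), paste0(prefix, ".nii.gz"))
  jsonlite::write_json(c(grid_to_list(images$grid),
                         list(format = "cestrecon-images-1")),
                       paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_image_series
#' @export
read_image_series <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"))
  img <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  image_series(array(as.numeric(img), dim(img)), grid_from_list(meta))
}

#' Write a run manifest
#'
#' Records the configuration, seeds and package version needed to re-run a
#' command bit-identically.
#'
#' @param path output JSON path.
#' @param config the run configuration (any JSON-serialisable list).
#' @param seed integer seed used.
#' @param extra optional extra fields.
#' @export
write_manifest <- function(path, config, seed, extra = list()) {
  manifest <- c(list(
    package = "cestrecon",
    version = as.character(utils::packageVersion("cestrecon")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, config = config), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Write fitted Z-spectrum parameter maps
#'
#' Parameter maps as a NIfTI stack (one volume per parameter) plus a JSON
#' sidecar naming the parameters, the fixed pool centres and the model kind.
#'
#' @param result a `cest_recon`.
#' @param prefix file path prefix.
#' @export
write_zparams <- function(result, prefix) {
  maps <- zparam_maps(result)
  arr <- array(unlist(maps), c(dim(maps[[1]]), length(maps)))
  RNifti::writeNifti(RNifti::asNifti(arr), paste0(prefix, ".nii.gz"))
  jsonlite::write_json(
    list(parameters = names(maps), centers_hz = result$zfit$centers,
         model = result$zfit$model, pool_sign = result$zfit$pool_sign,
         water_center_hz = result$zfit$water_center_hz,
         format = "cestrecon-zparams-1"),
    paste0(prefix, "_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
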