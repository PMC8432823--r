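# Import/export helpers: phantom specifications as flat JSON, parameter
# maps and ROIs as NIfTI volumes.

#' Write / read a phantom specification as flat JSON
#'
#' @param spec a `phantom_spec`
#' @param path file path
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  x <- jsonlite::fromJSON(path)
  do.call(phantom_spec, x)
}

#' Export parameter maps as NIfTI volumes
#'
#' Writes `<prefix>_t2.nii` (T2 in ms, out-of-band values retained),
#' `<prefix>_a0.nii`, and `<prefix>_valid.nii` (byte mask).
#'
#' @param maps a `parameter_maps`
#' @param prefix output path prefix
#' @return invisibly, the vector of files written
#' @export
write_maps_nifti <- function(maps, prefix) {
  stopifnot(inherits(maps, "parameter_maps"))
  t2 <- maps$t2_map
  t2[!is.finite(t2)] <- 0
  files <- c(paste0(prefix, "_t2.nii"), paste0(prefix, "_a0.nii"),
             paste0(prefix, "_valid.nii"))
  RNifti::writeNifti(RNifti::asNifti(t2), files[1])
  RNifti::writeNifti(RNifti::asNifti(maps$a0_map), files[2])
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(maps$valid_mask),
                                           dim = dim(maps$valid_mask))),
                     files[3])
  invisible(files)
}

#' Export the magnitude volumes of a multi-volume image as NIfTI
#'
#' One 4D volume file with the echo dimension fourth.
#'
#' @param img an `mvimage`
#' @param path output file
#' @export
write_mvimage_nifti <- function(img, path) {
  stopifnot(inherits(img, "mvimage"))
  RNifti::writeNifti(RNifti::asNifti(abs(img$volumes)), path)
  invisible(path)
}
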