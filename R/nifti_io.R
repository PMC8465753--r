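#' Read a NIfTI volume as a mask or probability map
#'
#' The geometry (shape, spacing, voxel-to-world affine) is reconstructed
#' from the file header. Integer-valued volumes with at most two distinct
#' values load as a `binary_mask` (non-zero voxels are foreground); other
#' volumes must lie in [0, 1] and load as a `probability_map`. Non-finite
#' values and out-of-range probabilities are rejected.
#'
#' @param path path to a readable NIfTI file (.nii or .nii.gz).
#' @return a `binary_mask` or `probability_map`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read NIfTI file: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("expected a 3D NIfTI volume, got ", length(dim(arr)), " dimensions")
  if (any(!is.finite(arr)))
    stop("volume contains non-finite values: ", path)
  geom <- geometry_from_nifti(img)
  vals <- unique(as.vector(arr))
  is_int <- all(vals == round(vals))
  if (is_int && length(vals) <= 2L) {
    binary_mask(arr != 0, geom)
  } else {
    if (any(arr < 0 | arr > 1))
      stop("non-binary volume has values outside [0, 1]: ", path)
    probability_map(arr, geom)
  }
}

geometry_from_nifti <- function(img) {
  aff <- unclass(RNifti::xform(img))
  spacing <- sqrt(colSums(aff[1:3, 1:3]^2))
  volume_geometry(dim(img)[1:3], spacing, aff)
}

#' Write a mask or probability map as NIfTI
#'
#' Masks are written as unsigned 8-bit integers, probability maps as
#' 32-bit floats. The geometry's affine is stored in the sform/qform.
#'
#' @param x a `binary_mask` or `probability_map`.
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  UseMethod("write_volume")
}

#' @export
write_volume.binary_mask <- function(x, path) {
  write_nifti_array(array(as.integer(x$voxels), dim = x$geometry$shape),
                    x$geometry, path, "uint8")
}

#' @export
write_volume.probability_map <- function(x, path) {
  write_nifti_array(x$values, x$geometry, path, "float")
}

write_nifti_array <- function(arr, geometry, path, datatype) {
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, geometry$spacing)
  img <- RNifti::`sform<-`(img, structure(geometry$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
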