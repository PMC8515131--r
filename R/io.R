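#' Read a 3D volume from NIfTI
#'
#' Axis convention throughout the package: array index 1 is the slice, 2 the
#' row (anterior to posterior), 3 the column (left to right).  Voxel spacing
#' is taken from the NIfTI pixdim.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return List with `volume` (3D numeric array) and `spacing` (mm).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D volume, got ", length(dim(img)), "D: ", path)
  sp <- RNifti::pixdim(img)[seq_len(3)]
  list(volume = array(as.numeric(img), dim = dim(img)), spacing = sp)
}

#' Write a volume or mask to NIfTI
#'
#' Masks are stored as uint8 (0/1); volumes as float.  The affine encodes
#' the voxel spacing.
#'
#' @param x 3D numeric or logical array.
#' @param path output path (`.nii.gz`).
#' @param spacing voxel spacing in mm.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, spacing = c(1, 1, 1)) {
  datatype <- if (is.logical(x)) "uint8" else "float"
  arr <- if (is.logical(x)) array(as.integer(x), dim(x)) else x
  attr(arr, "pixdim") <- spacing
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = datatype), path)
  invisible(path)
}

#' @rdname write_volume
#' @export
write_mask <- function(x, path, spacing = c(1, 1, 1)) {
  write_volume(as.logical(x) | array(FALSE, dim(x)), path, spacing)
}

#' Read a mask written by [write_mask()]
#'
#' @param path NIfTI path.
#' @return List with `mask` (logical array) and `spacing`.
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  list(mask = array(v$volume != 0, dim(v$volume)), spacing = v$spacing)
}
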