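#' Read a label volume from NIfTI
#'
#' Reads a .nii/.nii.gz file, normalises it to a canonical RAS axis order
#' where the image carries a usable orientation transform, and validates the
#' 0-5 label scheme. Non-integer voxel data or out-of-scheme labels raise an
#' error naming the offending value.
#'
#' @param path Path to a NIfTI file.
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  img <- .canonicalise(img)
  orient <- .orientation_tag(img)
  arr <- array(as.vector(img), dim = dim(img))
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 3L)
    stop("expected a 3D label image")
  label_volume(arr, RNifti::pixdim(img)[1:3], orient)
}

#' Write a label volume to NIfTI
#'
#' @param vol A [label_volume()].
#' @param path Output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  img <- RNifti::asNifti(vol$grid)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' Read a six-channel probability volume from NIfTI
#'
#' @param path Path to a 4D NIfTI file with 6 class channels.
#' @return A [prob_volume()].
#' @export
read_prob_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  arr <- array(as.vector(img), dim = dim(img))
  if (length(dim(arr)) != 4L)
    stop("expected a 4D probability image (x, y, z, class)")
  prob_volume(arr, RNifti::pixdim(img)[1:3], .orientation_tag(img))
}

#' Write a probability volume to NIfTI
#'
#' @param pv A [prob_volume()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prob_volume <- function(pv, path) {
  stopifnot(inherits(pv, "prob_volume"))
  img <- RNifti::asNifti(pv$channels)
  RNifti::pixdim(img) <- c(pv$spacing, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Reorient to RAS when the header carries a usable transform; images without
# qform/sform are passed through unchanged.
.canonicalise <- function(img) {
  tryCatch(suppressWarnings({
    if (!is.na(.orientation_tag(img)) && .orientation_tag(img) != "RAS")
      RNifti::orientation(img) <- "RAS"
    img
  }), error = function(e) img)
}

.orientation_tag <- function(img) {
  tryCatch(suppressWarnings(RNifti::orientation(img)),
           error = function(e) NA_character_)
}
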