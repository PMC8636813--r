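#' Read and write label volumes as NIfTI
#'
#' Volumes are stored as NIfTI-1 (`.nii` or `.nii.gz`) with the axis-aligned
#' affine implied by `origin` and `spacing`; the affine in the file header
#' is the single source of orientation truth on read. Label images must
#' hold integer codes; [read_label_volume()] rejects non-integer data.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param volume A [label_volume()].
#' @return `read_label_volume()` returns a [label_volume()];
#'   `write_label_volume()` returns `path` invisibly.
#' @export
read_label_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) abort("expected a 3D NIfTI volume.")
  if (max(abs(arr - round(arr))) > 1e-6) {
    abort("volume holds non-integer values: not a label image.")
  }
  x <- RNifti::xform(img)
  spacing <- sqrt(colSums(x[1:3, 1:3]^2))
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("missing or invalid voxel spacing in the NIfTI header.")
  }
  origin <- x[1:3, 4]
  label_volume(array(as.integer(round(arr)), dim(arr)), spacing, origin)
}

#' @rdname read_label_volume
#' @export
write_label_volume <- function(volume, path) {
  if (!inherits(volume, "label_volume")) abort("`volume` must be a label_volume.")
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  aff <- diag(4)
  diag(aff)[1:3] <- volume$spacing
  aff[1:3, 4] <- volume$origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Landmark and transform JSON round trips
#'
#' Landmarks (AC, PC, midsagittal point; world mm) and rigid transforms
#' (rotation matrix + translation) serialize to plain JSON.
#'
#' @param landmarks A [landmark_set()].
#' @param transform A [rigid_transform()].
#' @param path JSON file path.
#' @return Readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(
    list(ac = landmarks$ac, pc = landmarks$pc,
         midsagittal = landmarks$midsagittal),
    path, digits = NA, auto_unbox = FALSE
  )
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  landmark_set(x$ac, x$pc, x$midsagittal)
}

#' @rdname write_landmarks
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(
    list(rotation = transform$rotation, translation = transform$translation),
    path, digits = NA, matrix = "rowmajor"
  )
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(x$rotation, x$translation)
}
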