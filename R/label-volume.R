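#' Construct a labelled 3D volume
#'
#' A `label_volume` is the raw imaging object all geometry reads: a 3D
#' integer array of label codes on an axis-aligned grid, together with its
#' voxel spacing and the world coordinate of the first voxel centre. World
#' coordinates are millimetres in a RAS-like frame (+x right, +y anterior,
#' +z superior); the world position of voxel `(i, j, k)` is
#' `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param data 3D array of integer label codes.
#' @param spacing Numeric length-3, voxel spacing in mm (all > 0).
#' @param origin Numeric length-3, world position (mm) of the centre of
#'   voxel `(1, 1, 1)`.
#' @param labels Named integer vector mapping tissue names to codes.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, spacing, origin = c(0, 0, 0),
                         labels = VM_LABELS) {
  if (length(dim(data)) != 3L) abort("`data` must be a 3D array.")
  if (any(data != round(data))) abort("label volumes must hold integer codes.")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be 3 positive values (mm).")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    abort("`origin` must be 3 finite values (mm).")
  }
  storage.mode(data) <- "integer"
  structure(
    list(data = data, spacing = spacing, origin = origin, labels = labels),
    class = "label_volume"
  )
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<label_volume> %d x %d x %d voxels, spacing %s mm\n",
    d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")
  ))
  counts <- table(x$data)
  nm <- names(x$labels)[match(names(counts), as.character(x$labels))]
  nm[is.na(nm)] <- names(counts)[is.na(nm)]
  cat("  voxel counts:", paste(sprintf("%s=%s", nm, counts), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.label_volume <- function(x) dim(x$data)

# World coordinates of voxel centres along one axis (1 = x, 2 = y, 3 = z).
axis_coords <- function(vol, axis) {
  vol$origin[axis] + (seq_len(dim(vol$data)[axis]) - 1) * vol$spacing[axis]
}

# World coordinates (n x 3) of voxel index rows (n x 3).
index_to_world <- function(vol, idx) {
  sweep(sweep(idx - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

label_code <- function(vol, what) {
  code <- vol$labels[[what]]
  if (is.null(code)) abort(sprintf("volume has no '%s' label code.", what))
  code
}

# Logical mask for one or more tissue names.
tissue_mask <- function(vol, what) {
  codes <- vapply(what, function(w) label_code(vol, w), integer(1))
  array(vol$data %in% codes, dim = dim(vol$data))
}
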