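#' Ventricular volume by voxel counting
#'
#' Counts voxels carrying `label` and converts exactly to cm^3:
#' `volume_cm3 = voxel_count * voxel_volume_mm3 / 1000`.
#'
#' @param volume A [label_volume()].
#' @param label Label code to count (default: the ventricle code).
#' @return A `volume_report`: `voxel_count`, `voxel_volume_mm3`,
#'   `volume_cm3`, `label`.
#' @export
ventricular_volume <- function(volume, label = NULL) {
  if (!inherits(volume, "label_volume")) abort("`volume` must be a label_volume.")
  label <- label %||% label_code(volume, "ventricle")
  count <- sum(volume$data == label)
  if (count == 0L) {
    warn(sprintf("label %d absent from the volume: zero-volume report.", label))
  }
  vv <- prod(volume$spacing)
  structure(
    list(voxel_count = count, voxel_volume_mm3 = vv,
         volume_cm3 = count * vv / 1000, label = as.integer(label)),
    class = "volume_report"
  )
}

#' @export
print.volume_report <- function(x, ...) {
  cat(sprintf("<volume_report> label %d: %d voxels x %.3f mm^3 = %.3f cm^3\n",
              x$label, x$voxel_count, x$voxel_volume_mm3, x$volume_cm3))
  invisible(x)
}

#' @method tidy volume_report
#' @export
tidy.volume_report <- function(x, ...) {
  tibble(label = x$label, voxel_count = x$voxel_count,
         voxel_volume_mm3 = x$voxel_volume_mm3, volume_cm3 = x$volume_cm3)
}

#' Threshold-and-connectivity segmentation
#'
#' Selects voxels with intensity strictly below `threshold` that are
#' 26-connected to the seed. This is a deliberately simple segmenter for
#' exercising the intensity-to-mask-to-volume path on phantom images
#' (CSF is darker than brain on T1); it is not a clinical ventricle
#' segmenter.
#'
#' @param intensity An intensity volume (a [label_volume()]-shaped object
#'   with numeric data), e.g. `make_phantom(spec)$intensity`.
#' @param threshold Upper intensity bound (exclusive).
#' @param seed World coordinate (mm, length 3) of a point inside the
#'   intended region.
#' @return A [label_volume()] mask (1 inside the segmented component,
#'   0 elsewhere).
#' @export
segment_by_threshold <- function(intensity, threshold, seed) {
  if (!inherits(intensity, "label_volume")) {
    abort("`intensity` must be a volume object.")
  }
  arr <- intensity$data
  if (threshold <= min(arr)) {
    abort("threshold is at or below the minimum intensity: nothing to segment.")
  }
  dims <- dim(arr)
  si <- round((as.numeric(seed) - intensity$origin) / intensity$spacing) + 1
  if (any(si < 1) || any(si > dims)) abort("seed point lies outside the volume.")
  if (arr[si[1], si[2], si[3]] >= threshold) {
    abort("seed voxel intensity is not below the threshold.")
  }

  below <- arr < threshold
  visited <- array(FALSE, dims)
  # 26-connected flood fill, frontier-at-a-time on linear indices
  nbr <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nbr <- nbr[rowSums(abs(nbr)) > 0, ]
  offsets <- nbr[, 1] + nbr[, 2] * dims[1] + nbr[, 3] * dims[1] * dims[2]
  ii <- function(lin) ((lin - 1) %% dims[1]) + 1           # x index
  jj <- function(lin) ((lin - 1) %/% dims[1]) %% dims[2] + 1 # y index
  seed_lin <- si[1] + (si[2] - 1) * dims[1] + (si[3] - 1) * dims[1] * dims[2]
  visited[seed_lin] <- TRUE
  frontier <- seed_lin
  n_tot <- prod(dims)
  while (length(frontier) > 0) {
    cand <- rep(frontier, each = nrow(nbr)) + rep(offsets, times = length(frontier))
    # guard against wrapping across the x/y faces
    xi <- rep(ii(frontier), each = nrow(nbr)) + rep(nbr[, 1], times = length(frontier))
    yi <- rep(jj(frontier), each = nrow(nbr)) + rep(nbr[, 2], times = length(frontier))
    keep <- cand >= 1 & cand <= n_tot & xi >= 1 & xi <= dims[1] &
      yi >= 1 & yi <= dims[2]
    cand <- unique(cand[keep])
    cand <- cand[below[cand] & !visited[cand]]
    visited[cand] <- TRUE
    frontier <- cand
  }
  label_volume(array(as.integer(visited), dims), intensity$spacing,
               intensity$origin, labels = c(background = 0L, segment = 1L))
}
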