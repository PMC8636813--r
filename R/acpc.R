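#' Rigid transforms and ACPC realignment
#'
#' The canonical ACPC frame places the anterior commissure (AC) at the
#' origin, the posterior commissure (PC) at `(0, -d, 0)` with
#' `d = |AC - PC|`, the midsagittal plane at `x = 0`, and +z superior.
#' [compute_acpc_transform()] estimates the rigid map from three landmarks;
#' [resample_labels()] applies it to a label volume by nearest-neighbour
#' interpolation so label images stay integer.
#'
#' @param rotation 3x3 rotation matrix (orthonormal, determinant +1).
#' @param translation Length-3 translation (mm). The transform maps a world
#'   point `p` to `rotation %*% p + translation`.
#' @return `rigid_transform()` returns an object of class `rigid_transform`.
#' @name acpc
NULL

#' @rdname acpc
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  if (length(translation) != 3L) abort("`translation` must have length 3.")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8) {
    abort("`rotation` must be orthonormal.")
  }
  if (det(rotation) < 0) {
    abort("`rotation` must be proper (determinant +1), not a reflection.")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n  rotation:\n")
  print(round(x$rotation, 6))
  cat("  translation:", paste(round(x$translation, 4), collapse = ", "), "mm\n")
  invisible(x)
}

#' Apply, invert and compose rigid transforms
#'
#' @param transform,a,b [rigid_transform()] objects.
#' @param points Numeric length-3 vector or n x 3 matrix of world points (mm).
#' @return Transformed points, the inverse transform, or the composition
#'   `a` after `b` (i.e. `compose_transforms(a, b)` maps `p` to `a(b(p))`).
#' @export
transform_points <- function(transform, points) {
  p <- if (is.null(dim(points))) matrix(points, 1, 3) else as.matrix(points)
  out <- sweep(p %*% t(transform$rotation), 2, transform$translation, "+")
  if (is.null(dim(points))) drop(out) else out
}

#' @rdname transform_points
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -drop(Rt %*% transform$translation))
}

#' @rdname transform_points
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  drop(a$rotation %*% b$translation) + a$translation)
}

#' Construct an AC/PC/midsagittal landmark set
#'
#' @param ac,pc World coordinates (mm) of the anterior and posterior
#'   commissures.
#' @param midsagittal A third point on the midsagittal plane, superior to
#'   the ACPC line (used to fix the roll of the canonical frame); must not
#'   be collinear with the AC-PC line.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(ac, pc, midsagittal) {
  ac <- as.numeric(ac); pc <- as.numeric(pc); midsagittal <- as.numeric(midsagittal)
  if (any(lengths(list(ac, pc, midsagittal)) != 3L)) {
    abort("landmarks must be length-3 world coordinates (mm).")
  }
  d <- sqrt(sum((ac - pc)^2))
  if (d < 1e-9) abort("AC and PC coincide.")
  u <- (pc - ac) / d
  v <- midsagittal - ac
  if (sqrt(sum((v - sum(v * u) * u)^2)) < 1e-6) {
    abort("midsagittal point is collinear with the AC-PC line.")
  }
  structure(list(ac = ac, pc = pc, midsagittal = midsagittal, acpc_mm = d),
            class = "landmark_set")
}

#' Estimate the rigid ACPC realignment from landmarks
#'
#' Builds the rotation + translation that maps the AC to the origin, the
#' AC-to-PC direction to -y, and the midsagittal point into the `x = 0`
#' half-plane with positive z.
#'
#' @param landmarks A [landmark_set()].
#' @return A [rigid_transform()].
#' @export
compute_acpc_transform <- function(landmarks) {
  if (!inherits(landmarks, "landmark_set")) {
    landmarks <- do.call(landmark_set, landmarks[c("ac", "pc", "midsagittal")])
  }
  ac <- landmarks$ac
  ey <- (ac - landmarks$pc) / landmarks$acpc_mm      # +y is the PC-to-AC direction
  v <- landmarks$midsagittal - ac
  ez <- v - sum(v * ey) * ey
  ez <- ez / sqrt(sum(ez^2))
  ex <- c(ey[2] * ez[3] - ey[3] * ez[2],
          ey[3] * ez[1] - ey[1] * ez[3],
          ey[1] * ez[2] - ey[2] * ez[1])             # ex = ey x ez (right-handed)
  R <- rbind(ex, ey, ez)
  dimnames(R) <- NULL
  rigid_transform(R, -drop(R %*% ac))
}

#' Resample a label volume into the canonical ACPC frame
#'
#' Nearest-neighbour resampling of a [label_volume()] under a rigid
#' transform. The output grid covers the transformed bounding box of all
#' non-background voxels plus a one-voxel margin; no new labels can appear.
#'
#' @param volume A [label_volume()].
#' @param transform A [rigid_transform()] mapping input world coordinates to
#'   canonical ACPC coordinates (e.g. from [compute_acpc_transform()]).
#' @param spacing Output voxel spacing (mm), scalar or length-3; defaults to
#'   the input spacing.
#' @param acpc_mm Optional AC-PC distance to attach to the result (set
#'   automatically by [align_volume()]).
#' @return A `label_volume` that is also an `acpc_volume`.
#' @export
resample_labels <- function(volume, transform, spacing = NULL, acpc_mm = NULL) {
  if (!inherits(volume, "label_volume")) abort("`volume` must be a label_volume.")
  spacing <- as.numeric(spacing %||% volume$spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    abort("output `spacing` must be positive.")
  }

  idx <- which(volume$data != 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) abort("empty cranium mask: volume has no non-background voxels.")
  # transformed bounding box of the occupied corners
  rng <- apply(idx, 2, range)
  corners <- as.matrix(expand.grid(rng[, 1], rng[, 2], rng[, 3]))
  wc <- transform_points(transform, index_to_world(volume, corners))
  lo <- apply(wc, 2, min) - spacing
  hi <- apply(wc, 2, max) + spacing
  origin <- (floor(lo / spacing) + 0.5) * spacing    # half-spacing lattice
  dims <- pmax(ceiling((hi - origin) / spacing) + 1, 1)

  inv <- invert_transform(transform)
  n <- prod(dims)
  W <- grid_coord_vectors(origin, spacing, dims)
  P <- apply_rigid_vec(inv, W$x, W$y, W$z)
  ii <- round((P$x - volume$origin[1]) / volume$spacing[1]) + 1
  jj <- round((P$y - volume$origin[2]) / volume$spacing[2]) + 1
  kk <- round((P$z - volume$origin[3]) / volume$spacing[3]) + 1
  dv <- dim(volume$data)
  ok <- ii >= 1 & ii <= dv[1] & jj >= 1 & jj <= dv[2] & kk >= 1 & kk <= dv[3]
  lab <- integer(n)
  lab[ok] <- volume$data[cbind(ii[ok], jj[ok], kk[ok])]

  out <- label_volume(array(lab, dims), spacing, origin, labels = volume$labels)
  if (!is.null(acpc_mm)) {
    out$acpc_mm <- acpc_mm
    class(out) <- c("acpc_volume", class(out))
  }
  out
}

#' Align a label volume to the ACPC frame from landmarks
#'
#' Convenience wrapper: estimates the ACPC transform from `landmarks` and
#' resamples `volume` into the canonical frame.
#'
#' @inheritParams resample_labels
#' @param landmarks A [landmark_set()] in the volume's world coordinates.
#' @return An `acpc_volume` (a [label_volume()] carrying the AC-PC
#'   distance), ready for the morphometry functions.
#' @export
align_volume <- function(volume, landmarks, spacing = NULL) {
  if (!inherits(landmarks, "landmark_set")) {
    landmarks <- do.call(landmark_set, landmarks[c("ac", "pc", "midsagittal")])
  }
  tf <- compute_acpc_transform(landmarks)
  resample_labels(volume, tf, spacing = spacing, acpc_mm = landmarks$acpc_mm)
}

# Componentwise rigid map on coordinate vectors (avoids forming an n x 3
# matrix; these run over multi-million-voxel grids).
apply_rigid_vec <- function(transform, wx, wy, wz) {
  R <- transform$rotation
  t <- transform$translation
  list(
    x = R[1, 1] * wx + R[1, 2] * wy + R[1, 3] * wz + t[1],
    y = R[2, 1] * wx + R[2, 2] * wy + R[2, 3] * wz + t[2],
    z = R[3, 1] * wx + R[3, 2] * wy + R[3, 3] * wz + t[3]
  )
}

# Full-grid voxel-centre coordinates as three vectors in column-major order.
grid_coord_vectors <- function(origin, spacing, dims) {
  xs <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(dims[3]) - 1) * spacing[3]
  list(
    x = rep(xs, times = dims[2] * dims[3]),
    y = rep(rep(ys, each = dims[1]), times = dims[3]),
    z = rep(zs, each = dims[1] * dims[2])
  )
}

# Mark a volume already laid out in the canonical frame as aligned.
as_acpc_volume <- function(volume, acpc_mm) {
  volume$acpc_mm <- acpc_mm
  if (!inherits(volume, "acpc_volume")) {
    class(volume) <- c("acpc_volume", class(volume))
  }
  volume
}
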