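#' Voxelize a phantom specification
#'
#' Renders a [phantom_spec()] into a labelled volume (codes: 0 background,
#' 1 brain, 2 ventricle, 3 cranium shell), a T1-like intensity image
#' (background 0, CSF 100, shell 400, brain 600), the AC/PC/midsagittal
#' landmarks in world coordinates, and the closed-form [analytic_truth()].
#' The spec's `pose` is applied to the geometry before voxelization, so the
#' exported volume is the phantom "as scanned"; the grid is snapped to a
#' half-spacing lattice so that identity-pose phantoms with integer
#' dimensions voxelize exactly.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom` with elements `labels`
#'   ([label_volume()]), `intensity` (numeric volume, same grid),
#'   `landmarks` ([landmark_set()]), `truth` ([analytic_truth()]) and `spec`.
#' @export
make_phantom <- function(spec) {
  validate_phantom_spec(spec)
  lay <- phantom_layout(spec)
  hw <- spec$cranium_halfwidths
  t_sh <- spec$shell_mm
  sp <- spec$spacing_mm
  pose <- spec$pose

  # world-frame grid covering the posed outer shell, half-spacing lattice
  corners <- as.matrix(expand.grid(
    lay$centre[1] + c(-1, 1) * (hw[1] + t_sh),
    lay$centre[2] + c(-1, 1) * (hw[2] + t_sh),
    lay$centre[3] + c(-1, 1) * (hw[3] + t_sh)
  ))
  wc <- transform_points(pose, corners)
  lo <- apply(wc, 2, min) - sp
  hi <- apply(wc, 2, max) + sp
  origin <- (floor(lo / sp) + 0.5) * sp
  dims <- pmax(ceiling((hi - origin) / sp) + 1, 2)

  W <- grid_coord_vectors(origin, sp, dims)
  P <- apply_rigid_vec(invert_transform(pose), W$x, W$y, W$z) # phantom frame
  px <- P$x; py <- P$y; pz <- P$z

  dxc <- px - lay$centre[1]
  dyc <- py - lay$centre[2]
  dzc <- pz - lay$centre[3]
  if (spec$cranium_shape == "box") {
    interior <- abs(dxc) <= hw[1] & abs(dyc) <= hw[2] & abs(dzc) <= hw[3]
    outer <- abs(dxc) <= hw[1] + t_sh & abs(dyc) <= hw[2] + t_sh &
      abs(dzc) <= hw[3] + t_sh
  } else {
    interior <- (dxc / hw[1])^2 + (dyc / hw[2])^2 + (dzc / hw[3])^2 <= 1
    outer <- (dxc / (hw[1] + t_sh))^2 + (dyc / (hw[2] + t_sh))^2 +
      (dzc / (hw[3] + t_sh))^2 <= 1
  }

  if (spec$ventricle_shape == "ellipsoid") {
    vent <- (px / lay$vx)^2 + ((py - lay$y_vc) / lay$vy)^2 + (pz / lay$vz)^2 <= 1
  } else {
    s <- if (spec$ventricle_shape == "box") 0 else spec$roof_slope_s
    tilt <- if (spec$ventricle_shape == "box") 0 else spec$roof_tilt
    ax <- abs(px)
    horn <- ax <= spec$horn_width_mm / 2 & py > 0 & py <= lay$y_ant &
      pz >= lay$z_bot & pz <= lay$horn_top
    body <- ax <= lay$x_out & py <= 0 & py >= lay$y_post &
      pz >= lay$z_bot & pz <= lay$z_peak + tilt * (py + lay$d) - s * ax
    vent <- horn | body
  }

  lab <- integer(length(px))
  lab[outer] <- VM_LABELS[["shell"]]
  lab[interior] <- VM_LABELS[["brain"]]
  lab[vent & interior] <- VM_LABELS[["ventricle"]]
  labels <- label_volume(array(lab, dims), sp, origin)

  lut <- c(VM_INTENSITY[["background"]], VM_INTENSITY[["brain"]],
           VM_INTENSITY[["ventricle"]], VM_INTENSITY[["shell"]])
  intensity <- labels
  intensity$data <- array(lut[lab + 1L], dims)
  class(intensity) <- c("intensity_volume", "label_volume")

  lm <- landmark_set(
    ac = transform_points(pose, c(0, 0, 0)),
    pc = transform_points(pose, c(0, -lay$d, 0)),
    midsagittal = transform_points(pose, c(0, 0, 40))
  )

  structure(
    list(labels = labels, intensity = intensity, landmarks = lm,
         truth = analytic_truth(spec), spec = spec),
    class = "phantom"
  )
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf(
    "<phantom> %s cranium, %s ventricle, spacing %s mm\n",
    x$spec$cranium_shape, x$spec$ventricle_shape,
    paste(signif(x$spec$spacing_mm, 3), collapse = "x")
  ))
  tr <- x$truth
  cat(sprintf(
    "  truth: EI %.3f, BCI %.3f, z-Evans %.3f, CA %s, BVR(AC) %.3f, BVR(PC) %.3f, vol %.1f cm^3\n",
    tr$ei, tr$bci, tr$z_evans,
    if (is.na(tr$ca_deg)) "NA" else sprintf("%.1f deg", tr$ca_deg),
    tr$bvr_ac, tr$bvr_pc, tr$ventricle_volume_cm3
  ))
  invisible(x)
}

#' Align a phantom with its own landmarks
#'
#' Shortcut for [align_volume()] on a phantom's label volume using its
#' exported landmarks; undoes the spec's pose up to voxelization error.
#'
#' @param phantom A [make_phantom()] result.
#' @param spacing Output spacing (default: the phantom's own).
#' @return An `acpc_volume`.
#' @export
align_phantom <- function(phantom, spacing = NULL) {
  align_volume(phantom$labels, phantom$landmarks, spacing = spacing)
}

#' @method tidy analytic_truth
#' @export
tidy.analytic_truth <- function(x, ...) {
  tibble(
    index = c("ei", "bci", "z_evans", "ca_deg", "bvr_ac", "bvr_pc"),
    value = c(x$ei, x$bci, x$z_evans, x$ca_deg, x$bvr_ac, x$bvr_pc)
  )
}

#' @method glance analytic_truth
#' @export
glance.analytic_truth <- function(x, ...) {
  tibble(
    ei = x$ei, bci = x$bci, ca_deg = x$ca_deg, z_evans = x$z_evans,
    bvr_ac = x$bvr_ac, bvr_pc = x$bvr_pc,
    ventricle_volume_cm3 = x$ventricle_volume_cm3
  )
}
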