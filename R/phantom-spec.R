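#' Specify a synthetic brain phantom with analytically known morphometry
#'
#' A phantom is a simplified head model laid out directly in the canonical
#' ACPC frame (AC at the origin, PC at `(0, -acpc_mm, 0)`, midsagittal plane
#' `x = 0`, +z superior): a cranium interior (axis-aligned box or ellipsoid)
#' filled with brain, a bilaterally symmetric ventricular system carved out
#' of it, and a thin cranium shell. Every measured extent is an explicit
#' parameter, so all six linear indices and the ventricular volume are known
#' in closed form before voxelization (see [analytic_truth()]).
#'
#' The ventricular system has two parts sharing a common floor:
#' frontal horns (a block anterior to the AC, `y` in `[0, horn_anterior_extent_mm]`,
#' full width `horn_width_mm`, height `horn_zextent_mm`) and a body
#' spanning `y` from `-acpc_mm - horn_posterior_extent_mm` to 0 with outer
#' width `body_width_mm` and apex height `body_height_mm`. For
#' `ventricle_shape = "wedge_roof"` the body carries a symmetric tent roof
#' `z(x, y) = z_apex + roof_tilt * (y + acpc_mm) - roof_slope_s * |x|`
#' (highest at the midline, like the ventricular roofs under the corpus
#' callosum, and rising gently toward the front), which fixes the callosal
#' angle at the PC level at `180 - 2*atan(roof_slope_s)` degrees; `"box"`
#' is the flat-roof special case (degenerate for the callosal angle);
#' `"ellipsoid"` replaces the whole system by a single midline ellipsoid.
#'
#' @param cranium_halfwidths Semi-extents (mm, x/y/z) of the cranium
#'   interior (brain + ventricle region).
#' @param cranium_shape `"box"` or `"ellipsoid"`.
#' @param ventricle_shape `"wedge_roof"`, `"box"`, or `"ellipsoid"`.
#' @param horn_width_mm Full x-width of the frontal horns (Evans index
#'   numerator by construction).
#' @param horn_zextent_mm Vertical extent of the frontal horns (z-Evans
#'   numerator by construction).
#' @param horn_anterior_extent_mm How far the horns reach anterior to the AC.
#' @param horn_posterior_extent_mm How far the ventricle body reaches
#'   posterior to the PC.
#' @param body_width_mm Outer x-extent of the ventricle body (bicaudate
#'   numerator by construction).
#' @param body_height_mm Ventricle apex height at the PC level (BVR-at-PC
#'   "Ventricle" component by construction).
#' @param roof_slope_s Tent-roof slope |dz/dx| (`wedge_roof` only;
#'   must be >= 0).
#' @param roof_tilt Gentle anterior rise of the body roof (dz/dy,
#'   dimensionless; `wedge_roof` only). The apex height at the PC level is
#'   `body_height_mm` regardless of the tilt.
#' @param brain_above_ventricle_mm Distance from the horn roof to the top
#'   plane of the cranium interior at the midline.
#' @param acpc_mm AC-PC distance (mm).
#' @param spacing_mm Voxel spacing (mm), scalar or length-3.
#' @param shell_mm Cranium shell thickness (mm).
#' @param pose Optional rigid pose (see [rigid_transform()]) applied to the
#'   phantom before export; default identity.
#' @param validate_margin Required clearance (mm) between the ventricle and
#'   the cranium interior surface.
#' @return An object of class `phantom_spec`.
#' @seealso [make_phantom()], [analytic_truth()], [random_phantom_spec()]
#' @export
phantom_spec <- function(cranium_halfwidths = c(65, 75, 60),
                         cranium_shape = c("box", "ellipsoid"),
                         ventricle_shape = c("wedge_roof", "box", "ellipsoid"),
                         horn_width_mm = 55,
                         horn_zextent_mm = 42,
                         horn_anterior_extent_mm = 32,
                         horn_posterior_extent_mm = 14,
                         body_width_mm = 46,
                         body_height_mm = 34,
                         roof_slope_s = 0.5,
                         roof_tilt = 0.25,
                         brain_above_ventricle_mm = 20,
                         acpc_mm = 25,
                         spacing_mm = c(1, 1, 1),
                         shell_mm = 4,
                         pose = NULL,
                         validate_margin = 2) {
  cranium_shape <- match.arg(cranium_shape)
  ventricle_shape <- match.arg(ventricle_shape)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)

  spec <- structure(
    list(
      cranium_halfwidths = as.numeric(cranium_halfwidths),
      cranium_shape = cranium_shape,
      ventricle_shape = ventricle_shape,
      horn_width_mm = horn_width_mm,
      horn_zextent_mm = horn_zextent_mm,
      horn_anterior_extent_mm = horn_anterior_extent_mm,
      horn_posterior_extent_mm = horn_posterior_extent_mm,
      body_width_mm = body_width_mm,
      body_height_mm = body_height_mm,
      roof_slope_s = roof_slope_s,
      roof_tilt = roof_tilt,
      brain_above_ventricle_mm = brain_above_ventricle_mm,
      acpc_mm = acpc_mm,
      spacing_mm = as.numeric(spacing_mm),
      shell_mm = shell_mm,
      pose = pose %||% rigid_transform(diag(3), c(0, 0, 0))
    ),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec, margin = validate_margin)
  spec
}

# Internal geometric layout shared by truth and voxelizer. All coordinates
# in the phantom's own ACPC frame.
phantom_layout <- function(spec) {
  d <- spec$acpc_mm
  hze <- spec$horn_zextent_mm
  bh <- spec$body_height_mm
  z_bot <- -bh / 2
  horn_top <- z_bot + hze
  x_out <- spec$body_width_mm / 2
  z_peak <- z_bot + bh                       # apex height at the PC level
  z_sh <- z_peak - spec$roof_slope_s * x_out # shoulder height at the PC level
  hw <- spec$cranium_halfwidths
  centre <- c(0, -d / 2, horn_top + spec$brain_above_ventricle_mm - hw[3])
  lay <- list(
    d = d, z_bot = z_bot, horn_top = horn_top, x_out = x_out,
    z_peak = z_peak, z_sh = z_sh, centre = centre,
    y_post = -d - spec$horn_posterior_extent_mm,
    y_ant = spec$horn_anterior_extent_mm
  )
  if (spec$ventricle_shape == "ellipsoid") {
    lay$vx <- spec$horn_width_mm / 2
    lay$vy <- (spec$horn_anterior_extent_mm + d + spec$horn_posterior_extent_mm) / 2
    lay$vz <- hze / 2
    lay$y_vc <- spec$horn_anterior_extent_mm - lay$vy
  }
  lay
}

# Top of the cranium interior above column (x, y); -Inf outside.
interior_top <- function(spec, x, y) {
  hw <- spec$cranium_halfwidths
  c0 <- phantom_layout(spec)$centre
  if (spec$cranium_shape == "box") {
    ifelse(abs(x) <= hw[1] & abs(y - c0[2]) <= hw[2], c0[3] + hw[3], -Inf)
  } else {
    r2 <- 1 - (x / hw[1])^2 - ((y - c0[2]) / hw[2])^2
    ifelse(r2 > 0, c0[3] + hw[3] * sqrt(pmax(r2, 0)), -Inf)
  }
}

validate_phantom_spec <- function(spec, margin = 2) {
  with(spec, {
    ext <- c(
      cranium_halfwidths, horn_width_mm, horn_zextent_mm,
      horn_anterior_extent_mm, horn_posterior_extent_mm,
      brain_above_ventricle_mm, acpc_mm, shell_mm
    )
    if (ventricle_shape != "ellipsoid") ext <- c(ext, body_width_mm, body_height_mm)
    if (any(!is.finite(ext)) || any(ext <= 0)) {
      abort("all phantom extents must be positive and finite.")
    }
    if (any(spacing_mm <= 0)) abort("voxel spacing must be positive.")
    if (ventricle_shape == "wedge_roof" && (roof_slope_s < 0 || roof_tilt < 0)) {
      abort("wedge_roof phantoms require roof_slope_s >= 0 and roof_tilt >= 0.")
    }
  })
  lay <- phantom_layout(spec)

  if (spec$ventricle_shape != "ellipsoid") {
    if (spec$body_width_mm > spec$horn_width_mm) {
      abort("body_width_mm must not exceed horn_width_mm.")
    }
    tilt <- if (spec$ventricle_shape == "wedge_roof") spec$roof_tilt else 0
    if (spec$body_height_mm + tilt * spec$acpc_mm > spec$horn_zextent_mm) {
      abort("the body apex at the AC must not rise above the frontal horn roof.")
    }
    if (spec$ventricle_shape == "wedge_roof" &&
        lay$z_sh - tilt * spec$horn_posterior_extent_mm <= 0) {
      abort(paste(
        "roof slope too steep: the ventricle roof falls below the ACPC",
        "plane at the outer posterior edge (increase body_height_mm or",
        "reduce roof_slope_s / body_width_mm)."
      ))
    }
  } else if (lay$y_vc < 0) {
    abort(paste(
      "ellipsoid ventricle centre must not be posterior to the AC",
      "(horn_anterior_extent_mm too small relative to the posterior reach)."
    ))
  }

  # spacing coarser than a ventricle extent cannot be voxelized meaningfully
  vext <- if (spec$ventricle_shape == "ellipsoid") {
    lay2 <- phantom_layout(spec)
    c(2 * lay2$vx, 2 * lay2$vy, 2 * lay2$vz)
  } else {
    c(
      spec$horn_width_mm, spec$horn_zextent_mm, spec$horn_anterior_extent_mm,
      spec$body_height_mm, spec$body_width_mm
    )
  }
  if (max(spec$spacing_mm) >= min(vext)) {
    abort("voxel spacing is coarser than a ventricle extent; refine spacing.")
  }

  # ventricle strictly inside the cranium interior, with clearance
  pts <- ventricle_extreme_points(spec)
  if (!all(points_inside_interior(spec, pts, margin = margin))) {
    abort(sprintf(
      "ventricle is not strictly inside the brain (requires %.1f mm clearance).",
      margin
    ))
  }
  invisible(spec)
}

ventricle_extreme_points <- function(spec) {
  lay <- phantom_layout(spec)
  if (spec$ventricle_shape == "ellipsoid") {
    rbind(
      c(lay$vx, lay$y_vc, 0), c(-lay$vx, lay$y_vc, 0),
      c(0, lay$y_vc + lay$vy, 0), c(0, lay$y_vc - lay$vy, 0),
      c(0, lay$y_vc, lay$vz), c(0, lay$y_vc, -lay$vz)
    )
  } else {
    hwx <- spec$horn_width_mm / 2
    horn <- expand.grid(
      x = c(-hwx, hwx), y = c(0, lay$y_ant),
      z = c(lay$z_bot, lay$horn_top)
    )
    tilt <- if (spec$ventricle_shape == "wedge_roof") spec$roof_tilt else 0
    body <- expand.grid(
      x = c(-lay$x_out, 0, lay$x_out), y = c(lay$y_post, 0),
      z = c(lay$z_bot, lay$z_peak + tilt * spec$acpc_mm)
    )
    as.matrix(rbind(horn, body))
  }
}

points_inside_interior <- function(spec, pts, margin = 0) {
  hw <- spec$cranium_halfwidths
  c0 <- phantom_layout(spec)$centre
  p <- sweep(pts, 2, c0)
  if (spec$cranium_shape == "box") {
    apply(abs(p) <= matrix(hw - margin, nrow(p), 3, byrow = TRUE), 1, all)
  } else {
    rowSums(sweep(p, 2, pmax(hw - margin, 1e-9), "/")^2) <= 1
  }
}

#' Closed-form morphometry of a phantom
#'
#' Computes the six linear indices and the ventricular volume implied by a
#' [phantom_spec()] in continuous geometry, before any voxelization. These
#' are the ground-truth values against which voxel-grid measurements are
#' checked. For wedge-roof phantoms the callosal angle is
#' `180 - 2*atan(roof_slope_s)` degrees; flat-roof (`"box"`) phantoms have a
#' degenerate 180-degree angle and ellipsoid ventricles have no planar roof,
#' so `ca_deg` is `NA` there.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `analytic_truth` with elements `ei`, `bci`,
#'   `z_evans`, `ca_deg`, `bvr_ac`, `bvr_pc`, `ventricle_volume_cm3`, and a
#'   `components` list holding every numerator/denominator in mm.
#' @export
analytic_truth <- function(spec) {
  lay <- phantom_layout(spec)
  hw <- spec$cranium_halfwidths
  c0 <- lay$centre
  d <- lay$d

  # interior extents
  ei_den <- 2 * hw[1] # widest axial slice through the interior
  interior_x_extent <- function(y, z) {
    if (spec$cranium_shape == "box") {
      2 * hw[1]
    } else {
      2 * hw[1] * sqrt(max(
        0, 1 - ((y - c0[2]) / hw[2])^2 - ((z - c0[3]) / hw[3])^2
      ))
    }
  }
  interior_z_extent_col <- function(x, y) {
    if (spec$cranium_shape == "box") {
      2 * hw[3]
    } else {
      2 * hw[3] * sqrt(max(0, 1 - (x / hw[1])^2 - ((y - c0[2]) / hw[2])^2))
    }
  }

  # per-slice ventricle geometry
  if (spec$ventricle_shape == "ellipsoid") {
    vx <- lay$vx; vy <- lay$vy; vz <- lay$vz; y_vc <- lay$y_vc
    r_at <- function(y) sqrt(max(0, 1 - ((y - y_vc) / vy)^2))
    ei_num <- 2 * vx                       # widest frontal slice (centre is at y >= 0)
    bci_num <- 2 * vx * r_at(0)            # maximal width on the ACPC axial slice is at y = 0
    ze_num <- 2 * vz * r_at(0)
    vent_top_at <- function(x, y) {
      r <- r_at(y)
      ifelse(abs(x) <= vx * r, vz * sqrt(pmax(r^2 - (x / vx)^2, 0)), -Inf)
    }
    v_height <- function(y) 2 * vz * r_at(y)
    col_range <- function(y) c(0, vx * r_at(y))
    ca_deg <- NA_real_
    vol_mm3 <- 4 / 3 * pi * vx * vy * vz
  } else {
    s <- if (spec$ventricle_shape == "box") 0 else spec$roof_slope_s
    tilt <- if (spec$ventricle_shape == "box") 0 else spec$roof_tilt
    roof <- function(x, y) lay$z_peak + tilt * (y + d) - s * abs(x)
    ei_num <- spec$horn_width_mm
    bci_num <- spec$body_width_mm
    ze_num <- spec$horn_zextent_mm
    vent_top_at <- function(x, y) {
      if (y >= 0) {
        ifelse(abs(x) <= spec$horn_width_mm / 2, lay$horn_top, -Inf)
      } else {
        ifelse(abs(x) <= lay$x_out, roof(x, y), -Inf)
      }
    }
    v_height <- function(y) if (y >= 0) spec$horn_zextent_mm else spec$body_height_mm
    ca_deg <- if (spec$ventricle_shape == "box") 180 else 180 - 2 * atan(s) * 180 / pi
    hp <- spec$horn_posterior_extent_mm
    mean_bh <- spec$body_height_mm + tilt * (d^2 - hp^2) / (2 * (d + hp))
    body_area <- 2 * (mean_bh * lay$x_out - 0.5 * s * lay$x_out^2)
    vol_mm3 <- spec$horn_width_mm * lay$y_ant * spec$horn_zextent_mm +
      (d + hp) * body_area
  }

  # Brain thickness above the ventricle, read (as in the measurement) at
  # the midline, where the ventricular height peaks for every shape
  # (horn plateau, tent apex, ellipsoid crown).
  brain_over <- function(y) interior_top(spec, 0, y) - vent_top_at(0, y)

  bvr_ac_vent <- v_height(0)
  bvr_ac_brain <- brain_over(0)
  bvr_pc_vent <- v_height(-d)
  bvr_pc_brain <- brain_over(-d)

  comps <- list(
    ei_num = ei_num, ei_den = ei_den,
    bci_num = bci_num, bci_den = interior_x_extent(0, 0),
    ze_num = ze_num, ze_den = interior_z_extent_col(0, 0),
    bvr_ac_brain = bvr_ac_brain, bvr_ac_vent = bvr_ac_vent,
    bvr_pc_brain = bvr_pc_brain, bvr_pc_vent = bvr_pc_vent
  )
  structure(
    list(
      ei = ei_num / ei_den,
      bci = comps$bci_num / comps$bci_den,
      z_evans = comps$ze_num / comps$ze_den,
      ca_deg = ca_deg,
      bvr_ac = bvr_ac_brain / bvr_ac_vent,
      bvr_pc = bvr_pc_brain / bvr_pc_vent,
      ventricle_volume_cm3 = vol_mm3 / 1000,
      components = comps
    ),
    class = "analytic_truth"
  )
}

#' Draw a random phantom specification
#'
#' Samples a wedge-roof phantom with dimensions in broadly head-like ranges
#' (cranium interior 110-140 mm wide, ventricles 44-56 mm wide, tent-roof slopes
#' 0.35-0.85). Used for seeded recovery and pose-invariance testing; every
#' draw passes [phantom_spec()] validation.
#'
#' @param seed Optional integer seed (local RNG state).
#' @param spacing_mm Voxel spacing, scalar or length-3.
#' @param cranium_shape `"box"` (default) or `"ellipsoid"`.
#' @param pose Optional rigid pose, e.g. from [random_pose()].
#' @return A [phantom_spec()].
#' @export
random_phantom_spec <- function(seed = NULL, spacing_mm = 1,
                                cranium_shape = c("box", "ellipsoid"),
                                pose = NULL) {
  cranium_shape <- match.arg(cranium_shape)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  runif1 <- function(lo, hi) stats::runif(1, lo, hi)
  for (try in 1:100) {
    hw <- if (cranium_shape == "box") {
      c(runif1(55, 70), runif1(65, 80), runif1(55, 65))
    } else {
      c(runif1(70, 85), runif1(85, 100), runif1(68, 80))
    }
    horn_w <- runif1(54, 66)
    horn_z <- runif1(38, 48)
    body_w <- runif1(44, min(horn_w - 8, 56))
    body_h <- runif1(30, horn_z - 7.5)
    h_post <- runif1(8, 14)
    tilt <- 0.25
    s_max <- min(0.85, (body_h / 2 - tilt * h_post - 1.5) / (body_w / 2))
    s <- runif1(0.35, max(0.36, s_max))
    spec <- try(
      phantom_spec(
        cranium_halfwidths = hw, cranium_shape = cranium_shape,
        ventricle_shape = "wedge_roof",
        horn_width_mm = horn_w, horn_zextent_mm = horn_z,
        horn_anterior_extent_mm = runif1(28, 38),
        horn_posterior_extent_mm = h_post,
        body_width_mm = body_w, body_height_mm = body_h,
        roof_slope_s = s, roof_tilt = tilt,
        brain_above_ventricle_mm = runif1(14, 26),
        spacing_mm = spacing_mm, pose = pose
      ),
      silent = TRUE
    )
    if (!inherits(spec, "try-error")) return(spec)
  }
  abort("failed to draw a valid random phantom specification.")
}

#' Draw a random rigid pose
#'
#' A rotation of up to `max_angle_deg` about a random axis plus a uniform
#' translation, for exercising pose-invariance of the measurement pipeline.
#'
#' @param seed Optional integer seed (local RNG state).
#' @param max_angle_deg Maximum rotation angle (degrees).
#' @param max_shift_mm Maximum per-axis translation (mm).
#' @return A [rigid_transform()].
#' @export
random_pose <- function(seed = NULL, max_angle_deg = 20, max_shift_mm = 15) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, -max_angle_deg, max_angle_deg) * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  rigid_transform(R, stats::runif(3, -max_shift_mm, max_shift_mm))
}
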