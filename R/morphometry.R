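#' Linear morphometric indices on an ACPC-aligned volume
#'
#' These functions measure the classical 2d indices (Evans index, bicaudate
#' index, callosal angle) and the 3-directional indices (z-Evans index,
#' brain-per-ventricle ratio at the AC and PC levels) on an `acpc_volume` —
#' a label volume resampled into the canonical ACPC frame by
#' [align_volume()] (or built there directly).
#'
#' All linear extents are edge-to-edge voxel extents:
#' `(max index - min index + 1) * spacing`, i.e. the full width of the run
#' of voxels including both boundary half-voxels, so that a 38 mm box
#' voxelized at 1 mm measures exactly 38 mm. Ties in maximal searches are
#' broken toward the slice or column closest to the AC (and to the midline
#' for column searches). Coronal measurements "at" the AC use the first
#' voxel slab anterior to it (the frontal-horn side); the PC level uses the
#' nearest slab, since the ventricle body is continuous across it.
#'
#' @param aligned An `acpc_volume`.
#' @param level `"AC"` or `"PC"`: the coronal level for [bvr()].
#' @return Each index function returns an `index_measurement`: a list with
#'   `value` (dimensionless, or degrees for the callosal angle),
#'   `numerator_mm`, `denominator_mm`, `slice_mm` (position along the
#'   searched axis) and `method`.
#' @name morphometry
NULL

new_index_measurement <- function(value, numerator_mm, denominator_mm,
                                  slice_mm, method, extra = list()) {
  if (grepl("ratio", method)) {
    stopifnot(numerator_mm > 0, denominator_mm > 0)
    stopifnot(abs(value - numerator_mm / denominator_mm) <= 1e-9)
  }
  structure(
    c(list(value = unname(value), numerator_mm = unname(numerator_mm),
           denominator_mm = unname(denominator_mm),
           slice_mm = unname(slice_mm), method = method), extra),
    class = "index_measurement"
  )
}

#' @export
print.index_measurement <- function(x, ...) {
  cat(sprintf("<index_measurement> %s: %.4f (num %.2f mm / den %.2f mm, at %.1f mm)\n",
              x$method, x$value,
              x$numerator_mm %||% NA, x$denominator_mm %||% NA,
              x$slice_mm %||% NA))
  invisible(x)
}

check_aligned <- function(aligned) {
  if (!inherits(aligned, "acpc_volume") || is.null(aligned$acpc_mm)) {
    abort("input must be an `acpc_volume`; run align_volume() first.")
  }
  invisible(aligned)
}

# edge-to-edge extent of an index run
vox_extent <- function(nmin, nmax, spacing) (nmax - nmin + 1) * spacing

# Collapse a 3D logical array over one axis: any() along `over`,
# returning a matrix of the two remaining axes in order.
collapse_any <- function(mask, over) {
  perm <- c(over, setdiff(1:3, over))
  colSums(aperm(mask, perm), dims = 1) > 0
}

# index ranges of TRUE rows per column of a logical matrix
per_column_range <- function(pres) {
  cols <- which(colSums(pres) > 0)
  lapply(setNames(cols, cols), function(k) range(which(pres[, k])))
}

# pick the maximizing entry; ties (within `tol`) broken toward smallest |coord|
pick_max <- function(values, coords, tol = 1e-12) {
  best <- max(values)
  cand <- which(values >= best - tol)
  cand[which.min(abs(coords[cand]))]
}

# 3-point running median along the scan axis: stabilises "max over
# parallel lines" searches against voxel staircase spikes after
# resampling (each smoothed value is still one of the measured extents)
smooth3 <- function(ext) {
  if (length(ext) < 3L) return(ext)
  as.numeric(stats::runmed(ext, 3))
}

# Theil-Sen slope: median of pairwise slopes. Robust both to the voxel
# staircase and to columns clipping a vertical ventricle face, whose roof
# voxels sit far off the roof line.
theil_sen <- function(x, z) {
  ij <- utils::combn(length(x), 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  ok <- abs(dx) > 1e-9
  median((z[ij[2, ]] - z[ij[1, ]])[ok] / dx[ok])
}

# Magnitude of a descending staircase slope from roof-top voxels pooled
# over several coronal slabs. A straight-line fit to a 1-voxel staircase
# cannot beat ~spacing/width accuracy; instead the slope is the value that
# minimizes, summed over slabs, the trimmed spread of the de-trended tops
# z + s*x — for the correct s the de-trended tops of one slab collapse
# into a single quantization band. Trimming one point at each extreme per
# slab absorbs columns clipping a vertical ventricle face.
stair_slope <- function(x, z, slab, s_max = 2.5) {
  groups <- split(seq_along(x), slab)
  trange <- function(v) {
    n <- length(v)
    if (n >= 5) { sv <- sort(v); sv[n - 1] - sv[2] } else max(v) - min(v)
  }
  obj <- function(s) {
    r <- z + s * x
    sum(vapply(groups, function(ix) trange(r[ix]), numeric(1)))
  }
  ss <- seq(0, s_max, by = 0.01)
  s0 <- ss[which.min(vapply(ss, obj, numeric(1)))]
  stats::optimize(obj, c(max(0, s0 - 0.015), min(s_max, s0 + 0.015)))$minimum
}

# slice index nearest `target`; if prefer_anterior, the first slab with
# coordinate >= target (the geometry is one-sided at the AC boundary)
slice_index <- function(coords, target, prefer_anterior = FALSE) {
  if (prefer_anterior) {
    cand <- which(coords >= target - 1e-9)
    if (length(cand) > 0) return(cand[which.min(coords[cand])])
  }
  which.min(abs(coords - target))
}

#' Frontal-horn submask of the ventricles
#'
#' The frontal horns are taken as all ventricle voxels anterior to the AC
#' (`y > 0` in the canonical frame); the anatomical horn boundary is not
#' otherwise defined by the labelling.
#'
#' @inheritParams morphometry
#' @return A logical array over the volume grid.
#' @export
frontal_horn_mask <- function(aligned) {
  check_aligned(aligned)
  vent <- tissue_mask(aligned, "ventricle")
  if (!any(vent)) abort("volume contains no ventricle label.")
  ys <- axis_coords(aligned, 2)
  anterior <- array(rep(ys > 0, each = dim(aligned$data)[1]), dim(aligned$data))
  mask <- vent & anterior
  if (!any(mask)) abort("no frontal horn: ventricle is entirely posterior to the AC.")
  mask
}

#' @rdname morphometry
#' @export
evans_index <- function(aligned) {
  check_aligned(aligned)
  horn <- frontal_horn_mask(aligned)
  interior <- tissue_mask(aligned, c("brain", "ventricle"))
  if (!any(interior)) abort("missing brain/cranium-interior labels.")
  sx <- aligned$spacing[1]
  zs <- axis_coords(aligned, 3)

  horn_xz <- collapse_any(horn, 2)        # x presence per axial slice
  rng <- per_column_range(horn_xz)
  ext <- smooth3(vapply(rng, function(r) vox_extent(r[1], r[2], sx), numeric(1)))
  ks <- as.integer(names(rng))
  i_best <- pick_max(ext, zs[ks])

  int_xz <- collapse_any(interior, 2)
  rng_d <- per_column_range(int_xz)
  den <- max(smooth3(vapply(rng_d, function(r) vox_extent(r[1], r[2], sx),
                            numeric(1))))

  new_index_measurement(
    value = ext[i_best] / den, numerator_mm = ext[i_best], denominator_mm = den,
    slice_mm = zs[ks[i_best]], method = "evans_index_ratio"
  )
}

#' @rdname morphometry
#' @export
bicaudate_index <- function(aligned) {
  check_aligned(aligned)
  d <- aligned$acpc_mm
  sx <- aligned$spacing[1]
  ys <- axis_coords(aligned, 2)
  zs <- axis_coords(aligned, 3)
  sy <- aligned$spacing[2]
  k0 <- slice_index(zs, 0)
  slab <- aligned$data[, , k0]
  vent <- slab == label_code(aligned, "ventricle")
  rows <- which(colSums(vent) > 0)
  # candidate lines sit between PC and AC, at least half a voxel below the
  # AC: the boundary row abuts the frontal-horn face and picks up its
  # (wider) voxels after resampling
  rows <- rows[ys[rows] <= -sy / 2 - 1e-9 & ys[rows] >= -d - 1e-9]
  if (length(rows) == 0L) {
    abort("ventricle absent from the ACPC axial slice between PC and AC.")
  }
  ext <- smooth3(vapply(rows, function(j) {
    r <- range(which(vent[, j])); vox_extent(r[1], r[2], sx)
  }, numeric(1)))
  j_best <- rows[pick_max(ext, ys[rows])]   # ties toward the AC (y = 0)
  num <- max(ext)

  interior <- slab %in% c(label_code(aligned, "brain"), label_code(aligned, "ventricle"))
  dim(interior) <- dim(slab)
  ri <- which(interior[, j_best])
  if (length(ri) == 0L) abort("no brain along the intercaudate line.")
  den <- vox_extent(min(ri), max(ri), sx)
  value <- num / den
  if (value > 1) {
    abort("invalid geometry: intercaudate distance exceeds the brain width.")
  }
  new_index_measurement(
    value = value, numerator_mm = num, denominator_mm = den,
    slice_mm = ys[j_best], method = "bicaudate_index_ratio"
  )
}

#' @rdname morphometry
#' @export
callosal_angle <- function(aligned) {
  check_aligned(aligned)
  d <- aligned$acpc_mm
  xs <- axis_coords(aligned, 1)
  ys <- axis_coords(aligned, 2)
  zs <- axis_coords(aligned, 3)
  j0 <- slice_index(ys, -d)
  code_v <- label_code(aligned, "ventricle")
  if (!any(aligned$data[, j0, ] == code_v)) {
    abort("ventricle absent from the PC coronal slice.")
  }
  # Roof points pooled over a thin coronal slab (+-3 voxels around the PC
  # slice; the ventricle body spans it): the slabs carry different
  # staircase phases, which the staircase-aware slope fit needs.
  js <- intersect(j0 + (-3:3), seq_along(ys))
  js <- js[vapply(js, function(j) any(aligned$data[, j, ] == code_v), logical(1))]

  roof_points <- function(side) {
    pts <- purrr::map_dfr(js, function(j) {
      vent <- aligned$data[, j, ] == code_v
      cols <- which(rowSums(vent) > 0)
      cols <- cols[sign(xs[cols]) == side & abs(xs[cols]) > 1e-9]
      tibble(
        slab = j, x = xs[cols],
        z = vapply(cols, function(i) zs[max(which(vent[i, ]))], numeric(1))
      )
    })
    if (length(unique(pts$x)) < 3L) {
      abort(sprintf("insufficient roof: fewer than 3 ventricle columns on the %s side.",
                    if (side < 0) "left" else "right"))
    }
    pts
  }
  roof_slope <- function(side) {
    pts <- roof_points(side)
    # tops descend moving laterally on either side; the staircase fit
    # returns the slope magnitude, re-signed per side
    side * -stair_slope(side * pts$x, pts$z, pts$slab)
  }
  m_l <- roof_slope(-1)
  m_r <- roof_slope(1)
  if (min(abs(m_l), abs(m_r)) < 0.02) {
    abort("degenerate flat roof: fitted ventricle roof slope is ~0.")
  }
  # angle between the two roof directions, oriented from the midline laterally
  cos_th <- (-1 - m_l * m_r) / sqrt((1 + m_l^2) * (1 + m_r^2))
  value <- acos(pmin(pmax(cos_th, -1), 1)) * 180 / pi
  new_index_measurement(
    value = value, numerator_mm = NA_real_, denominator_mm = NA_real_,
    slice_mm = ys[j0], method = "callosal_angle_roof_fit",
    extra = list(slope_left = m_l, slope_right = m_r)
  )
}

#' @rdname morphometry
#' @export
z_evans_index <- function(aligned) {
  check_aligned(aligned)
  xs <- axis_coords(aligned, 1)
  ys <- axis_coords(aligned, 2)
  sz <- aligned$spacing[3]
  j0 <- slice_index(ys, 0, prefer_anterior = TRUE)
  slab <- aligned$data[, j0, ]
  vent <- slab == label_code(aligned, "ventricle")
  interior <- slab %in% c(label_code(aligned, "brain"), label_code(aligned, "ventricle"))
  dim(interior) <- dim(slab)
  if (!any(vent) || !any(interior)) {
    abort("ventricle or cranium interior absent from the AC coronal slice.")
  }
  col_ext <- function(mask) {
    cols <- which(rowSums(mask) > 0)
    ext <- smooth3(vapply(cols, function(i) {
      r <- range(which(mask[i, ])); vox_extent(r[1], r[2], sz)
    }, numeric(1)))
    list(cols = cols, ext = ext)
  }
  v <- col_ext(vent)
  i_best <- pick_max(v$ext, xs[v$cols])
  den <- max(col_ext(interior)$ext)
  new_index_measurement(
    value = v$ext[i_best] / den, numerator_mm = v$ext[i_best],
    denominator_mm = den, slice_mm = xs[v$cols[i_best]],
    method = "z_evans_index_ratio"
  )
}

#' @rdname morphometry
#' @export
bvr <- function(aligned, level = c("AC", "PC")) {
  level <- match.arg(level)
  check_aligned(aligned)
  xs <- axis_coords(aligned, 1)
  ys <- axis_coords(aligned, 2)
  zs <- axis_coords(aligned, 3)
  sz <- aligned$spacing[3]
  y_target <- if (level == "AC") 0 else -aligned$acpc_mm
  j0 <- slice_index(ys, y_target, prefer_anterior = level == "AC")
  code_v <- label_code(aligned, "ventricle")
  code_b <- label_code(aligned, "brain")
  if (!any(aligned$data[, j0, ] == code_v)) {
    abort(sprintf("ventricle absent from the %s coronal slice.", level))
  }
  # The read is pooled over a thin coronal slab around the level (staying
  # anterior to the AC at the AC level, where the geometry is one-sided):
  # the ventricle is prismatic there and per-slice voxel jitter averages
  # out in the slab median.
  js <- if (level == "AC") j0 + 0:2 else j0 + (-2:2)
  js <- intersect(js, seq_along(ys))
  js <- js[vapply(js, function(j) any(aligned$data[, j, ] == code_v), logical(1))]

  prof <- function(j) { # per-column ventricle height / tops / floor in slab j
    vent <- aligned$data[, j, ] == code_v
    brain <- aligned$data[, j, ] == code_b
    nx <- nrow(vent)
    h <- vt <- vb <- bt <- rep(NA_real_, nx)
    for (i in which(rowSums(vent) > 0)) {
      r <- range(which(vent[i, ]))
      h[i] <- vox_extent(r[1], r[2], sz)
      vt[i] <- zs[r[2]]
      vb[i] <- zs[r[1]]
      kb <- which(brain[i, ])
      bt[i] <- if (length(kb)) zs[max(kb)] else NA_real_
    }
    list(h = h, vt = vt, vb = vb, bt = bt)
  }
  profs <- lapply(js, prof)
  med_across <- function(field) {
    apply(do.call(cbind, lapply(profs, `[[`, field)), 1, median, na.rm = TRUE)
  }
  h <- med_across("h")
  vt <- med_across("vt")
  vb <- med_across("vb")
  bt <- med_across("bt")
  cols <- which(!is.na(h))
  # Both lines are read at the column of maximal ventricular height
  # (near-ties within one voxel broken toward the midline): the brain
  # mantle is measured directly above the tallest point of the ventricle.
  # Per-column maxima over all ventricle columns are ill-conditioned on
  # voxel grids — partial-volume columns at the near-vertical lateral
  # margin report spuriously low roof voxels; columns more than two voxels
  # short of the maximal height are likewise excluded from the read.
  elig <- cols[h[cols] >= max(h[cols]) - 2 * sz]
  i_star <- elig[pick_max(h[elig], xs[elig], tol = sz + 1e-9)]

  # Sub-voxel apex: the ventricular roof peaks at the midline for a
  # bilaterally symmetric system, so the roof height at x = 0 is taken as
  # the mean of the two per-side roof-line fits evaluated at the midline
  # (for a flat roof both fits are the plateau level; for a tent they
  # intersect at the apex). Falls back to the tallest-column top when a
  # side has too few columns.
  apex_side <- function(sgn) {
    sc <- cols[sign(xs[cols]) == sgn & !is.na(vt[cols])]
    if (length(sc) < 3L) return(NA_real_)
    m <- theil_sen(xs[sc], vt[sc])
    median(vt[sc] - m * xs[sc])   # robust intercept at x = 0
  }
  apex <- c(apex_side(-1), apex_side(1))
  vt_peak <- if (anyNA(apex)) vt[i_star] else mean(apex)
  # clamp to the observed tallest top: never below it, and at most 1.5
  # voxels above (line intercepts overshoot on curved roofs)
  vt_peak <- min(max(vt_peak, vt[i_star]), vt[i_star] + 1.5 * sz)
  vb_min <- min(vb[elig])
  V <- vt_peak - vb_min + sz
  if (is.na(bt[i_star])) {
    abort(sprintf("degenerate BVR at %s: no brain above the ventricle.", level))
  }
  B <- bt[i_star] - vt_peak
  if (!is.finite(B) || B <= 0) {
    abort(sprintf("degenerate BVR at %s: no brain above the ventricle.", level))
  }
  new_index_measurement(
    value = B / V, numerator_mm = B, denominator_mm = V,
    slice_mm = ys[j0], method = sprintf("bvr_%s_ratio", tolower(level))
  )
}

#' Measure all morphometric indices on an aligned volume
#'
#' One-call orchestration: the six linear indices plus voxel-count
#' ventricular volumetry. Any member failure is re-signalled with the
#' failing index named.
#'
#' @inheritParams morphometry
#' @return A `morphometric_result`: named `index_measurement`s (`ei`, `bci`,
#'   `ca`, `z_evans`, `bvr_ac`, `bvr_pc`), the BVR-at-PC brain/ventricle
#'   components in mm, and `ventricle_volume_cm3`.
#' @export
measure_all <- function(aligned) {
  check_aligned(aligned)
  run <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      abort(sprintf("%s: %s", name, conditionMessage(e)))
    })
  }
  ei <- run("evans_index", function() evans_index(aligned))
  bci <- run("bicaudate_index", function() bicaudate_index(aligned))
  ca <- run("callosal_angle", function() callosal_angle(aligned))
  ze <- run("z_evans_index", function() z_evans_index(aligned))
  bvr_ac <- run("bvr_ac", function() bvr(aligned, "AC"))
  bvr_pc <- run("bvr_pc", function() bvr(aligned, "PC"))
  vol <- run("ventricular_volume", function() {
    ventricular_volume(aligned, label_code(aligned, "ventricle"))
  })
  structure(
    list(
      ei = ei, bci = bci, ca = ca, z_evans = ze,
      bvr_ac = bvr_ac, bvr_pc = bvr_pc,
      bvr_pc_brain_mm = bvr_pc$numerator_mm,
      bvr_pc_ventricle_mm = bvr_pc$denominator_mm,
      ventricle_volume_cm3 = vol$volume_cm3,
      volume_report = vol
    ),
    class = "morphometric_result"
  )
}

#' @export
print.morphometric_result <- function(x, ...) {
  cat("<morphometric_result>\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy a morphometric result
#'
#' @param x A `morphometric_result` from [measure_all()].
#' @param ... Unused.
#' @return `tidy()`: one row per index with value, numerator/denominator
#'   (mm) and the slice coordinate searched. `glance()`: a one-row wide
#'   tibble including the BVR-at-PC components and the ventricular volume.
#' @method tidy morphometric_result
#' @export
tidy.morphometric_result <- function(x, ...) {
  ix <- c("ei", "bci", "ca", "z_evans", "bvr_ac", "bvr_pc")
  purrr::map_dfr(ix, function(nm) {
    m <- x[[nm]]
    tibble(
      index = nm, value = m$value, numerator_mm = m$numerator_mm,
      denominator_mm = m$denominator_mm, slice_mm = m$slice_mm,
      method = m$method
    )
  })
}

#' @rdname tidy.morphometric_result
#' @method glance morphometric_result
#' @export
glance.morphometric_result <- function(x, ...) {
  tibble(
    ei = x$ei$value, bci = x$bci$value, ca_deg = x$ca$value,
    z_evans = x$z_evans$value, bvr_ac = x$bvr_ac$value,
    bvr_pc = x$bvr_pc$value,
    bvr_pc_brain_mm = x$bvr_pc_brain_mm,
    bvr_pc_ventricle_mm = x$bvr_pc_ventricle_mm,
    ventricle_volume_cm3 = x$ventricle_volume_cm3
  )
}
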