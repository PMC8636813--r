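test_that("analytic truth matches forced constructions", {
  spec <- phantom_spec(
    cranium_halfwidths = c(50, 70, 55), horn_width_mm = 38,
    horn_zextent_mm = 40, body_width_mm = 36, body_height_mm = 32,
    roof_slope_s = 0.5
  )
  tr <- analytic_truth(spec)
  expect_equal(tr$ei, 38 / 100)
  expect_equal(tr$bci, 36 / 100)
  expect_equal(tr$z_evans, 40 / 110)
  expect_equal(tr$components$bvr_pc_vent, 32)
  expect_equal(tr$bvr_pc,
               tr$components$bvr_pc_brain / tr$components$bvr_pc_vent)

  # symmetric roof slope 1 halves the flat 180-degree limit twice over
  s1 <- phantom_spec(body_width_mm = 28, body_height_mm = 34,
                     roof_slope_s = 1, roof_tilt = 0)
  expect_equal(analytic_truth(s1)$ca_deg, 90)
  s2 <- phantom_spec(body_width_mm = 32, body_height_mm = 34,
                     roof_slope_s = 0.753, roof_tilt = 0)
  expect_equal(analytic_truth(s2)$ca_deg, 180 - 2 * atan(0.753) * 180 / pi,
               tolerance = 1e-9)
  expect_equal(analytic_truth(s2)$ca_deg, 106.0, tolerance = 1e-3)
})

test_that("truth ratios are scale invariant and volume scales cubically", {
  base <- phantom_spec()
  k <- 1.5
  scaled <- phantom_spec(
    cranium_halfwidths = base$cranium_halfwidths * k,
    horn_width_mm = base$horn_width_mm * k,
    horn_zextent_mm = base$horn_zextent_mm * k,
    horn_anterior_extent_mm = base$horn_anterior_extent_mm * k,
    horn_posterior_extent_mm = base$horn_posterior_extent_mm * k,
    body_width_mm = base$body_width_mm * k,
    body_height_mm = base$body_height_mm * k,
    roof_slope_s = base$roof_slope_s,
    brain_above_ventricle_mm = base$brain_above_ventricle_mm * k,
    acpc_mm = base$acpc_mm * k,
    spacing_mm = base$spacing_mm * k
  )
  t0 <- analytic_truth(base)
  t1 <- analytic_truth(scaled)
  for (f in c("ei", "bci", "z_evans", "ca_deg", "bvr_ac", "bvr_pc")) {
    expect_equal(t1[[f]], t0[[f]], tolerance = 1e-9, label = f)
  }
  expect_equal(t1$ventricle_volume_cm3, t0$ventricle_volume_cm3 * k^3,
               tolerance = 1e-9)
})

test_that("invalid phantom specifications are rejected", {
  expect_error(phantom_spec(horn_width_mm = 200), "inside the brain")
  expect_error(phantom_spec(spacing_mm = 60), "spacing is coarser")
  expect_error(phantom_spec(roof_slope_s = -0.2), "roof_slope_s >= 0")
  expect_error(phantom_spec(body_width_mm = 80), "body_width_mm")
  expect_error(phantom_spec(roof_slope_s = 2.5), "too steep")
})

test_that("voxelization is deterministic and labels are complete", {
  spec <- phantom_spec()
  a <- make_phantom(spec)
  b <- make_phantom(spec)
  expect_identical(a$labels$data, b$labels$data)
  expect_setequal(unique(as.vector(a$labels$data)), 0:3)
  # intensity coding: CSF darker than brain, background zero
  expect_equal(sort(unique(as.vector(a$intensity$data))), c(0, 100, 400, 600))
})

test_that("measurements on an unposed phantom recover the analytic truth", {
  ph <- default_phantom()
  m <- glance(measure_all(aligned_from(ph)))
  tr <- ph$truth
  co <- tr$components
  sp <- ph$spec$spacing_mm[1]
  expect_lt(abs(m$ei - tr$ei), 2 * sp / co$ei_den)
  expect_lt(abs(m$bci - tr$bci), 2 * sp / co$bci_den)
  expect_lt(abs(m$z_evans - tr$z_evans), 2 * sp / co$ze_den)
  expect_lt(abs(m$ca_deg - tr$ca_deg), 2)
  expect_lt(abs(m$bvr_ac - tr$bvr_ac), 2 * sp / co$bvr_ac_vent)
  expect_lt(abs(m$bvr_pc - tr$bvr_pc), 2 * sp / co$bvr_pc_vent)
  expect_lt(abs(m$ventricle_volume_cm3 / tr$ventricle_volume_cm3 - 1), 0.05)
})

test_that("ellipsoid phantoms recover EI and z-Evans; BVR matches a voxel oracle", {
  spec <- phantom_spec(
    cranium_halfwidths = c(65, 75, 60), cranium_shape = "box",
    ventricle_shape = "ellipsoid",
    horn_width_mm = 50, horn_zextent_mm = 40,
    horn_anterior_extent_mm = 45, horn_posterior_extent_mm = 12
  )
  ph <- make_phantom(spec)
  al <- aligned_from(ph)
  tr <- ph$truth
  co <- tr$components
  m_ei <- evans_index(al)
  m_ze <- z_evans_index(al)
  expect_lt(abs(m_ei$value - tr$ei), 2 / co$ei_den)
  expect_lt(abs(m_ze$value - tr$z_evans), 2 / co$ze_den)

  # independent brute-force voxel oracle for the BVR at AC: scan the first
  # anterior slab column by column, no shared code with bvr()
  ys <- al$origin[2] + (seq_len(dim(al$data)[2]) - 1) * al$spacing[2]
  j0 <- which(ys >= 0)[which.min(ys[ys >= 0])]
  slab <- al$data[, j0, ]
  zs <- al$origin[3] + (seq_len(dim(al$data)[3]) - 1) * al$spacing[3]
  hs <- apply(slab == 2, 1, sum)
  mid <- which.max(hs)                     # tallest (crown) column
  vt <- max(zs[slab[mid, ] == 2])
  bt <- max(zs[slab[mid, ] == 1])
  oracle <- (bt - vt) / (hs[mid] * al$spacing[3])
  m_bvr <- bvr(al, "AC")
  expect_lt(abs(m_bvr$value - oracle), 0.06)
  # the continuum crown is tangent to the voxel grid, so the truth check
  # for this shape is held to ~3 voxels of combined read error
  expect_lt(abs(m_bvr$value - tr$bvr_ac), 0.08)
})

test_that("NPH-like phantoms order against HC-like phantoms as in disease", {
  # larger ventricles and steeper roofs (NPH) vs small ventricles (HC)
  for (k in 1:3) {
    jit <- function(x, f = 0.03) x * (1 + stats::runif(1, -f, f))
    set.seed(500 + k)
    nph <- make_phantom(phantom_spec(
      horn_width_mm = jit(58), horn_zextent_mm = jit(46),
      body_width_mm = jit(48), body_height_mm = jit(38),
      roof_slope_s = 0.62, brain_above_ventricle_mm = jit(12)
    ))
    hc <- make_phantom(phantom_spec(
      horn_width_mm = jit(40), horn_zextent_mm = jit(30),
      body_width_mm = jit(32), body_height_mm = jit(22),
      roof_slope_s = 0.3, brain_above_ventricle_mm = jit(28)
    ))
    mn <- glance(measure_all(aligned_from(nph)))
    mh <- glance(measure_all(aligned_from(hc)))
    expect_gt(mn$ei, mh$ei)
    expect_gt(mn$bci, mh$bci)
    expect_gt(mn$z_evans, mh$z_evans)
    expect_lt(mn$ca_deg, mh$ca_deg)
    expect_lt(mn$bvr_ac, mh$bvr_ac)
    expect_lt(mn$bvr_pc, mh$bvr_pc)
  }
})

test_that("random phantom specs are valid and seed-deterministic", {
  a <- random_phantom_spec(seed = 42)
  b <- random_phantom_spec(seed = 42)
  expect_identical(a[names(a) != "pose"], b[names(b) != "pose"])
  expect_s3_class(a, "phantom_spec")
  p1 <- random_pose(seed = 7)
  p2 <- random_pose(seed = 7)
  expect_identical(p1, p2)
  expect_equal(det(p1$rotation), 1, tolerance = 1e-9)
})
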