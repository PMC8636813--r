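# tiny_brain(): 31 x 41 x 31 voxel brain box at 1 mm, origin chosen so the
# canonical frame's AC (y = 0) sits inside; ventricle box carved by index.

test_that("frontal horn mask is the anterior ventricle and errors when empty", {
  # default tiny ventricle spans y -15..-6 mm (all posterior to AC)
  post <- tiny_brain(vent_y = 11:20)
  expect_error(frontal_horn_mask(post), "entirely posterior")

  # ventricle straddling the AC: y indices 21:30 are -5.5..3.5 mm
  strad <- tiny_brain(vent_y = 21:30)
  mask <- frontal_horn_mask(strad)
  n_ant <- sum(mask)
  # 4 of the 10 y-slabs are anterior (0.5, 1.5, 2.5, 3.5 mm)
  expect_equal(n_ant, 10 * 10 * 4)

  # entirely anterior: mask equals the whole ventricle
  ant <- tiny_brain(vent_y = 27:36)
  expect_equal(sum(frontal_horn_mask(ant)), sum(ant$data == 2))
})

test_that("evans index is the exact construction ratio on box masks", {
  al <- tiny_brain(vent_x = 11:20, vent_y = 27:36)  # 10 mm horn, 31 mm brain
  m <- evans_index(al)
  expect_equal(m$numerator_mm, 10)
  expect_equal(m$denominator_mm, 31)
  expect_equal(m$value, 10 / 31)
  expect_match(m$method, "evans")
})

test_that("bicaudate index reads the widest line between PC and AC", {
  al <- tiny_brain(vent_x = 9:22, vent_y = 12:24, vent_z = 11:20)
  m <- bicaudate_index(al)
  expect_equal(m$numerator_mm, 14)
  expect_equal(m$denominator_mm, 31)
  expect_equal(m$value, 14 / 31)
  # the chosen line lies between PC (-15) and the AC
  expect_lte(m$slice_mm, 0)
  expect_gte(m$slice_mm, -15)

  # ventricle absent from the ACPC axial slice -> error
  high <- tiny_brain(vent_z = 25:30)
  expect_error(bicaudate_index(high), "absent")
})

test_that("z-Evans and BVR read per-column vertical extents at the AC", {
  # ventricle spanning the AC with 12 mm of vertical extent, brain roof
  # 31-voxel box: z indices 9:20 are -7.5..4.5 mm; brain top 15.5 mm
  al <- tiny_brain(vent_x = 12:19, vent_y = 18:28, vent_z = 9:20)
  ze <- z_evans_index(al)
  expect_equal(ze$numerator_mm, 12)
  expect_equal(ze$denominator_mm, 31)
  expect_equal(ze$value, 12 / 31)

  m <- bvr(al, "AC")
  expect_equal(m$denominator_mm, 12)        # ventricular height
  expect_equal(m$numerator_mm, 14.5 - 3.5)  # brain top to ventricle top centres
  expect_equal(m$value, 11 / 12)
})

test_that("callosal angle recovers tent roofs and rejects flat ones", {
  ph <- default_phantom()
  m <- callosal_angle(aligned_from(ph))
  expect_lt(abs(m$value - ph$truth$ca_deg), 2)
  expect_equal(m$slope_left, -m$slope_right, tolerance = 0.15)

  flat <- make_phantom(phantom_spec(ventricle_shape = "box"))
  expect_error(callosal_angle(aligned_from(flat)), "flat roof")

  # fewer than 3 columns on a side
  thin <- tiny_brain(vent_x = 15:16, vent_y = 8:12, vent_z = 11:20)
  expect_error(callosal_angle(thin), "insufficient roof")
})

test_that("measure_all is deterministic and names the failing index", {
  ph <- default_phantom()
  al <- aligned_from(ph)
  r1 <- glance(measure_all(al))
  r2 <- glance(measure_all(al))
  expect_identical(r1, r2)

  no_vent <- al
  no_vent$data[no_vent$data == 2L] <- 1L
  err <- tryCatch(measure_all(no_vent), error = conditionMessage)
  expect_match(err, "evans_index")

  td <- tidy(measure_all(al))
  expect_equal(nrow(td), 6)
  expect_true(all(c("index", "value", "numerator_mm") %in% names(td)))
})

test_that("ratio invariants hold on valid phantoms", {
  for (seed in c(31, 32)) {
    ph <- make_phantom(random_phantom_spec(seed = seed))
    m <- glance(measure_all(aligned_from(ph)))
    expect_gt(m$ei, 0); expect_lt(m$ei, 1)
    expect_gt(m$bci, 0); expect_lt(m$bci, 1)
    expect_gt(m$z_evans, 0); expect_lt(m$z_evans, 1)
    expect_gt(m$ca_deg, 0); expect_lt(m$ca_deg, 180)
    expect_gt(m$bvr_ac, 0)
    expect_equal(m$bvr_pc, m$bvr_pc_brain_mm / m$bvr_pc_ventricle_mm,
                 tolerance = 1e-9)
  }
})

test_that("anisotropic spacing propagates into millimetre extents", {
  spec <- phantom_spec(spacing_mm = c(1, 1, 2))
  ph <- make_phantom(spec)
  m <- glance(measure_all(aligned_from(ph)))
  tr <- ph$truth
  co <- tr$components
  expect_lt(abs(m$z_evans - tr$z_evans), 2 * 2 / co$ze_den)
  expect_lt(abs(m$ei - tr$ei), 2 / co$ei_den)
  expect_lt(abs(m$ventricle_volume_cm3 / tr$ventricle_volume_cm3 - 1), 0.06)
})
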