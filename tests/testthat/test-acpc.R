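test_that("ACPC transform maps canonical and offset landmarks correctly", {
  tf <- compute_acpc_transform(landmark_set(c(0, 0, 0), c(0, -25, 0), c(0, 0, 30)))
  expect_equal(tf$rotation, diag(3), tolerance = 1e-12)
  expect_equal(tf$translation, c(0, 0, 0), tolerance = 1e-12)

  tf2 <- compute_acpc_transform(
    landmark_set(c(10, 5, 0), c(10, -20, 0), c(10, 5, 30))
  )
  expect_equal(tf2$rotation, diag(3), tolerance = 1e-12)
  expect_equal(tf2$translation, c(-10, -5, 0), tolerance = 1e-12)
})

test_that("landmarks pre-rotated by R are realigned by its transpose", {
  set.seed(11)
  for (rep in 1:5) {
    R <- random_pose(seed = rep)$rotation
    lm0 <- list(ac = c(0, 0, 0), pc = c(0, -25, 0), mid = c(0, 0, 30))
    lm <- landmark_set(
      drop(R %*% lm0$ac), drop(R %*% lm0$pc), drop(R %*% lm0$mid)
    )
    tf <- compute_acpc_transform(lm)
    expect_equal(tf$rotation, t(R), tolerance = 1e-9)
    # and the full map restores the canonical positions
    expect_equal(transform_points(tf, lm$pc), c(0, -25, 0), tolerance = 1e-9)
  }
})

test_that("degenerate landmark sets are rejected", {
  expect_error(landmark_set(c(0, 0, 0), c(0, 0, 0), c(0, 0, 30)), "coincide")
  expect_error(landmark_set(c(0, 0, 0), c(0, -25, 0), c(0, -50, 0)), "collinear")
  expect_error(rigid_transform(matrix(c(1, 0, 0, 0, 1, 0, 0, 0, -1), 3)),
               "determinant")
  expect_error(rigid_transform(diag(3) * 2), "orthonormal")
})

test_that("rigid transforms compose and invert to high precision", {
  a <- random_pose(seed = 1)
  b <- random_pose(seed = 2)
  p <- matrix(stats::rnorm(30), 10, 3)
  expect_equal(
    transform_points(compose_transforms(a, b), p),
    transform_points(a, transform_points(b, p)),
    tolerance = 1e-9
  )
  back <- transform_points(invert_transform(a), transform_points(a, p))
  expect_lt(max(abs(back - p)), 1e-6)
  # distances preserved
  q <- transform_points(a, p)
  expect_equal(as.vector(dist(q)), as.vector(dist(p)), tolerance = 1e-9)
})

test_that("identity resampling preserves per-class voxel counts", {
  ph <- default_phantom()
  out <- resample_labels(ph$labels, rigid_transform(diag(3)), acpc_mm = 25)
  expect_identical(table(out$data[out$data > 0]), table(ph$labels$data[ph$labels$data > 0]))
  expect_s3_class(out, "acpc_volume")
})

test_that("a 90-degree rotation conserves per-class counts within 1%", {
  ph <- default_phantom()
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  out <- resample_labels(ph$labels, rigid_transform(Rz))
  for (lab in 1:3) {
    n0 <- sum(ph$labels$data == lab)
    n1 <- sum(out$data == lab)
    expect_lt(abs(n1 / n0 - 1), 0.01, label = sprintf("label %d", lab))
  }
})

test_that("resampling rejects bad spacing and empty volumes", {
  ph <- default_phantom()
  expect_error(resample_labels(ph$labels, rigid_transform(diag(3)), spacing = 0),
               "positive")
  empty <- label_volume(array(0L, c(4, 4, 4)), c(1, 1, 1))
  expect_error(resample_labels(empty, rigid_transform(diag(3))), "empty cranium")
})

test_that("aligning a posed phantom reproduces unposed measurements", {
  spec <- random_phantom_spec(seed = 3, pose = random_pose(seed = 103))
  ph <- make_phantom(spec)
  spec0 <- spec
  spec0$pose <- rigid_transform(diag(3))
  m0 <- glance(measure_all(aligned_from(make_phantom(spec0))))
  m1 <- glance(measure_all(align_phantom(ph)))
  co <- ph$truth$components
  expect_lt(abs(m1$ei - m0$ei), 2 / co$ei_den)
  expect_lt(abs(m1$z_evans - m0$z_evans), 2 / co$ze_den)
  expect_lt(abs(m1$ca_deg - m0$ca_deg), 2)
  expect_lt(abs(m1$bvr_pc - m0$bvr_pc), 2 / co$bvr_pc_vent)
})
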