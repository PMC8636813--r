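test_that("the parameter registry carries the printed group values", {
  p <- default_paper_params()
  expect_equal(unlist(param_lookup(p, "NPH", "ca_deg")), c(mean = 57.1, sd = 20.8))
  expect_equal(unlist(param_lookup(p, "HC", "bvr_pc")), c(mean = 3.281, sd = 1.220))
  expect_equal(unlist(param_lookup(p, "NPH", "z_evans")), c(mean = 0.448, sd = 0.056))
  expect_equal(unlist(param_lookup(p, "Responder", "z_evans", "post")),
               c(mean = 0.460, sd = 0.059))
  expect_equal(unname(p$responder_sizes), c(9L, 12L))
  expect_equal(p$responder_fraction, 9 / 21, tolerance = 1e-12)
  expect_equal(unname(p$prevalences["hypertension"]), 17 / 21, tolerance = 1e-12)
  # the anomalous ventricular-component SD is carried verbatim but flagged
  expect_equal(unlist(param_lookup(p, "Responder", "bvr_pc_ventricle_mm", "pre")),
               c(mean = 38.60, sd = 0.490))
  expect_true(any(grepl("0.490", p$flags)))
})

test_that("parameter validation rejects inconsistent inputs", {
  p <- default_paper_params()
  p$rho_within <- 1.2
  expect_error(ventmorph:::validate_cohort_params(p), "rho_within")
  p <- default_paper_params()
  p$baseline$sd[1] <- -1
  expect_error(ventmorph:::validate_cohort_params(p), "positive")
})

test_that("simulation is seed-deterministic", {
  p <- default_paper_params()
  a <- simulate_cohort(p, "baseline", seed = 7)
  b <- simulate_cohort(p, "baseline", seed = 7)
  expect_identical(a, b)
  c2 <- simulate_cohort(p, "baseline", seed = 8)
  expect_false(identical(a, c2))
})

test_that("simulated group means recover the registry parameters (CLT)", {
  p <- default_paper_params()
  p$group_sizes <- c(NPH = 100000L)
  co <- simulate_cohort(p, "baseline", seed = 21)
  mu <- param_lookup(p, "NPH", "ei")
  expect_lt(abs(mean(co$ei) - mu$mean), 3 * mu$sd / sqrt(nrow(co)) + 1e-4)
  mu_z <- param_lookup(p, "NPH", "z_evans")
  expect_lt(abs(mean(co$z_evans) - mu_z$mean), 3 * mu_z$sd / sqrt(nrow(co)) + 1e-4)
  # truncation keeps every draw in range
  expect_true(all(co$ei > 0 & co$ei < 1))
  expect_true(all(co$ca_deg > 0 & co$ca_deg < 180))
})

test_that("zero prevalences give all-zero mFI scores", {
  p <- default_paper_params()
  p$prevalences[] <- 0
  co <- simulate_cohort(p, "baseline", seed = 3)
  scored <- mfi11_score(co)
  expect_true(all(scored$mfi11_score == 0))
})

test_that("impossible truncation signals parameter inconsistency", {
  set.seed(1)
  expect_error(rnorm_trunc(10, mean = -6, sd = 1, lower = 0, upper = 1),
               "parameter inconsistency")
  p <- default_paper_params()
  p$baseline$mean[p$baseline$measure == "ei"] <- -3
  expect_error(simulate_cohort(p, "baseline", seed = 1),
               "parameter inconsistency")
})

test_that("pre/post pairs share the configured within-subject correlation", {
  p <- default_paper_params(rho_within = 0.9)
  p$responder_sizes <- c(`Non-Responder` = 800L)
  co <- simulate_cohort(p, "prepost", seed = 5)
  wide <- tidyr::pivot_wider(co[c("subject_id", "timepoint", "z_evans")],
                             names_from = "timepoint", values_from = "z_evans")
  r <- stats::cor(wide$pre, wide$post)
  expect_gt(r, 0.85)
  expect_lt(r, 0.95)
  # outcome scores agree with the assigned responder label by construction
  cls <- classify_responder(co)
  expect_identical(as.character(cls$responder), as.character(co$true_responder))
})

test_that("power replicates at the printed NPH/AD parameters separate groups", {
  reps <- mw_power_replicates("z_evans", reps = 20, seed = 9)
  expect_equal(nrow(reps), 20)
  expect_true(all(reps$p_value < 0.001))
  # reproducible replicate-by-replicate
  reps2 <- mw_power_replicates("z_evans", reps = 20, seed = 9)
  expect_identical(reps, reps2)
})
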