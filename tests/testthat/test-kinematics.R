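test_that("coefficient of variation matches hand values and is scale invariant", {
  expect_equal(cv_percent(c(1, 3)), 70.7106781, tolerance = 1e-6)
  expect_equal(cv_percent(rep(2.5, 10)), 0)
  withr::with_seed(1, {
    for (i in 1:20) {
      x <- runif(10, 1, 5)
      c_ <- runif(1, 0.1, 10)
      expect_equal(cv_percent(c_ * x), cv_percent(x), tolerance = 1e-10)
    }
  })
  expect_error(cv_percent(c(1)), "at least 2")
  expect_error(cv_percent(c(-1, 1)), "zero mean")
})

test_that("gait asymmetry matches the log-ratio formula and is symmetric", {
  expect_equal(gait_asymmetry(0.37, 0.38), 2.6668, tolerance = 1e-4)
  expect_equal(gait_asymmetry(0.4, 0.4), 0)
  withr::with_seed(2, {
    for (i in 1:20) {
      a <- runif(1, 0.2, 0.6); b <- runif(1, 0.2, 0.6)
      expect_equal(gait_asymmetry(a, b), gait_asymmetry(b, a))
    }
  })
  expect_error(gait_asymmetry(0, 0.4), "positive")
})

test_that("stride intervals reproduce the hand geometry of alternating contacts", {
  # stride 1.10, swing 0.385 -> stance 0.715, dst 0.330
  strikes_l <- seq(0, 11, by = 1.1)
  strikes_r <- strikes_l + 0.55
  evl <- gait_events(strikes_l, strikes_l + 0.715, "left", 100)
  evr <- gait_events(strikes_r, strikes_r + 0.715, "right", 100)
  iv <- stride_intervals(evl, evr)
  expect_equal(unique(round(iv$stance_s, 12)), 0.715)
  expect_equal(unique(round(iv$swing_s, 12)), 0.385)
  dst <- iv$dst_s[!is.na(iv$dst_s)]
  expect_equal(unique(round(dst, 12)), 0.330)
})

test_that("stride intervals match generator ground truth on a synthetic subject", {
  sub <- detect_subject(noisy_profile(duration = 90, noise = 0.01), seed = 6)
  iv <- stride_intervals(sub$events$left, sub$events$right)
  for (side in c("left", "right")) {
    tr <- sub$schedule[[side]]
    m <- iv[iv$side == side, ]
    expect_lt(abs(median(m$stride_s) - median(tr$stride_s)), 0.011)
    expect_lt(abs(median(m$stance_s) - median(tr$stance_s)), 0.011)
    expect_lt(abs(median(m$swing_s) - median(tr$swing_s)), 0.011)
  }
})

test_that("stride intervals require two usable feet", {
  strikes <- seq(0, 11, by = 1.1)
  evl <- gait_events(strikes, strikes + 0.715, "left", 100)
  dead <- gait_events(strikes + 0.55, strikes + 1.26, "right", 100,
                      valid = rep(FALSE, length(strikes)))
  expect_error(stride_intervals(evl, dead), "fewer than 2 valid")
})

test_that("phase follows the normalized contralateral step-timing formula", {
  # reference strikes 0, 1.2; contralateral at 0.5 -> phi = 150
  evl <- gait_events(c(0, 1.2, 2.4, 3.6), c(0.8, 2.0, 3.2, 4.4), "left", 100)
  evr <- gait_events(c(0.5, 1.7, 2.9), c(1.3, 2.5, 3.7), "right", 100)
  # equal swing -> tie broken to left with a warning
  expect_warning(ps <- phase_series(evl, evr), "tie")
  expect_equal(ps$phi[1], 150)
  expect_true(all(ps$phi > 0 & ps$phi < 360))
})

test_that("reference strides without exactly one interior contralateral strike are skipped", {
  evl <- gait_events(c(0, 1.2, 2.4, 3.6, 4.8), c(0.8, 2.0, 3.2, 4.4, 5.6),
                     "left", 100)
  # a missing right strike leaves one reference window with two interior
  # strikes; the right foot's longer swings make it the reference leg
  evr <- gait_events(c(0.6, 3.0, 4.2), c(1.4, 3.8, 5.0), "right", 100)
  ps <- phase_series(evl, evr)
  expect_equal(attr(ps, "reference"), "right")
  expect_equal(attr(ps, "n_skipped"), 1L)
  expect_equal(nrow(ps), 1)
  expect_equal(ps$phi[1], 180)
})

test_that("phase statistics normalize deviation and satisfy the PCI identity", {
  ideal <- phase_stats(rep(180, 10))
  expect_equal(unlist(ideal[c("phi_mean", "phi_cv", "phi_deviation", "pci")]),
               c(phi_mean = 180, phi_cv = 0, phi_deviation = 0, pci = 0))

  alt <- phase_stats(rep(c(170, 190), 25))
  expect_equal(alt$phi_mean, 180)
  expect_equal(alt$phi_deviation, 5.5556, tolerance = 1e-4)
  expect_equal(alt$phi_deviation_deg, 10)

  deg <- phase_stats(rep(c(170, 190), 25), deviation = "degrees")
  expect_equal(deg$phi_deviation, 10)

  withr::with_seed(3, {
    for (i in 1:10) {
      phi <- rnorm(50, 180, 6)
      st <- phase_stats(phi)
      expect_equal(st$pci - (st$phi_cv + st$phi_deviation), 0)
    }
  })
})

test_that("cadence recovers the dominant frequency of the combined GRF", {
  t <- seq(0, 300, by = 0.01)[-1]
  sine <- grf_series(sin(2 * pi * 1.75 * t) + 1.2, 100)
  expect_equal(estimate_cadence(sine), 1.75, tolerance = 1 / 300 + 1e-9)

  sub <- detect_subject(zero_var_profile(duration = 67), seed = 1)
  cad <- estimate_cadence(moving_average(sub$grf$left, 5),
                          moving_average(sub$grf$right, 5))
  expect_equal(cad, 2 / 1.10, tolerance = 2 / 67)

  expect_error(estimate_cadence(grf_series(rep(1, 6000), 100)), "constant")
})

test_that("spatial estimates follow displacement / duration and / step count", {
  sp <- spatial_estimates(524.5, 300, 377.3)
  expect_equal(sp$speed_m_s, 1.2577, tolerance = 1e-4)
  expect_equal(round(sp$speed_m_s, 2), 1.26)
  expect_equal(sp$step_length_m, 0.7194, tolerance = 1e-4)
  expect_equal(round(sp$step_length_m, 2), 0.72)
  expect_error(spatial_estimates(0, 300, 377.3), "positive")
})

test_that("the assembled kinematic set has exactly the 28 named parameters", {
  sub <- detect_subject(noisy_profile(duration = 60), seed = 2)
  iv <- stride_intervals(sub$events$left, sub$events$right)
  ph <- phase_stats(phase_series(sub$events$left, sub$events$right))
  kin <- assemble_kinematics(iv, ph, 1.8, n_steps = 100, duration_s = 60,
                             distance_m = 75)
  expect_equal(names(kin), kinematic_parameter_names())
  expect_equal(ncol(kin), 28)
  # stance and swing percentages partition the stride
  expect_lt(abs(kin[["R PST"]] + kin[["R PSWT"]] - 100), 0.5)
  expect_lt(abs(kin[["L PST"]] + kin[["L PSWT"]] - 100), 0.5)
  expect_error(assemble_kinematics(iv, ph, NA_real_, 100, 60, 75),
               "cadence_hz")
})

test_that("a zero-variance subject yields zero variability, asymmetry and PCI", {
  sub <- detect_subject(zero_var_profile(stride = 1.10, swing = 0.385,
                                         duration = 45), seed = 1)
  iv <- stride_intervals(sub$events$left, sub$events$right)
  ph <- suppressWarnings(phase_stats(phase_series(sub$events$left,
                                                  sub$events$right)))
  kin <- assemble_kinematics(iv, ph, 2 / 1.1, n_steps = 80, duration_s = 45,
                             distance_m = 50)
  for (cv in c("R stride time CV", "L stride time CV", "R stance time CV",
               "L stance time CV", "R swing time CV", "L swing time CV",
               "DST CV", "phi CV")) {
    expect_equal(kin[[cv]], 0)
  }
  expect_equal(kin[["GA"]], 0, tolerance = 1e-10)
  expect_equal(kin[["PCI"]], 0, tolerance = 1e-10)
  expect_equal(kin[["phi"]], 180, tolerance = 1e-10)
})

test_that("GA and PCI are invariant under left/right relabeling", {
  prof <- noisy_profile(duration = 60)
  prof$swing_time_mean_s <- c(left = 0.395, right = 0.375)
  sub <- detect_subject(prof, seed = 8)
  iv1 <- stride_intervals(sub$events$left, sub$events$right)
  ph1 <- phase_stats(phase_series(sub$events$left, sub$events$right))
  swapped_l <- sub$events$right
  swapped_l$side <- "left"
  swapped_r <- sub$events$left
  swapped_r$side <- "right"
  iv2 <- stride_intervals(swapped_l, swapped_r)
  ph2 <- phase_stats(phase_series(swapped_l, swapped_r))
  ga1 <- gait_asymmetry(mean(iv1$swing_s[iv1$side == "left"]),
                        mean(iv1$swing_s[iv1$side == "right"]))
  ga2 <- gait_asymmetry(mean(iv2$swing_s[iv2$side == "left"]),
                        mean(iv2$swing_s[iv2$side == "right"]))
  expect_equal(ga1, ga2)
  expect_equal(ph1$pci, ph2$pci)
})
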