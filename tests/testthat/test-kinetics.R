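test_that("segmentation normalizes Newtons by body weight", {
  # constant 700 N plateau, weight 71.36 kg -> 700 / (71.36 * 9.81) = 1.00
  plateau <- c(rep(0, 40), rep(700, 70), rep(0, 40), rep(700, 70), rep(0, 40))
  s <- grf_series(plateau, 100, units = "N")
  ev <- gait_events(c(0.40, 1.50), c(1.09, 2.19), "left", 100)
  cyc <- segment_stance_cycles(s, ev, weight_kg = 71.36)
  mid <- cyc$force_bw[cyc$stance_pct > 10 & cyc$stance_pct < 90]
  expect_equal(unique(round(mid, 4)), 1.00, tolerance = 1e-3)
  expect_error(segment_stance_cycles(s, ev), "weight_kg")
})

test_that("noise-free resampled cycles stay within 2% of the template", {
  # stance = 0.70 s is an integer number of samples at 100 Hz, so the crop
  # aligns exactly; half-sample stances shift the steep edges by up to 5%
  sub <- detect_subject(zero_var_profile(stride = 1.10, swing = 0.40,
                                         duration = 40), seed = 1)
  cyc <- segment_stance_cycles(sub$grf$left, sub$events$left, weight_kg = 70)
  grid <- seq(0, 1, length.out = 101)
  tmpl <- insolegait:::stance_template_at(grid, c(0.26, 0.46, 0.74),
                                          c(0.95, 0.62, 1.10))
  one <- cyc$force_bw[cyc$cycle == cyc$cycle[150]]
  expect_lt(max(abs(one - tmpl)), 0.02 * max(tmpl))
})

test_that("zero usable strides yields an empty cycle set with a warning", {
  s <- grf_series(rep(0, 300) + 1, 100, units = "bw")
  ev <- gait_events(c(0.1, 1.2), c(0.8, 1.9), "left", 100,
                    valid = c(FALSE, FALSE))
  expect_warning(cyc <- segment_stance_cycles(s, ev), "No usable")
  expect_equal(nrow(cyc), 0)
})

test_that("M-shape extraction recovers the template landmarks and rejects non-M cycles", {
  grid <- seq(0, 1, length.out = 101)
  y <- insolegait:::stance_template_at(grid, c(0.26, 0.46, 0.74),
                                       c(1.0, 0.6, 1.1))
  m <- extract_m_shape(y)
  expect_true(m$usable)
  expect_equal(m$hpf, 1.0, tolerance = 0.01)
  expect_equal(m$msf, 0.6, tolerance = 0.01)
  expect_equal(m$tof, 1.1, tolerance = 0.01)
  expect_equal(m$hpt, 26, tolerance = 1)
  expect_equal(m$mst, 46, tolerance = 1)
  expect_equal(m$tot, 74, tolerance = 1)
  expect_true(m$hpt < m$mst && m$mst < m$tot)

  # monotone triangle: no M-shape
  tri <- c(seq(0, 1, length.out = 51), seq(1, 0, length.out = 50))
  expect_false(extract_m_shape(tri)$usable)
  expect_false(extract_m_shape(seq(0, 1, length.out = 101))$usable)
  expect_false(extract_m_shape(rep(0.5, 101))$usable)
})

test_that("average cycle is the pointwise mean", {
  sub <- detect_subject(zero_var_profile(duration = 40), seed = 1)
  cyc <- segment_stance_cycles(sub$grf$left, sub$events$left, weight_kg = 70)
  avg <- average_cycle(cyc)
  expect_equal(nrow(avg), 101)
  one <- cyc$force_bw[cyc$cycle == unique(cyc$cycle)[1]]
  expect_equal(avg$force_bw, one, tolerance = 1e-9) # identical cycles

  # linearity: mean of c and 2c is 1.5c
  two <- cyc
  two$force_bw <- 2 * two$force_bw
  both <- dplyr::bind_rows(cyc, two)
  both$cycle <- rep(seq_len(nrow(both) / 101), each = 101)
  class(both) <- class(cyc)
  expect_equal(average_cycle(both)$force_bw, 1.5 * one, tolerance = 1e-9)
})

test_that("the assembled kinetic set has exactly the 24 named parameters", {
  sub <- detect_subject(noisy_profile(duration = 60), seed = 4)
  feats <- lapply(c(left = "left", right = "right"), function(sd_) {
    m_shape_features(segment_stance_cycles(sub$grf[[sd_]], sub$events[[sd_]],
                                           weight_kg = 70))
  })
  knt <- assemble_kinetics(feats$left, feats$right)
  expect_equal(names(knt), kinetic_parameter_names())
  expect_equal(ncol(knt), 24)
  # time landmarks are ordered and inside (0, 100)
  expect_true(knt[["R HPT"]] < knt[["R MST"]])
  expect_true(knt[["R MST"]] < knt[["R TOT"]])
  expect_true(all(unlist(knt[c("R HPT", "R TOT", "L HPT", "L TOT")]) > 0))
  expect_true(all(unlist(knt[c("R HPT", "R TOT", "L HPT", "L TOT")]) < 100))
})

test_that("a zero-noise subject has zero kinetic variability", {
  sub <- detect_subject(zero_var_profile(duration = 45), seed = 1)
  feats <- lapply(c(left = "left", right = "right"), function(sd_) {
    m_shape_features(segment_stance_cycles(sub$grf[[sd_]], sub$events[[sd_]],
                                           weight_kg = 70))
  })
  knt <- assemble_kinetics(feats$left, feats$right)
  for (cv in grep(" CV$", kinetic_parameter_names(), value = TRUE)) {
    expect_equal(knt[[cv]], 0, tolerance = 1e-8)
  }
})

test_that("doubling body weight halves force fields and leaves times unchanged", {
  sub <- detect_subject(noisy_profile(duration = 60, noise = 0), seed = 5)
  run <- function(w) {
    feats <- lapply(c(left = "left", right = "right"), function(sd_) {
      m_shape_features(segment_stance_cycles(sub$grf[[sd_]], sub$events[[sd_]],
                                             weight_kg = w))
    })
    assemble_kinetics(feats$left, feats$right)
  }
  k1 <- run(70)
  k2 <- run(140)
  for (f in c("R HPF", "L HPF", "R MSF", "L MSF", "R TOF", "L TOF")) {
    expect_equal(k2[[f]], k1[[f]] / 2, tolerance = 1e-9)
  }
  for (tm in c("R HPT", "L HPT", "R MST", "L MST", "R TOT", "L TOT")) {
    expect_equal(k2[[tm]], k1[[tm]], tolerance = 1e-9)
  }
})

test_that("per-cycle ordering invariant holds on noisy cohort cycles", {
  sub <- detect_subject(noisy_profile(duration = 90, noise = 0.02), seed = 6)
  mf <- m_shape_features(segment_stance_cycles(sub$grf$left, sub$events$left,
                                               weight_kg = 70))
  ok <- mf[mf$usable, ]
  expect_gt(nrow(ok), 0.9 * nrow(mf))
  expect_true(all(ok$hpt < ok$mst & ok$mst < ok$tot))
  expect_true(all(ok$msf < pmin(ok$hpf, ok$tof)))
})
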