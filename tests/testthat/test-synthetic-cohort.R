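test_that("zero-variance schedules are exactly periodic with midway contralateral strikes", {
  prof <- zero_var_profile(stride = 1.10, swing = 0.385, duration = 40)
  sch <- generate_stride_schedule(prof, seed = 1)
  expect_equal(unique(sch$left$stride_s), 1.10)
  expect_equal(unique(round(diff(sch$left$strike_s), 12)), 1.10)
  offsets <- sch$right$strike_s - sch$left$strike_s[seq_len(nrow(sch$right))]
  expect_equal(unique(round(offsets, 12)), 0.55)
  # hand geometry: stance 0.715, dst = 2 * (0.715 - 0.550) = 0.330 per stride
  expect_equal(unique(sch$left$stance_s), 0.715)
  dst <- sch$left$dst_s[!is.na(sch$left$dst_s)]
  expect_equal(unique(round(dst, 12)), 0.330)
})

test_that("identical (profile, seed) give identical schedules and cohorts", {
  prof <- noisy_profile(duration = 40, turn_every = 12)
  s1 <- generate_stride_schedule(prof, seed = 42)
  s2 <- generate_stride_schedule(prof, seed = 42)
  expect_identical(s1$left, s2$left)
  expect_identical(s1$right, s2$right)
  c1 <- generate_cohort(n_yc = 2, n_amc = 0, n_pd = 1,
                        profiles = short_profiles(40), seed = 5)
  c2 <- generate_cohort(n_yc = 2, n_amc = 0, n_pd = 1,
                        profiles = short_profiles(40), seed = 5)
  expect_identical(c1$subjects, c2$subjects)
  expect_identical(c1$grf[[1]]$left$force, c2$grf[[1]]$left$force)
})

test_that("realized phase noise matches the profile's stated spread", {
  prof <- zero_var_profile(stride = 1.10, swing = 0.385,
                           duration = 250 * 1.10 + 3)
  prof$phase_sd_deg <- 5
  sch <- generate_stride_schedule(prof, seed = 11)
  phi <- 360 * (sch$right$strike_s - sch$left$strike_s[seq_len(nrow(sch$right))]) /
    sch$left$stride_s[seq_len(nrow(sch$right))]
  expect_gt(nrow(sch$left), 249)
  expect_lt(abs(sd(phi) - 5) / 5, 0.20)
  expect_lt(abs(mean(phi) - 180), 1)
})

test_that("infeasible profiles are rejected with informative errors", {
  expect_error(gait_profile("YC", swing_time_mean_s = 1.2,
                            stride_time_mean_s = 1.1),
               "swing time must be shorter")
  expect_error(gait_profile("YC", stride_time_mean_s = 1.1,
                            swing_time_mean_s = 0.7, phase_offset_deg = 180),
               "double support would be negative")
  expect_error(gait_profile("YC", peak_magnitudes_bw = c(1, 1, 1)),
               "not a valley")
  expect_error(gait_profile("YC", landmark_fractions = c(0.5, 0.4, 0.7)),
               "strictly increasing")
})

test_that("stance curve has the M-shape: extrema exactly at landmarks, magnitudes exact", {
  lm <- c(0.26, 0.46, 0.74)
  pk <- c(1.0, 0.6, 1.1)
  y <- synth_stance_curve(0.7, lm, pk, 100)
  n <- length(y) - 1 # 70 intervals
  expect_equal(n, 70)
  expect_equal(y[1], 0)
  expect_equal(y[length(y)], 0)
  expect_true(all(y >= 0))
  expect_gt(sum(y), 0)
  # extrema at round(f * n) in 0-based sample units
  expect_equal(which.max(y[1:36]) - 1, round(0.26 * 70))
  i_hp <- which.max(y[1:36])
  i_to <- which.max(y[36:length(y)]) + 35
  expect_equal(i_to - 1, round(0.74 * 70))
  i_ms <- which.min(y[i_hp:i_to]) + i_hp - 1
  expect_equal(i_ms - 1, round(0.46 * 70))
  # magnitudes within 1%
  expect_lt(abs(y[i_hp] - 1.0), 0.01)
  expect_lt(abs(y[i_ms] - 0.6), 0.01)
  expect_lt(abs(y[i_to] - 1.1), 0.01)
  # exactly two interior local maxima and one interior local minimum
  sign_changes <- diff(sign(diff(y)))
  expect_equal(sum(sign_changes < 0), 2)
  expect_equal(sum(sign_changes > 0), 1)
})

test_that("stance curve rejects degenerate requests", {
  expect_error(synth_stance_curve(0.7, peaks = c(1, 1, 1)), "valley")
  expect_error(synth_stance_curve(0.03, sampling_rate_hz = 100),
               "shorter than 5 samples")
})

test_that("cohorts have the right shape and clinical fields only for patients", {
  coh <- generate_cohort(n_yc = 3, n_amc = 2, n_pd = 2,
                         profiles = short_profiles(40), seed = 3)
  expect_equal(nrow(coh$subjects), 7)
  expect_length(coh$grf, 7)
  expect_length(unlist(coh$grf, recursive = FALSE), 14)
  expect_true(all(is.na(coh$subjects$updrs_iii[coh$subjects$group != "PD"])))
  expect_true(all(!is.na(coh$subjects$updrs_iii[coh$subjects$group == "PD"])))
  expect_equal(coh$subjects$bmi_kg_m2,
               round(coh$subjects$weight_kg / coh$subjects$height_m^2, 2))

  no_pd <- generate_cohort(n_yc = 2, n_amc = 2, n_pd = 0,
                           profiles = short_profiles(40), seed = 3)
  expect_false(any(c("updrs_iii", "mmse", "ledd_mg", "disease_duration_years",
                     "affected_side") %in% names(no_pd$subjects)))
})

test_that("ground truth is self-consistent with the emitted schedule", {
  prof <- noisy_profile(duration = 60, turn_every = 15)
  sch <- generate_stride_schedule(prof, seed = 9)
  for (tab in list(sch$left, sch$right)) {
    expect_equal(tab$stride_s[-nrow(tab)], diff(tab$strike_s))
    expect_equal(tab$stance_s, tab$toe_off_s - tab$strike_s)
    expect_equal(tab$swing_s, tab$stride_s - tab$stance_s)
    expect_true(all(diff(tab$strike_s) > 0))
  }
  expect_true(all(sch$turn_strides$left %in% seq_len(nrow(sch$left))))
})

test_that("doubling double-support jitter raises downstream DST CV in nearly all replicates", {
  base <- noisy_profile(duration = 90)
  hi <- base
  hi$double_support_sd_s <- 2 * base$double_support_sd_s + 0.012
  higher <- vapply(1:20, function(s) {
    cv_of <- function(p) {
      sub <- detect_subject(p, seed = s, noise_seed = 100 + s)
      iv <- stride_intervals(sub$events$left, sub$events$right)
      dst <- iv$dst_s[iv$side == "left"]
      cv_percent(dst[!is.na(dst)])
    }
    cv_of(hi) > cv_of(base)
  }, logical(1))
  expect_gte(mean(higher), 0.90)
})

test_that("written cohorts round-trip through the plain-text formats", {
  coh <- generate_cohort(n_yc = 1, n_amc = 0, n_pd = 1,
                         profiles = short_profiles(40), seed = 2)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  man <- read_subject_table(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 2)
  id <- coh$subjects$subject_id[1]
  back <- read_grf_csv(file.path(dir, sprintf("grf_%s_left.csv", id)),
                       side = "left")
  expect_equal(back$force, coh$grf[[id]]$left$force, tolerance = 1e-9)
  truth <- jsonlite::read_json(file.path(dir, sprintf("truth_%s.json", id)))
  expect_equal(length(truth$left$strike_s), nrow(coh$truth[[id]]$schedule$left))
})
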