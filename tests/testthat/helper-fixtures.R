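# Fixture builders shared across the suite. All synthetic, built in code.

# A deterministic profile: zero stride-to-stride variance, no noise, no turns.
zero_var_profile <- function(stride = 1.10, swing = 0.385, duration = 67,
                             phase = 180, fs = 100,
                             landmarks = c(0.26, 0.46, 0.74),
                             peaks = c(0.95, 0.62, 1.10)) {
  gait_profile(
    "YC",
    stride_time_mean_s = stride, stride_time_sd_s = 0,
    swing_time_mean_s = swing, swing_time_sd_s = 0,
    double_support_sd_s = 0, phase_offset_deg = phase, phase_sd_deg = 0,
    phase_offset_subject_sd_deg = 0, landmark_fractions = landmarks,
    peak_magnitudes_bw = peaks, noise_sd_bw = 0, sampling_rate_hz = fs,
    duration_s = duration, turn_every_n_strides = Inf
  )
}

# A realistic noisy profile for shorter recordings.
noisy_profile <- function(duration = 120, noise = 0.02,
                          turn_every = Inf, stride = 1.10, swing = 0.385,
                          stride_sd = 0.025, swing_sd = 0.010) {
  gait_profile(
    "YC",
    stride_time_mean_s = stride, stride_time_sd_s = stride_sd,
    swing_time_mean_s = swing, swing_time_sd_s = swing_sd,
    double_support_sd_s = 0.004, phase_offset_deg = 180, phase_sd_deg = 1.2,
    phase_offset_subject_sd_deg = 0, noise_sd_bw = noise,
    duration_s = duration, turn_every_n_strides = turn_every
  )
}

# Short-duration copies of the default group profiles (for cohort-shape
# tests where the full 5-min recordings are unnecessary).
short_profiles <- function(duration = 60) {
  lapply(default_profiles(), function(p) {
    p$duration_s <- duration
    p
  })
}

# Synthesize one subject and run detection on both feet.
detect_subject <- function(profile, seed = 1, noise_seed = 2, weight = 70,
                           config = pipeline_config()) {
  sched <- generate_stride_schedule(profile, seed = seed)
  sig <- synthesize_grf(sched, profile, weight_kg = weight, seed = noise_seed)
  ev <- lapply(sig, function(s) {
    suppressWarnings(remove_outlier_strides(
      detect_contacts(moving_average(s, config$smooth_window),
                      config$contact_threshold_frac),
      window = config$outlier_window, mad_factor = config$mad_factor
    ))
  })
  list(schedule = sched, grf = sig, events = ev)
}

# Align detected events to the truth schedule (detection drops strides
# truncated by the recording edges) and return per-event errors in samples.
event_errors <- function(events, truth_tab, fs = 100) {
  align <- which.min(abs(truth_tab$strike_s - events$foot_strike_s[1]))
  n <- min(nrow(events), nrow(truth_tab) - align + 1)
  idx <- align:(align + n - 1)
  list(
    strike = (events$foot_strike_s[1:n] - truth_tab$strike_s[idx]) * fs,
    toe = (events$toe_off_s[1:n] - truth_tab$toe_off_s[idx]) * fs,
    truth_idx = idx
  )
}

# --- independent oracles -------------------------------------------------

# Rank-based Kruskal-Wallis statistic, written from the definition with
# average ranks and tie correction.
kw_oracle <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(ri) sum(ri)^2 / length(ri))) - 3 * (N + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# ReliefF (classification) by exhaustive plain loops.
relieff_oracle_cls <- function(X, y, k) {
  y <- factor(y)
  m <- nrow(X); p <- ncol(X)
  rng <- apply(X, 2, function(v) diff(range(v)))
  rng[rng == 0] <- 1
  dif <- function(i, j) abs(X[i, ] - X[j, ]) / rng
  prior <- table(y) / m
  W <- numeric(p)
  for (i in seq_len(m)) {
    d <- vapply(seq_len(m), function(j) sum(dif(i, j)), numeric(1))
    ord <- order(d, seq_len(m))
    ord <- ord[ord != i]
    same <- ord[y[ord] == y[i]]
    hits <- same[seq_len(min(k, length(same)))]
    hc <- numeric(p)
    for (h in hits) hc <- hc + dif(i, h)
    W <- W - hc / (m * length(hits))
    for (cl in levels(y)[levels(y) != y[i]]) {
      others <- ord[y[ord] == cl]
      ms <- others[seq_len(min(k, length(others)))]
      if (length(ms) == 0) next
      mc <- numeric(p)
      for (h in ms) mc <- mc + dif(i, h)
      W <- W + (prior[[cl]] / (1 - prior[[as.character(y[i])]])) *
        mc / (m * length(ms))
    }
  }
  W
}

# RReliefF (regression) by exhaustive plain loops, exponential rank weights.
relieff_oracle_reg <- function(X, y, k, sigma = k) {
  m <- nrow(X); p <- ncol(X)
  rng <- apply(X, 2, function(v) diff(range(v)))
  rng[rng == 0] <- 1
  dif <- function(i, j) abs(X[i, ] - X[j, ]) / rng
  y_rng <- diff(range(y))
  n_dy <- 0; n_df <- numeric(p); n_dy_df <- numeric(p); total <- 0
  for (i in seq_len(m)) {
    d <- vapply(seq_len(m), function(j) sum(dif(i, j)), numeric(1))
    ord <- order(d, seq_len(m))
    ord <- ord[ord != i]
    nb <- ord[seq_len(min(k, length(ord)))]
    wt <- exp(-(seq_along(nb) / sigma)^2)
    wt <- wt / sum(wt)
    for (jj in seq_along(nb)) {
      dy <- abs(y[i] - y[nb[jj]]) / y_rng
      dfv <- dif(i, nb[jj])
      n_dy <- n_dy + wt[jj] * dy
      n_df <- n_df + wt[jj] * dfv
      n_dy_df <- n_dy_df + wt[jj] * dy * dfv
    }
    total <- total + 1
  }
  n_dy_df / n_dy - (n_df - n_dy_df) / (total - n_dy)
}

# Linear discriminant scores from the closed form, via solve().
lda_scores_oracle <- function(X, y, newx) {
  y <- factor(y)
  mu <- t(vapply(levels(y), function(cl)
    colMeans(X[y == cl, , drop = FALSE]), numeric(ncol(X))))
  ctr <- X - mu[as.integer(y), , drop = FALSE]
  S <- crossprod(ctr) / (nrow(X) - nlevels(y))
  Sinv <- solve(S)
  pri <- as.numeric(table(y)) / nrow(X)
  t(vapply(seq_len(nrow(newx)), function(i) {
    x <- newx[i, ]
    vapply(seq_len(nlevels(y)), function(kk) {
      drop(x %*% Sinv %*% mu[kk, ] - 0.5 * mu[kk, ] %*% Sinv %*% mu[kk, ] +
             log(pri[kk]))
    }, numeric(1))
  }, numeric(nlevels(y))))
}
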