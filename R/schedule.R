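#' Generate a per-leg gait event schedule from a profile
#'
#' Draws a full sequence of foot-strike and toe-off times for both legs under
#' the profile's stochastic timing model. Left-leg stride durations are drawn
#' first; right-leg foot-strikes are placed within each left stride at the
#' profile's phase offset plus phase noise, so that bilateral phase and
#' double-support variability are independently controllable. Turn artifacts
#' (stride duration inflated by a factor drawn from U(1.5, 2.5), force later
#' scaled by 0.8) are injected every `turn_every_n_strides` left strides.
#'
#' With all standard deviations zero the schedule is exactly periodic:
#' stride durations equal the nominal means and contralateral strikes sit at
#' exactly `phase_offset_deg / 360` of each stride.
#'
#' @param profile A [gait_profile()].
#' @param seed Optional integer seed; identical `(profile, seed)` pairs yield
#'   identical schedules. The caller's RNG state is left untouched.
#' @param phase_offset_deg Override of the profile's phase set-point (used by
#'   the cohort generator to give each subject their own set-point).
#' @return An object of class `stride_schedule`: a list with `left` and
#'   `right` tibbles (columns `stride`, `strike_s`, `toe_off_s`, `stride_s`,
#'   `stance_s`, `swing_s`, `dst_s`, `turn`), the turn indices per leg, and
#'   the profile used. Event times are exact (not snapped to the sample grid).
#' @export
generate_stride_schedule <- function(profile, seed = NULL,
                                     phase_offset_deg = NULL) {
  validate_gait_profile(profile)
  p <- profile
  offset <- phase_offset_deg %||% p$phase_offset_deg
  with_rng_seed(seed, {
    n <- ceiling(p$duration_s / min(p$stride_time_mean_s)) + 2L

    # left leg stride durations, with turn inflation
    s_l <- rnorm_trunc(n, p$stride_time_mean_s["left"], p$stride_time_sd_s["left"],
                       lower = 0.4 * p$stride_time_mean_s["left"])
    turn_idx <- integer(0)
    if (is.finite(p$turn_every_n_strides)) {
      turn_idx <- seq(p$turn_every_n_strides, n - 1L, by = p$turn_every_n_strides)
      s_l[turn_idx] <- s_l[turn_idx] * stats::runif(length(turn_idx), 1.5, 2.5)
    }
    strike_l <- cumsum(c(0, s_l))[seq_len(n)]
    stride_l <- s_l

    # left stances: stride - swing, plus double-support jitter on toe-off.
    # Swing scales proportionally with the realized stride (tempo
    # fluctuations stretch the whole cycle) plus an additive residual, so
    # stride-time variation does not couple fully into double support.
    frac_l <- p$swing_time_mean_s["left"] / p$stride_time_mean_s["left"]
    swing_l <- rnorm_trunc(n, frac_l * s_l, p$swing_time_sd_s["left"],
                           lower = 0.1 * p$swing_time_mean_s["left"])
    ds_jit_l <- if (p$double_support_sd_s > 0) {
      stats::rnorm(n, 0, p$double_support_sd_s / sqrt(2))
    } else numeric(n)
    stance_l <- pmin(pmax(stride_l - swing_l + ds_jit_l, 0.55 * stride_l),
                     0.95 * stride_l)

    # right strikes placed within left strides at phase offset + noise
    eps <- if (p$phase_sd_deg > 0) stats::rnorm(n, 0, p$phase_sd_deg) else numeric(n)
    strike_r <- strike_l + (offset + eps) / 360 * stride_l

    stride_r <- diff(strike_r)
    n_r <- length(stride_r)
    # the realized right-stride mean equals the left one (right strikes are
    # interleaved within left strides), so the left stride mean is the
    # denominator for both legs' swing fractions — otherwise the intended
    # swing asymmetry would be distorted by the nominal stride difference
    frac_r <- p$swing_time_mean_s["right"] / p$stride_time_mean_s["left"]
    swing_r <- rnorm_trunc(n_r, frac_r * stride_r, p$swing_time_sd_s["right"],
                           lower = 0.1 * p$swing_time_mean_s["right"])
    ds_jit_r <- if (p$double_support_sd_s > 0) {
      stats::rnorm(n_r, 0, p$double_support_sd_s / sqrt(2))
    } else numeric(n_r)
    stance_r <- pmin(pmax(stride_r - swing_r + ds_jit_r, 0.55 * stride_r),
                     0.95 * stride_r)

    # trim to recording duration
    keep_l <- strike_l + stride_l <= p$duration_s
    keep_r <- strike_r[seq_len(n_r)] + stride_r <= p$duration_s

    left <- tibble::tibble(
      stride = seq_len(sum(keep_l)),
      strike_s = strike_l[keep_l],
      toe_off_s = (strike_l + stance_l)[keep_l],
      stride_s = stride_l[keep_l],
      stance_s = stance_l[keep_l],
      swing_s = (stride_l - stance_l)[keep_l],
      turn = seq_len(n)[keep_l] %in% turn_idx
    )
    right <- tibble::tibble(
      stride = seq_len(sum(keep_r)),
      strike_s = strike_r[seq_len(n_r)][keep_r],
      toe_off_s = (strike_r[seq_len(n_r)] + stance_r)[keep_r],
      stride_s = stride_r[keep_r],
      stance_s = stance_r[keep_r],
      swing_s = (stride_r - stance_r)[keep_r],
      # a turn in left stride i perturbs right strides i-1 and i
      turn = seq_len(n_r)[keep_r] %in% unique(c(turn_idx - 1L, turn_idx))
    )
    left$dst_s <- schedule_dst(left, right)
    right$dst_s <- schedule_dst(right, left)

    structure(list(
      left = left, right = right,
      turn_strides = list(left = which(left$turn), right = which(right$turn)),
      profile = p, phase_offset_deg = offset, seed = seed
    ), class = "stride_schedule")
  })
}

# True double-support time per stride of `ref`: total bilateral-contact time
# within each stride window [strike_i, strike_{i+1}), i.e. the sum of the
# overlaps between the reference foot's contact and all contralateral
# contacts, clipped to the window.
schedule_dst <- function(ref, other) {
  n <- nrow(ref)
  dst <- rep(NA_real_, n)
  if (n < 2 || nrow(other) == 0) return(dst)
  for (i in seq_len(n - 1)) {
    w0 <- ref$strike_s[i]; w1 <- ref$strike_s[i + 1]
    c0 <- w0; c1 <- min(ref$toe_off_s[i], w1)
    lo <- pmax(pmax(other$strike_s, c0), w0)
    hi <- pmin(pmin(other$toe_off_s, c1), w1)
    seg <- pmax(hi - lo, 0)
    # normal alternating gait has exactly two bilateral-contact segments per
    # stride window; anything else (recording edges) is left undefined
    if (sum(seg > 0) == 2) dst[i] <- sum(seg)
  }
  dst
}

#' @export
print.stride_schedule <- function(x, ...) {
  cat(sprintf(
    "<stride_schedule: %d left / %d right strides, %d turns, phase %.1f deg>\n",
    nrow(x$left), nrow(x$right), length(x$turn_strides$left), x$phase_offset_deg
  ))
  invisible(x)
}
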