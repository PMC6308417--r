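#' Gait profile for the synthetic cohort generator
#'
#' A gait profile holds the generative parameters for one group's free-walking
#' pattern: per-leg stride and swing timing (mean and stride-to-stride sd),
#' double-support jitter, bilateral phase target and spread, the M-shape
#' landmark template of the stance ground-reaction-force curve, measurement
#' noise, and recording geometry (duration, sampling rate, walkway length and
#' turn spacing).
#'
#' Timing parameters are in seconds, phase in degrees, forces in fractions of
#' body weight (BW). `landmark_fractions` are the heel-peak, mid-stance-valley
#' and toe-off-peak times as fractions of stance; `peak_magnitudes_bw` their
#' magnitudes. `phase_offset_subject_sd_deg` is the between-subject spread of
#' each subject's own phase set-point (within-subject stride-to-stride phase
#' noise is `phase_sd_deg`).
#'
#' @param group_label One of `"YC"`, `"AMC"`, `"PD"` (young controls,
#'   age-matched controls, Parkinson's disease patients).
#' @param stride_time_mean_s,stride_time_sd_s Per-leg stride time mean/sd;
#'   a scalar is recycled to both legs, or a named `c(left=, right=)` pair.
#' @param swing_time_mean_s,swing_time_sd_s Per-leg swing time mean/sd.
#' @param double_support_sd_s Extra jitter (s) applied to each toe-off,
#'   controlling double-support-time variability independently of phase.
#' @param phase_offset_deg Target mean bilateral phase (180 = ideal alternation).
#' @param phase_sd_deg Within-subject stride-to-stride phase noise sd (degrees).
#' @param phase_offset_subject_sd_deg Between-subject sd of the phase set-point.
#' @param phase_offset_lateral_deg Magnitude of a consistent lateralized phase
#'   shift (degrees): each subject's set-point is displaced from
#'   `phase_offset_deg` by `sign * (lateral + |N(0, subject sd)|)` with a
#'   random sign, emulating a lateralized deficit (asymmetric clinical
#'   onset). 0 (default) gives plain Gaussian set-points.
#' @param landmark_fractions Length-3 increasing vector in (0, 1).
#' @param peak_magnitudes_bw Length-3 vector (HPF, MSF, TOF) in BW fractions;
#'   the mid-stance value must be below both peaks.
#' @param noise_sd_bw Additive Gaussian measurement noise sd, in BW.
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param duration_s Recording duration (s).
#' @param walkway_length_m Walkway length (m), used for the distance estimate.
#' @param turn_every_n_strides Inject a turn artifact every this many strides;
#'   `Inf` disables turns.
#' @return An object of class `gait_profile` (a named list).
#' @seealso [default_profiles()], [generate_cohort()]
#' @export
gait_profile <- function(group_label = c("YC", "AMC", "PD"),
                         stride_time_mean_s = 1.13,
                         stride_time_sd_s = 0.027,
                         swing_time_mean_s = 0.38,
                         swing_time_sd_s = 0.010,
                         double_support_sd_s = 0.004,
                         phase_offset_deg = 180,
                         phase_sd_deg = 2.4,
                         phase_offset_subject_sd_deg = 2,
                         phase_offset_lateral_deg = 0,
                         landmark_fractions = c(0.26, 0.46, 0.74),
                         peak_magnitudes_bw = c(0.95, 0.62, 1.10),
                         noise_sd_bw = 0.02,
                         sampling_rate_hz = 100,
                         duration_s = 300,
                         walkway_length_m = 25,
                         turn_every_n_strides = 17) {
  group_label <- match.arg(group_label)
  profile <- structure(list(
    group_label = group_label,
    stride_time_mean_s = as_leg_pair(stride_time_mean_s, "stride_time_mean_s"),
    stride_time_sd_s = as_leg_pair(stride_time_sd_s, "stride_time_sd_s"),
    swing_time_mean_s = as_leg_pair(swing_time_mean_s, "swing_time_mean_s"),
    swing_time_sd_s = as_leg_pair(swing_time_sd_s, "swing_time_sd_s"),
    double_support_sd_s = double_support_sd_s,
    phase_offset_deg = phase_offset_deg,
    phase_sd_deg = phase_sd_deg,
    phase_offset_subject_sd_deg = phase_offset_subject_sd_deg,
    phase_offset_lateral_deg = phase_offset_lateral_deg,
    landmark_fractions = unname(landmark_fractions),
    peak_magnitudes_bw = unname(peak_magnitudes_bw),
    noise_sd_bw = noise_sd_bw,
    sampling_rate_hz = sampling_rate_hz,
    duration_s = duration_s,
    walkway_length_m = walkway_length_m,
    turn_every_n_strides = turn_every_n_strides
  ), class = "gait_profile")
  validate_gait_profile(profile)
}

validate_gait_profile <- function(profile) {
  p <- profile
  stopifnot_scalar_pos(p$sampling_rate_hz, "sampling_rate_hz")
  stopifnot_scalar_pos(p$duration_s, "duration_s")
  stopifnot_scalar_pos(p$walkway_length_m, "walkway_length_m")
  if (any(p$stride_time_mean_s <= 0) || any(p$swing_time_mean_s <= 0)) {
    abort("Stride and swing time means must be positive.")
  }
  if (any(p$stride_time_sd_s < 0) || any(p$swing_time_sd_s < 0) ||
      p$double_support_sd_s < 0 || p$phase_sd_deg < 0 ||
      p$phase_offset_subject_sd_deg < 0 || p$phase_offset_lateral_deg < 0 ||
      p$noise_sd_bw < 0) {
    abort("Standard deviations must be non-negative.")
  }
  if (any(p$swing_time_mean_s >= p$stride_time_mean_s)) {
    abort("Infeasible profile: swing time must be shorter than stride time.")
  }
  lf <- p$landmark_fractions
  if (length(lf) != 3 || any(!is.finite(lf)) || any(lf <= 0) || any(lf >= 1) ||
      any(diff(lf) <= 0)) {
    abort("`landmark_fractions` must be 3 strictly increasing values in (0, 1).")
  }
  pk <- p$peak_magnitudes_bw
  if (length(pk) != 3 || any(!is.finite(pk)) || any(pk <= 0)) {
    abort("`peak_magnitudes_bw` must be 3 positive values.")
  }
  if (pk[2] >= min(pk[1], pk[3])) {
    abort("Infeasible profile: mid-stance force must be lower than both peaks (not a valley).")
  }
  # nominal double support must be positive: stance fraction > step fraction
  stance_frac <- 1 - p$swing_time_mean_s / p$stride_time_mean_s
  step_frac <- p$phase_offset_deg / 360
  if (any(stance_frac <= step_frac)) {
    abort("Infeasible profile: double support would be negative (stance shorter than step).")
  }
  if (!(is.infinite(p$turn_every_n_strides) || p$turn_every_n_strides >= 2)) {
    abort("`turn_every_n_strides` must be >= 2 or Inf.")
  }
  profile
}

#' @export
print.gait_profile <- function(x, ...) {
  cat(sprintf(
    "<gait_profile: %s>  stride %.3f/%.3f s, swing %.3f/%.3f s, phase %.1f deg (sd %.1f)\n",
    x$group_label, x$stride_time_mean_s[1], x$stride_time_mean_s[2],
    x$swing_time_mean_s[1], x$swing_time_mean_s[2],
    x$phase_offset_deg, x$phase_sd_deg
  ))
  invisible(x)
}

#' Default group gait profiles
#'
#' Generative profiles for the three study groups: young controls (YC),
#' age-matched controls (AMC) and medicated Parkinson's disease patients (PD).
#' Timing medians follow the group summary statistics of 5-min free walking at
#' 100 Hz; the PD profile carries the group's hallmark coordination deficits
#' (roughly tripled double-support jitter, larger swing asymmetry and a wider,
#' more offset bilateral phase distribution) while the M-shape force template
#' is common to all groups, mirroring the absence of kinetic group differences.
#'
#' @return A named list of three [gait_profile()] objects (`YC`, `AMC`, `PD`).
#' @export
default_profiles <- function() {
  list(
    YC = gait_profile(
      "YC",
      stride_time_mean_s = c(left = 1.12, right = 1.13),
      stride_time_sd_s = 0.027,
      swing_time_mean_s = c(left = 0.3835, right = 0.3800),
      swing_time_sd_s = 0.010,
      double_support_sd_s = 0.004,
      phase_offset_deg = 180.1,
      phase_sd_deg = 1.0,
      phase_offset_subject_sd_deg = 2.0
    ),
    AMC = gait_profile(
      "AMC",
      stride_time_mean_s = c(left = 1.13, right = 1.14),
      stride_time_sd_s = 0.026,
      swing_time_mean_s = c(left = 0.3840, right = 0.3757),
      swing_time_sd_s = 0.010,
      double_support_sd_s = 0.006,
      phase_offset_deg = 181.3,
      phase_sd_deg = 0.9,
      phase_offset_subject_sd_deg = 2.2
    ),
    PD = gait_profile(
      "PD",
      stride_time_mean_s = c(left = 1.10, right = 1.10),
      stride_time_sd_s = 0.025,
      swing_time_mean_s = c(left = 0.3750, right = 0.3648),
      swing_time_sd_s = 0.011,
      double_support_sd_s = 0.022,
      phase_offset_deg = 181.5,
      phase_sd_deg = 1.6,
      phase_offset_subject_sd_deg = 1.5,
      phase_offset_lateral_deg = 3.5
    )
  )
}
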