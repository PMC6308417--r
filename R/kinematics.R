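#' Table of the 28 kinematic parameter names
#'
#' Column order of the kinematic feature set: spatial estimates, per-leg
#' timing, stride-to-stride CVs, stance/swing percentages, double-support
#' time, bilateral phase statistics, gait asymmetry and the phase
#' coordination index.
#'
#' @return Character vector of length 28.
#' @export
kinematic_parameter_names <- function() {
  c("Nr steps", "Distance", "Step length", "Speed", "Cadence",
    "R stride time", "L stride time", "R stance time", "L stance time",
    "R swing time", "L swing time",
    "R stride time CV", "L stride time CV", "R stance time CV",
    "L stance time CV", "R swing time CV", "L swing time CV",
    "R PST", "L PST", "R PSWT", "L PSWT",
    "DST", "DST CV", "phi", "phi CV", "phi deviation", "GA", "PCI")
}

# Bilateral-contact (double-support) time within each stride window of
# `ref`: the sum of the loading and pre-swing double-support intervals. A
# window of normal alternating gait contains exactly two bilateral-contact
# segments (one contralateral contact ending inside, one starting inside);
# windows with any other count — recording edges, gaps left by removed turn
# strides — have no well-defined double support and yield NA.
events_dst <- function(ref, other) {
  ov <- other[other$valid, ]
  n <- nrow(ref)
  dst <- rep(NA_real_, n - 1)
  for (i in seq_len(n - 1)) {
    w0 <- ref$foot_strike_s[i]; w1 <- ref$foot_strike_s[i + 1]
    c1 <- min(ref$toe_off_s[i], w1)
    lo <- pmax(ov$foot_strike_s, w0)
    hi <- pmin(pmin(ov$toe_off_s, c1), w1)
    seg <- pmax(hi - lo, 0)
    if (sum(seg > 0) == 2) dst[i] <- sum(seg)
  }
  dst
}

#' Per-stride timing intervals from bilateral gait events
#'
#' Computes, for every usable stride of each foot, the stride time (initial
#' contact to next initial contact of the same foot), stance time (initial to
#' final contact), swing time (stride minus stance) and the double-support
#' time (total bilateral-contact time within the stride window, i.e. the sum
#' of the loading and pre-swing double-support intervals).
#'
#' A stride is usable when it is flagged valid, the next same-foot strike
#' exists and is valid (turn strides and their followers are excluded).
#'
#' @param left,right `gait_events` for the two feet.
#' @return A tibble of class `stride_intervals`: `side`, `stride`,
#'   `foot_strike_s`, `stride_s`, `stance_s`, `swing_s`, `dst_s`.
#' @export
stride_intervals <- function(left, right) {
  for (ev in list(left, right)) {
    if (!inherits(ev, "gait_events")) abort("Inputs must be <gait_events>.")
    if (sum(ev$valid) < 2) {
      abort(sprintf("Foot '%s' has fewer than 2 valid strides.", ev$side[1]))
    }
  }
  one_foot <- function(ref, other) {
    n <- nrow(ref)
    stride_s <- c(diff(ref$foot_strike_s), NA_real_)
    dst_s <- c(events_dst(ref, other), NA_real_)
    usable <- ref$valid & c(ref$valid[-1], FALSE) & !is.na(stride_s)
    tibble::tibble(
      side = ref$side,
      stride = ref$stride,
      foot_strike_s = ref$foot_strike_s,
      stride_s = stride_s,
      stance_s = ref$toe_off_s - ref$foot_strike_s,
      swing_s = stride_s - (ref$toe_off_s - ref$foot_strike_s),
      dst_s = dst_s
    )[usable, ]
  }
  out <- dplyr::bind_rows(one_foot(left, right), one_foot(right, left))
  if (nrow(out) == 0 || !all(c("left", "right") %in% out$side)) {
    abort("No overlapping valid strides across the two feet.")
  }
  structure(out, class = c("stride_intervals", class(out)))
}

#' Gait asymmetry from mean swing times
#'
#' `GA = 100 * |ln(SSWT / LSWT)|` where SSWT and LSWT are the mean swing
#' times of the legs with the shorter and longer swing. Symmetric in its
#' arguments and zero for perfectly symmetric gait.
#'
#' @param swing_a_s,swing_b_s Mean swing times of the two legs, in seconds.
#' @return Gait asymmetry (dimensionless, log-percent scale).
#' @export
#' @examples
#' gait_asymmetry(0.37, 0.38) # 2.6668
gait_asymmetry <- function(swing_a_s, swing_b_s) {
  if (!all(is.finite(c(swing_a_s, swing_b_s))) ||
      swing_a_s <= 0 || swing_b_s <= 0) {
    abort("Swing times must be positive.")
  }
  100 * abs(log(min(swing_a_s, swing_b_s) / max(swing_a_s, swing_b_s)))
}

#' Bilateral phase series
#'
#' For each stride of the reference leg (the leg with the higher mean swing
#' time; ties broken to the left leg with a warning), the phase of the
#' contralateral foot-strike is
#' `phi_i = 360 * (t_Si - t_Li) / (t_L(i+1) - t_Li)`,
#' where `t_Li` and `t_L(i+1)` are consecutive reference strikes and `t_Si`
#' the single contralateral strike between them; 180 degrees is ideal
#' alternation. Reference strides containing zero or more than one interior
#' contralateral strike (e.g. around removed turns) are skipped and counted.
#'
#' @param left,right `gait_events` for the two feet.
#' @return A tibble of class `phase_series` with columns `phi`, `t_ref_s`,
#'   `t_contra_s`; attributes `reference` (side) and `n_skipped`.
#' @export
phase_series <- function(left, right) {
  iv <- stride_intervals(left, right)
  mean_swing <- tapply(iv$swing_s, iv$side, mean)
  if (isTRUE(all.equal(mean_swing[["left"]], mean_swing[["right"]]))) {
    warn("Mean swing times tie; using the left leg as phase reference.")
    ref_side <- "left"
  } else {
    ref_side <- names(which.max(mean_swing))
  }
  ref <- if (ref_side == "left") left else right
  con <- if (ref_side == "left") right else left
  # windows run between consecutive reference strikes; only windows whose
  # reference stride is valid contribute (a window must never span strides
  # removed as turns). Contralateral strikes are genuine timing events
  # whatever their own stride's validity.
  ref_t <- ref$foot_strike_s
  con_t <- con$foot_strike_s
  phi <- t_ref <- t_con <- numeric(0)
  n_skipped <- 0L
  for (i in seq_len(nrow(ref) - 1)) {
    if (!ref$valid[i]) next
    inside <- con_t[con_t > ref_t[i] & con_t < ref_t[i + 1]]
    if (length(inside) != 1) {
      n_skipped <- n_skipped + 1L
      next
    }
    phi <- c(phi, 360 * (inside - ref_t[i]) / (ref_t[i + 1] - ref_t[i]))
    t_ref <- c(t_ref, ref_t[i])
    t_con <- c(t_con, inside)
  }
  out <- tibble::tibble(phi = phi, t_ref_s = t_ref, t_contra_s = t_con)
  structure(out, class = c("phase_series", class(out)),
            reference = ref_side, n_skipped = n_skipped)
}

#' Phase statistics and the phase coordination index
#'
#' Summarizes a bilateral phase series into its mean, coefficient of
#' variation, deviation from the ideal 180 degrees, and the phase
#' coordination index `PCI = phi CV + phi deviation` (inconsistency plus
#' inaccuracy of phase generation).
#'
#' By default the deviation is normalized to percent,
#' `100 * mean(|phi - 180|) / 180`, making PCI the sum of two percentages;
#' the raw-degree variant is always returned as `phi_deviation_deg`.
#'
#' @param phases A [phase_series()] (or a numeric vector of phases in
#'   degrees).
#' @param deviation `"percent"` (default) or `"degrees"`; the convention
#'   used for `phi_deviation` and hence PCI.
#' @return A one-row tibble: `phi_mean`, `phi_cv`, `phi_deviation`, `pci`,
#'   `phi_deviation_deg`, `n_phases`.
#' @export
phase_stats <- function(phases, deviation = c("percent", "degrees")) {
  deviation <- match.arg(deviation)
  phi <- if (is.numeric(phases)) phases else phases$phi
  if (length(phi) < 2) abort("Need at least 2 phase values.")
  dev_deg <- mean(abs(phi - 180))
  dev <- if (deviation == "percent") 100 * dev_deg / 180 else dev_deg
  phi_cv <- cv_percent(phi)
  tibble::tibble(
    phi_mean = mean(phi),
    phi_cv = phi_cv,
    phi_deviation = dev,
    pci = phi_cv + dev,
    phi_deviation_deg = dev_deg,
    n_phases = length(phi)
  )
}

#' Cadence from the periodogram of the combined GRF
#'
#' Estimates cadence as the dominant frequency of the power spectral density
#' (periodogram) of the mean-removed combined left + right GRF series,
#' searched within a physiological band. For alternating gait the combined
#' signal fluctuates at the step rate, so the estimate is in steps per
#' second (about `2 / stride time`).
#'
#' @param left A [grf_series()]; if `right` is supplied the two are summed
#'   sample-wise (truncated to the common length).
#' @param right Optional second [grf_series()].
#' @param freq_range Search band in Hz (default `c(0.5, 4)`).
#' @return Dominant frequency in Hz.
#' @export
estimate_cadence <- function(left, right = NULL, freq_range = c(0.5, 4)) {
  if (!inherits(left, "grf_series")) abort("`left` must be a <grf_series>.")
  fs <- grf_fs(left)
  x <- left$force
  if (!is.null(right)) {
    n <- min(length(x), nrow(right))
    x <- x[seq_len(n)] + right$force[seq_len(n)]
  }
  if (length(x) < 30 * fs) abort("Need at least 30 s of signal for cadence.")
  if (stats::sd(x) == 0) abort("Cadence is undefined for a constant series.")
  spg <- stats::spec.pgram(x - mean(x), taper = 0, detrend = TRUE,
                           plot = FALSE)
  freq <- spg$freq * fs
  band <- freq >= freq_range[1] & freq <= freq_range[2]
  if (!any(band)) abort("No periodogram frequencies inside `freq_range`.")
  freq[band][which.max(spg$spec[band])]
}

#' Spatial gait estimates from displacement and step count
#'
#' Average speed is total displacement over task duration; step length is
#' displacement over the number of steps.
#'
#' @param n_steps Total number of steps (both feet).
#' @param duration_s Task duration in seconds.
#' @param distance_m Total displacement in metres.
#' @return A one-row tibble: `speed_m_s`, `step_length_m`.
#' @export
#' @examples
#' spatial_estimates(524.5, 300, 377.3) # speed 1.2577, step length 0.7194
spatial_estimates <- function(n_steps, duration_s, distance_m) {
  stopifnot_scalar_pos(n_steps, "n_steps")
  stopifnot_scalar_pos(duration_s, "duration_s")
  stopifnot_scalar_pos(distance_m, "distance_m")
  tibble::tibble(
    speed_m_s = distance_m / duration_s,
    step_length_m = distance_m / n_steps
  )
}

#' Assemble the 28-parameter kinematic feature set
#'
#' Combines per-stride intervals, phase statistics, cadence and the spatial
#' estimates into the full kinematic feature row of one subject: 28 named
#' parameters, `PST + PSWT = 100` per foot (up to sample rounding) and
#' `PCI = phi CV + phi deviation` by construction.
#'
#' @param intervals A [stride_intervals()] result.
#' @param phase A [phase_stats()] row.
#' @param cadence_hz Cadence estimate in Hz ([estimate_cadence()]).
#' @param n_steps Total valid foot-strikes across both feet.
#' @param duration_s Recording duration (s).
#' @param distance_m Walked distance (m), from the cohort manifest.
#' @return A one-row tibble with the 28 columns of
#'   [kinematic_parameter_names()].
#' @export
assemble_kinematics <- function(intervals, phase, cadence_hz, n_steps,
                                duration_s, distance_m) {
  comp <- list(intervals = intervals, phase = phase, cadence_hz = cadence_hz,
               n_steps = n_steps, duration_s = duration_s,
               distance_m = distance_m)
  for (nm in names(comp)) {
    if (is.null(comp[[nm]]) || (is.numeric(comp[[nm]]) && anyNA(comp[[nm]]))) {
      abort(sprintf("Missing kinematic component: `%s`.", nm))
    }
  }
  sp <- spatial_estimates(n_steps, duration_s, distance_m)
  per_foot <- function(side) {
    iv <- intervals[intervals$side == side, ]
    list(
      stride = mean(iv$stride_s), stance = mean(iv$stance_s),
      swing = mean(iv$swing_s),
      stride_cv = cv_percent(iv$stride_s), stance_cv = cv_percent(iv$stance_s),
      swing_cv = cv_percent(iv$swing_s),
      pst = mean(100 * iv$stance_s / iv$stride_s),
      pswt = mean(100 * iv$swing_s / iv$stride_s)
    )
  }
  R <- per_foot("right"); L <- per_foot("left")
  dst <- intervals$dst_s[intervals$side == "left"]
  dst <- dst[!is.na(dst)]
  if (length(dst) < 2) abort("Too few strides with defined double support.")
  ga <- gait_asymmetry(L$swing, R$swing)
  vals <- c(
    n_steps, distance_m, sp$step_length_m, sp$speed_m_s, cadence_hz,
    R$stride, L$stride, R$stance, L$stance, R$swing, L$swing,
    R$stride_cv, L$stride_cv, R$stance_cv, L$stance_cv, R$swing_cv, L$swing_cv,
    R$pst, L$pst, R$pswt, L$pswt,
    mean(dst), cv_percent(dst),
    phase$phi_mean, phase$phi_cv, phase$phi_deviation, ga, phase$pci
  )
  out <- tibble::as_tibble(as.list(stats::setNames(vals, kinematic_parameter_names())))
  out
}
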