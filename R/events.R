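#' Centered moving-average smoothing
#'
#' Smooths a GRF series with a centered moving average of odd window length.
#' At the edges the window shrinks symmetrically to the available samples, so
#' the output length equals the input length.
#'
#' @param series A [grf_series()].
#' @param window Odd window length in samples (default 5).
#' @return A smoothed [grf_series()] with the same metadata.
#' @export
moving_average <- function(series, window = 5) {
  if (!inherits(series, "grf_series")) abort("`series` must be a <grf_series>.")
  if (window %% 2 == 0) abort("`window` must be odd.")
  if (window < 1 || window > nrow(series)) {
    abort("`window` must be between 1 and the series length.")
  }
  x <- series$force
  if (window == 1) return(series)
  h <- (window - 1) / 2
  cs <- cumsum(c(0, x))
  n <- length(x)
  i <- seq_len(n)
  lo <- pmax(i - h, 1)
  hi <- pmin(i + h, n)
  sm <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  out <- series
  out$force <- sm
  out
}

#' Construct a gait-events table
#'
#' One row per stride: the foot-strike and toe-off times of one foot, a
#' validity flag and an optional removal reason. Within each stride
#' `toe_off_s > foot_strike_s`, and strides are strictly increasing.
#'
#' @param foot_strike_s,toe_off_s Event times in seconds (equal length).
#' @param side `"left"` or `"right"`.
#' @param sampling_rate_hz Sampling rate of the source series.
#' @param valid Logical validity flags (default all `TRUE`).
#' @param reason Optional character removal reasons.
#' @return A tibble of class `gait_events`.
#' @export
gait_events <- function(foot_strike_s, toe_off_s, side = c("left", "right"),
                        sampling_rate_hz = 100, valid = NULL, reason = NULL) {
  side <- match.arg(side)
  if (length(foot_strike_s) != length(toe_off_s)) {
    abort("`foot_strike_s` and `toe_off_s` must have equal length.")
  }
  if (any(toe_off_s <= foot_strike_s)) {
    abort("Each toe-off must follow its foot-strike.")
  }
  if (is.unsorted(foot_strike_s, strictly = TRUE) && length(foot_strike_s) > 1) {
    abort("Strides must be strictly increasing.")
  }
  new_gait_events(foot_strike_s, toe_off_s, side, sampling_rate_hz,
                  valid = valid, reason = reason)
}

new_gait_events <- function(strike_s, toe_off_s, side, fs,
                            valid = NULL, reason = NULL) {
  n <- length(strike_s)
  out <- tibble::tibble(
    side = rep(side, n),
    stride = seq_len(n),
    foot_strike_s = strike_s,
    toe_off_s = toe_off_s,
    valid = valid %||% rep(TRUE, n),
    reason = reason %||% rep(NA_character_, n)
  )
  structure(out, class = c("gait_events", class(out)),
            sampling_rate_hz = fs)
}

#' Build gait events directly from a generator schedule
#'
#' Bypasses signal synthesis and detection: turns the ground-truth schedule of
#' a [generate_stride_schedule()] into a pair of `gait_events` objects. Turn
#' strides are pre-flagged invalid. Useful for testing downstream parameter
#' computations against exact event times.
#'
#' @param schedule A `stride_schedule`.
#' @return A list with `left` and `right` `gait_events`.
#' @export
events_from_schedule <- function(schedule) {
  if (!inherits(schedule, "stride_schedule")) {
    abort("`schedule` must be a <stride_schedule>.")
  }
  fs <- schedule$profile$sampling_rate_hz
  build <- function(tab, side) {
    new_gait_events(tab$strike_s, tab$toe_off_s, side = side, fs = fs,
                    valid = !tab$turn,
                    reason = ifelse(tab$turn, "turn", NA_character_))
  }
  list(left = build(schedule$left, "left"),
       right = build(schedule$right, "right"))
}

# Back-extrapolation of a contact edge to zero force. `idx` are samples on
# the monotone edge (force between the detection threshold and a fraction of
# the run peak); a low-order polynomial is fit and its zero-force root
# nearest `near` returned, in sample index units (NA if degenerate). A
# quadratic accommodates the curvature of the loading/unloading ramps; with
# only two points a line is used.
edge_zero_intercept <- function(x, idx, near) {
  idx <- idx[idx >= 1 & idx <= length(x)]
  if (length(idx) < 2) return(NA_real_)
  y <- x[idx]
  j <- idx - near # center for conditioning
  if (length(idx) >= 3) {
    co <- quad_ls(j, y)
    if (!is.null(co) && co[3] != 0) {
      disc <- co[2]^2 - 4 * co[3] * co[1]
      if (is.finite(disc) && disc >= 0) {
        roots <- (-co[2] + c(-1, 1) * sqrt(disc)) / (2 * co[3])
        roots <- roots[is.finite(roots)]
        if (length(roots) > 0) {
          return(near + roots[which.min(abs(roots))])
        }
      }
    }
    # fall through to the linear fit if the quadratic has no real root
  }
  fit_slope <- stats::cov(j, y) / stats::var(j)
  if (!is.finite(fit_slope) || fit_slope == 0) return(NA_real_)
  near + mean(j) - mean(y) / fit_slope
}

#' Detect foot-strike and toe-off events from a GRF series
#'
#' Hybrid threshold-plus-refinement detector. Contact phases are found as
#' runs of force above a threshold set to `contact_threshold_frac` times the
#' median per-stance peak force. Each run boundary is then refined by
#' back-extrapolating the supra-threshold edge samples to zero force (the
#' standard force-platform onset technique), clamped to within 3 samples of
#' the threshold crossing and reported at sample resolution.
#'
#' @param series A smoothed [grf_series()] (see [moving_average()]).
#' @param contact_threshold_frac Threshold as a fraction of the median
#'   stance peak force (default 0.05).
#' @param min_stance_samples Minimum run length counted as a stance
#'   (default 5 samples).
#' @return A `gait_events` tibble: `side`, `stride`, `foot_strike_s`,
#'   `toe_off_s`, `valid`, `reason`. Empty (zero rows) for an all-zero
#'   series.
#' @export
detect_contacts <- function(series, contact_threshold_frac = 0.05,
                            min_stance_samples = 5) {
  if (!inherits(series, "grf_series")) abort("`series` must be a <grf_series>.")
  if (contact_threshold_frac <= 0 || contact_threshold_frac >= 1) {
    abort("`contact_threshold_frac` must be in (0, 1).")
  }
  x <- series$force
  fs <- grf_fs(series)
  side <- grf_side(series)
  if (max(x) <= 0) {
    return(new_gait_events(numeric(0), numeric(0), side, fs))
  }

  # provisional runs to estimate the typical stance peak
  prov <- contact_threshold_frac * max(x)
  r <- rle(x > prov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  peak_med <- stats::median(vapply(which(r$values), function(j)
    max(x[starts[j]:ends[j]]), numeric(1)))
  thr <- contact_threshold_frac * peak_med

  if (min(x) > thr) abort("No swing phase detected: force never drops below threshold.")

  r <- rle(x > thr)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values & r$lengths >= min_stance_samples)
  # drop stances truncated by the recording edges
  runs <- runs[starts[runs] > 1 & ends[runs] < length(x)]
  if (length(runs) < 2) abort("Fewer than 2 strides detected.")

  strike <- numeric(length(runs))
  toe <- numeric(length(runs))
  for (k in seq_along(runs)) {
    a <- starts[runs[k]]; b <- ends[runs[k]]
    pk <- max(x[a:b])
    # Fit-band offsets: samples closer than 2 to the crossing carry smearing
    # from the (window 5) moving average, so the fit starts 2 samples inside
    # the run and uses up to 4 clean edge samples below ~60% of the peak.
    cand <- a - 1
    ridx <- min(a + 2, b):min(a + 5, b)
    ridx <- ridx[x[ridx] >= thr & x[ridx] <= 0.6 * pk]
    j0 <- edge_zero_intercept(x, ridx, near = cand)
    strike[k] <- if (is.finite(j0)) {
      min(max(round(j0), cand - 3), cand + 3)
    } else cand
    # falling edge
    cand <- b + 1
    fidx <- max(b - 5, a):max(b - 2, a)
    fidx <- fidx[x[fidx] >= thr & x[fidx] <= 0.6 * pk]
    j1 <- edge_zero_intercept(x, fidx, near = cand)
    toe[k] <- if (is.finite(j1)) {
      min(max(round(j1), cand - 3), cand + 3)
    } else cand
  }
  new_gait_events((strike - 1) / fs, (toe - 1) / fs, side, fs)
}

#' Flag outlier strides (turns) with a running-median filter
#'
#' Compares every stride duration against a running median; strides deviating
#' by more than `mad_factor` times the MAD of these deviations are flagged
#' invalid, together with the stride immediately following each (turns and
#' their contiguous strides). Nothing is deleted: flags and reasons are set,
#' so re-running is idempotent. The MAD is floored at 1.5 samples so that
#' sample-resolution quantization on clean recordings is never flagged.
#'
#' @param events A `gait_events` tibble from [detect_contacts()].
#' @param window Running-median window in strides (default 9).
#' @param mad_factor Deviation threshold in MAD units (default 3).
#' @return The events with updated `valid`/`reason` columns.
#' @export
remove_outlier_strides <- function(events, window = 9, mad_factor = 3.0) {
  if (!inherits(events, "gait_events")) abort("`events` must be <gait_events>.")
  n <- nrow(events)
  if (n < window) {
    warn(sprintf("Only %d strides (< window %d): outlier filtering skipped.",
                 n, window))
    return(events)
  }
  fs <- attr(events, "sampling_rate_hz")
  d <- diff(events$foot_strike_s) # duration of strides 1..n-1
  med <- stats::runmed(d, k = window, endrule = "median")
  dev <- abs(d - med)
  mad_d <- max(stats::mad(d - med, center = 0), 1.5 / fs)
  out <- dev > mad_factor * mad_d
  flagged <- which(out)
  followers <- setdiff(flagged + 1L, flagged)
  events$valid[flagged] <- FALSE
  events$reason[flagged] <- ifelse(
    is.na(events$reason[flagged]), "duration_outlier", events$reason[flagged])
  followers <- followers[followers <= n]
  events$valid[followers] <- FALSE
  events$reason[followers] <- ifelse(
    is.na(events$reason[followers]), "follows_outlier", events$reason[followers])
  events
}

#' Export gait events as a plain tibble
#'
#' @param events A `gait_events` object.
#' @return A plain tibble with columns `side`, `stride`, `foot_strike_s`,
#'   `toe_off_s`, `valid`, `reason`.
#' @export
as_events_table <- function(events) {
  tibble::as_tibble(unclass(events)[c("side", "stride", "foot_strike_s",
                                      "toe_off_s", "valid", "reason")])
}
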