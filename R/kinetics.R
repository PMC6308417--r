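#' Table of the 24 kinetic parameter names
#'
#' Per-leg heel-peak, mid-stance and toe-off forces (body-weight fractions),
#' their times (% of stance), and the stride-to-stride CVs of all six.
#'
#' @return Character vector of length 24.
#' @export
kinetic_parameter_names <- function() {
  c("R HPF", "L HPF", "R MSF", "L MSF", "R TOF", "L TOF",
    "R HPF CV", "L HPF CV", "R MSF CV", "L MSF CV", "R TOF CV", "L TOF CV",
    "R HPT", "L HPT", "R MST", "L MST", "R TOT", "L TOT",
    "R HPT CV", "L HPT CV", "R MST CV", "L MST CV", "R TOT CV", "L TOT CV")
}

#' Segment stance cycles and normalize by body weight
#'
#' Crops the GRF between each valid foot-strike/toe-off pair, divides by the
#' body-weight force (`weight_kg * 9.81` when the series is in Newtons; no-op
#' when already in body-weight fractions) and linearly resamples each cycle
#' onto a common 101-point 0-100% stance grid.
#'
#' @param series A [grf_series()]; typically the raw series, so that peak
#'   amplitudes are not attenuated by smoothing (events may come from the
#'   smoothed copy).
#' @param events Matching `gait_events`.
#' @param weight_kg Subject body mass in kg (required for Newton input).
#' @return A tibble of class `stance_cycles` in long format: `cycle`,
#'   `stance_pct` (0..100), `force_bw`. Cycles shorter than 5 samples are
#'   skipped (count in attribute `n_skipped`).
#' @export
segment_stance_cycles <- function(series, events, weight_kg = NULL) {
  if (!inherits(series, "grf_series")) abort("`series` must be a <grf_series>.")
  if (!inherits(events, "gait_events")) abort("`events` must be <gait_events>.")
  units <- grf_units(series)
  if (units == "N") {
    if (is.null(weight_kg) || !is.finite(weight_kg) || weight_kg <= 0) {
      abort("`weight_kg` is required to normalize forces in Newtons.")
    }
    denom <- weight_kg * 9.81
  } else {
    denom <- 1
  }
  fs <- grf_fs(series)
  x <- series$force / denom
  grid <- seq(0, 100, length.out = 101)
  keep <- which(events$valid)
  curves <- vector("list", length(keep))
  ids <- integer(length(keep))
  n_ok <- 0L
  n_skipped <- 0L
  for (k in keep) {
    i0 <- round(events$foot_strike_s[k] * fs) + 1
    i1 <- round(events$toe_off_s[k] * fs) + 1
    if (i0 < 1 || i1 > length(x) || i1 - i0 + 1 < 5) {
      n_skipped <- n_skipped + 1L
      next
    }
    seg <- x[i0:i1]
    pct <- seq(0, 100, length.out = length(seg))
    n_ok <- n_ok + 1L
    curves[[n_ok]] <- stats::approx(pct, seg, xout = grid)$y
    ids[n_ok] <- events$stride[k]
  }
  if (n_ok == 0) {
    warn("No usable stance cycles after segmentation.")
    out <- tibble::tibble(cycle = integer(0), stance_pct = numeric(0),
                          force_bw = numeric(0))
  } else {
    out <- tibble::tibble(
      cycle = rep(ids[seq_len(n_ok)], each = 101),
      stance_pct = rep(grid, n_ok),
      force_bw = unlist(curves[seq_len(n_ok)], use.names = FALSE)
    )
  }
  structure(out, class = c("stance_cycles", class(out)),
            side = grf_side(series), n_skipped = n_skipped)
}

#' Extract the six M-shape parameters from one stance cycle
#'
#' Identifies the heel-peak force HPF (the maximum over the first half of
#' stance, i.e. the first peak after the foot touches the ground), the
#' toe-off force TOF (the maximum over the second half, the last peak before
#' toe-off) and the mid-stance force MSF (the minimum between them),
#' together with their times as percentages of the stance cycle. Windowed
#' maxima are equivalent to the first/last local maximum for a valid
#' M-shape, and robust to noise ripples on the loading and unloading edges.
#' A cycle is usable only when the result is a genuine M: both peaks
#' interior to their windows, ordered `HPT < MST < TOT`, and the valley
#' strictly below both peaks.
#'
#' @param force_bw Numeric vector: one cycle on the 101-point stance grid.
#' @return A one-row tibble `hpf, msf, tof, hpt, mst, tot, usable`; when no
#'   valid M-shape is found (flat, monotone or single-bump cycle), `usable`
#'   is `FALSE` and the values are `NA`.
#' @export
extract_m_shape <- function(force_bw) {
  v <- m_shape_vec(as.numeric(force_bw))
  tibble::tibble(
    hpf = v[1], msf = v[2], tof = v[3],
    hpt = v[4], mst = v[5], tot = v[6],
    usable = is.finite(v[1])
  )
}

# numeric core of extract_m_shape: c(hpf, msf, tof, hpt, mst, tot), all NA
# when the cycle is not a valid M-shape
m_shape_vec <- function(y) {
  n <- length(y)
  bad <- rep(NA_real_, 6)
  if (n < 5 || all(y == y[1])) return(bad)
  pct <- seq(0, 100, length.out = n)
  lo <- which(pct > 0 & pct <= 50)
  hi <- which(pct >= 50 & pct < 100)
  i_hp <- lo[which.max(y[lo])]
  i_to <- hi[which.max(y[hi])]
  if (i_to <= i_hp) return(bad)
  mid <- i_hp:i_to
  i_ms <- mid[which.min(y[mid])]
  # reject non-M shapes: peaks on window edges or a valley that is not
  # strictly below both peaks
  if (i_ms == i_hp || i_ms == i_to) return(bad)
  if (i_hp == lo[1] || i_to == hi[length(hi)]) return(bad)
  if (y[i_ms] >= min(y[i_hp], y[i_to])) return(bad)
  hp <- refine_extremum(y, pct, i_hp)
  ms <- refine_extremum(y, pct, i_ms)
  to <- refine_extremum(y, pct, i_to)
  unname(c(hp["value"], ms["value"], to["value"],
           hp["pct"], ms["pct"], to["pct"]))
}

# Least-squares parabola over a +/-4-point window around a grid extremum:
# sub-grid refinement of its location and value. A windowed quadratic (not
# the 3-point formula) is used because the 101-point grid is a linear
# resampling of the raw samples, so neighboring grid values lie on line
# segments with a kink at the true extremum.
refine_extremum <- function(y, pct, i, half_window = 4L) {
  n <- length(y)
  idx <- max(1L, i - half_window):min(n, i + half_window)
  if (length(idx) < 5) return(c(pct = pct[i], value = y[i]))
  j <- idx - i
  co <- quad_ls(j, y[idx])
  if (is.null(co) || co[3] == 0) return(c(pct = pct[i], value = y[i]))
  delta <- -co[2] / (2 * co[3])
  if (!is.finite(delta) || abs(delta) > half_window) {
    return(c(pct = pct[i], value = y[i]))
  }
  step <- pct[2] - pct[1]
  val <- co[1] + co[2] * delta + co[3] * delta^2
  # never report a refined peak below / valley above the grid sample
  c(pct = pct[i] + delta * step, value = unname(val))
}

#' Per-cycle M-shape features for all cycles of one foot
#'
#' @param cycles A [segment_stance_cycles()] result.
#' @return A tibble with one row per cycle: `cycle`, the six M-shape
#'   parameters and `usable`.
#' @export
m_shape_features <- function(cycles) {
  if (!inherits(cycles, "stance_cycles")) abort("`cycles` must be <stance_cycles>.")
  if (nrow(cycles) == 0) {
    return(tibble::tibble(cycle = integer(0), hpf = numeric(0),
                          msf = numeric(0), tof = numeric(0),
                          hpt = numeric(0), mst = numeric(0),
                          tot = numeric(0), usable = logical(0)))
  }
  ids <- unique(cycles$cycle)
  Y <- matrix(cycles$force_bw, nrow = 101) # one column per cycle, in order
  M <- t(apply(Y, 2, m_shape_vec))
  out <- tibble::tibble(
    cycle = as.integer(ids),
    hpf = M[, 1], msf = M[, 2], tof = M[, 3],
    hpt = M[, 4], mst = M[, 5], tot = M[, 6],
    usable = is.finite(M[, 1])
  )
  dplyr::arrange(out, .data$cycle)
}

#' Pointwise average stance cycle
#'
#' @param cycles A [segment_stance_cycles()] result (>= 1 cycle).
#' @return A tibble `stance_pct`, `force_bw`: the mean curve over the
#'   101-point stance grid.
#' @export
average_cycle <- function(cycles) {
  if (!inherits(cycles, "stance_cycles") || nrow(cycles) == 0) {
    abort("`cycles` must be a non-empty <stance_cycles>.")
  }
  dplyr::summarise(dplyr::group_by(cycles, .data$stance_pct),
                   force_bw = mean(.data$force_bw), .groups = "drop")
}

#' Assemble the 24-parameter kinetic feature set
#'
#' Per-foot means of the six per-cycle M-shape quantities and their
#' coefficients of variation. Per-cycle extraction comes first and summary
#' statistics second, so the CVs measure genuine cycle-to-cycle variability.
#'
#' @param left_features,right_features Per-cycle feature tibbles from
#'   [m_shape_features()] for the left and right foot (>= 2 usable cycles
#'   each).
#' @return A one-row tibble with the 24 columns of
#'   [kinetic_parameter_names()].
#' @export
assemble_kinetics <- function(left_features, right_features) {
  summarise_foot <- function(feat, foot) {
    ok <- feat[feat$usable, ]
    if (nrow(ok) < 2) {
      abort(sprintf("Fewer than 2 usable stance cycles for the %s foot.", foot))
    }
    vals <- c(
      mean(ok$hpf), mean(ok$msf), mean(ok$tof),
      cv_percent(ok$hpf), cv_percent(ok$msf), cv_percent(ok$tof),
      mean(ok$hpt), mean(ok$mst), mean(ok$tot),
      cv_percent(ok$hpt), cv_percent(ok$mst), cv_percent(ok$tot)
    )
    stats::setNames(vals, paste(foot, c("HPF", "MSF", "TOF",
                                        "HPF CV", "MSF CV", "TOF CV",
                                        "HPT", "MST", "TOT",
                                        "HPT CV", "MST CV", "TOT CV")))
  }
  vals <- c(summarise_foot(right_features, "R"),
            summarise_foot(left_features, "L"))
  tibble::as_tibble(as.list(vals[kinetic_parameter_names()]))
}
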