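# The stance-phase vertical GRF template: an M-shaped curve through
# (0, 0) -> (f1, HPF) -> (f2, MSF) -> (f3, TOF) -> (1, 0). The contact
# edges are quarter-sine ramps (near-linear take-off at the contacts,
# quadratic tangency at the peaks); the two interior segments are raised
# cosines (zero slope and quadratic tangency at both ends). Each segment is
# strictly monotone, so the curve has exactly two local maxima and one
# interior local minimum, located exactly at the landmark fractions with
# exactly the requested magnitudes; the quadratic tangency makes every
# extremum locally parabolic, as in measured GRFs.

# Evaluate the template at stance fractions u in [0, 1].
stance_template_at <- function(u, landmarks, peaks) {
  f1 <- landmarks[1]; f2 <- landmarks[2]; f3 <- landmarks[3]
  hpf <- peaks[1]; msf <- peaks[2]; tof <- peaks[3]
  y <- numeric(length(u))

  # rising edge 0 -> HPF: quarter sine
  i <- u >= 0 & u < f1
  y[i] <- hpf * sin(pi / 2 * u[i] / f1)

  # HPF -> MSF valley: raised cosine
  i <- u >= f1 & u < f2
  v <- (u[i] - f1) / (f2 - f1)
  y[i] <- hpf + (msf - hpf) * (1 - cos(pi * v)) / 2

  # MSF -> TOF: raised cosine
  i <- u >= f2 & u < f3
  v <- (u[i] - f2) / (f3 - f2)
  y[i] <- msf + (tof - msf) * (1 - cos(pi * v)) / 2

  # falling edge TOF -> 0: quarter sine
  i <- u >= f3 & u <= 1
  y[i] <- tof * sin(pi / 2 * (1 - u[i]) / (1 - f3))

  y[u < 0 | u > 1] <- 0
  y
}

#' Synthesize one M-shaped stance-phase GRF curve
#'
#' Builds the vertical ground-reaction-force profile of a single stance phase:
#' zero at foot-strike, rising to the heel peak, dipping to the mid-stance
#' valley, rising again to the toe-off peak and returning to zero at toe-off.
#' The three extrema sit exactly at the requested stance fractions with the
#' requested magnitudes.
#'
#' @param stance_duration_s Stance duration in seconds.
#' @param landmarks Length-3 increasing vector of stance fractions in (0, 1):
#'   heel-peak, mid-stance valley, toe-off peak times.
#' @param peaks Length-3 vector of magnitudes (HPF, MSF, TOF), typically in
#'   body-weight fractions; the middle value must be below both peaks.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @return A numeric vector of force samples at times
#'   `0, 1/fs, ..., round(stance * fs)/fs` (first and last samples are 0).
#' @export
#' @examples
#' curve <- synth_stance_curve(0.7, c(0.26, 0.46, 0.74), c(1.0, 0.6, 1.1), 100)
#' which.max(curve) # heel peak near sample round(0.26 * 70) + 1
synth_stance_curve <- function(stance_duration_s,
                               landmarks = c(0.26, 0.46, 0.74),
                               peaks = c(0.95, 0.62, 1.10),
                               sampling_rate_hz = 100) {
  stopifnot_scalar_pos(stance_duration_s, "stance_duration_s")
  stopifnot_scalar_pos(sampling_rate_hz, "sampling_rate_hz")
  if (length(landmarks) != 3 || any(diff(landmarks) <= 0) ||
      landmarks[1] <= 0 || landmarks[3] >= 1) {
    abort("`landmarks` must be 3 strictly increasing stance fractions in (0, 1).")
  }
  if (length(peaks) != 3 || any(peaks <= 0)) {
    abort("`peaks` must be 3 positive magnitudes.")
  }
  if (peaks[2] >= min(peaks[1], peaks[3])) {
    abort("Mid-stance force must be lower than both peaks (not a valley).")
  }
  n <- round(stance_duration_s * sampling_rate_hz)
  if (n < 5) {
    abort("Stance shorter than 5 samples cannot be synthesized.")
  }
  u <- seq(0, n) / n
  stance_template_at(u, landmarks, peaks)
}
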