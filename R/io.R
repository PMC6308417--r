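#' Construct a per-foot GRF series
#'
#' A `grf_series` is a tibble with columns `time_s` and `force` plus metadata
#' attributes: sampling rate, foot side, force units (`"N"` for Newtons or
#' `"bw"` for body-weight fractions) and subject id.
#'
#' @param force Numeric vector of vertical ground-reaction-force samples.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param side `"left"` or `"right"`.
#' @param units `"N"` or `"bw"`.
#' @param subject_id Optional subject identifier.
#' @return A tibble of class `grf_series`.
#' @export
grf_series <- function(force, sampling_rate_hz, side = c("left", "right"),
                       units = c("N", "bw"), subject_id = NA_character_) {
  side <- match.arg(side)
  units <- match.arg(units)
  stopifnot_scalar_pos(sampling_rate_hz, "sampling_rate_hz")
  force <- as.numeric(force)
  if (length(force) < 2) abort("A GRF series needs at least 2 samples.")
  if (any(!is.finite(force))) abort("GRF samples must all be finite.")
  out <- tibble::tibble(
    time_s = (seq_along(force) - 1) / sampling_rate_hz,
    force = force
  )
  structure(out,
    class = c("grf_series", class(out)),
    sampling_rate_hz = sampling_rate_hz, side = side,
    units = units, subject_id = subject_id
  )
}

grf_fs <- function(series) attr(series, "sampling_rate_hz")
grf_side <- function(series) attr(series, "side")
grf_units <- function(series) attr(series, "units")

#' Construct a sensor-grid frame set
#'
#' An ordered set of per-sensor pressure frames from one insole. All frames
#' share one grid shape; values must be non-negative (NA/NaN are tolerated
#' here and rejected with a frame index by [sum_sensors()]).
#'
#' @param frames A 3-d array (frame x row x col).
#' @param sampling_rate_hz Frame rate in Hz.
#' @param side `"left"` or `"right"`.
#' @param units `"N"` or `"bw"`.
#' @param subject_id Optional subject identifier.
#' @return An object of class `sensor_grid`.
#' @export
sensor_grid <- function(frames, sampling_rate_hz, side = c("left", "right"),
                        units = c("N", "bw"), subject_id = NA_character_) {
  side <- match.arg(side)
  units <- match.arg(units)
  stopifnot_scalar_pos(sampling_rate_hz, "sampling_rate_hz")
  if (length(dim(frames)) != 3) abort("`frames` must be a 3-d array.")
  if (any(frames < 0, na.rm = TRUE)) abort("Sensor values must be >= 0.")
  structure(list(frames = frames),
    class = "sensor_grid",
    sampling_rate_hz = sampling_rate_hz, side = side,
    units = units, subject_id = subject_id
  )
}

#' Reduce a sensor-grid frame set to a GRF series
#'
#' Sums the per-sensor pressure values of every frame of an insole recording,
#' yielding the vertical ground-reaction-force time series (one sample per
#' frame).
#'
#' @param grid A `sensor_grid` object as returned by [grf_to_sensor_grid()]:
#'   a list with a 3-d `frames` array (frame x row x col) and attributes
#'   `sampling_rate_hz`, `side`, `units`.
#' @return A [grf_series()] with one sample per frame, units propagated.
#' @export
sum_sensors <- function(grid) {
  if (!inherits(grid, "sensor_grid")) abort("`grid` must be a <sensor_grid>.")
  fr <- grid$frames
  if (length(dim(fr)) != 3 || dim(fr)[1] == 0) abort("`grid` has no frames.")
  nas <- which(apply(fr, 1, anyNA))
  if (length(nas) > 0) {
    abort(sprintf("NaN/NA sensor values in frame(s): %s",
                  paste(head(nas, 5), collapse = ", ")))
  }
  force <- apply(fr, 1, sum)
  grf_series(force, attr(grid, "sampling_rate_hz"), side = attr(grid, "side"),
             units = attr(grid, "units"), subject_id = attr(grid, "subject_id"))
}

#' Emit a coarse sensor-grid frame set from a GRF series
#'
#' Distributes each force sample over a small pressure grid using a fixed
#' random spatial weighting, so the grid reader can be exercised without
#' simulating a real 954-sensor insole.
#'
#' @param series A [grf_series()].
#' @param dims Grid dimensions `c(rows, cols)`.
#' @param seed Optional seed for the spatial weighting.
#' @return A `sensor_grid` object; `sum_sensors()` recovers `series`.
#' @export
grf_to_sensor_grid <- function(series, dims = c(4, 6), seed = NULL) {
  if (!inherits(series, "grf_series")) abort("`series` must be a <grf_series>.")
  w <- with_rng_seed(seed, stats::runif(prod(dims)))
  w <- w / sum(w)
  n <- nrow(series)
  frames <- array(outer(series$force, w), dim = c(n, dims[1], dims[2]))
  structure(list(frames = frames),
    class = "sensor_grid",
    sampling_rate_hz = grf_fs(series), side = grf_side(series),
    units = grf_units(series), subject_id = attr(series, "subject_id")
  )
}

#' Read and write per-foot GRF CSV files
#'
#' The dialect is a UTF-8 comma-separated file with header `time_s,force`
#' ('.' decimal separator). The time column is optional on read; if absent,
#' `sampling_rate_hz` must be supplied. Time steps must be regular to within
#' 1% of the median step.
#'
#' @param path File path.
#' @param sampling_rate_hz Sampling rate, required when the file has no
#'   `time_s` column (default 100 Hz).
#' @param side,units,subject_id Metadata for the returned series.
#' @return `read_grf_csv()` returns a [grf_series()]; `write_grf_csv()`
#'   returns `path` invisibly. A written series reads back equal to within
#'   float formatting (12 significant digits).
#' @export
read_grf_csv <- function(path, sampling_rate_hz = NULL,
                         side = c("left", "right"), units = c("N", "bw"),
                         subject_id = NA_character_) {
  side <- match.arg(side)
  units <- match.arg(units)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"force" %in% names(df)) {
    abort("GRF CSV is missing required column: force")
  }
  if ("time_s" %in% names(df)) {
    dt <- diff(df$time_s)
    if (any(!is.finite(dt)) || any(dt <= 0)) {
      abort("`time_s` must be strictly increasing.")
    }
    md <- stats::median(dt)
    if (any(abs(dt - md) > 0.01 * md)) {
      abort("Irregular time steps in `time_s` (beyond 1% tolerance); gap or jitter in the recording.")
    }
    fs <- 1 / md
  } else {
    if (is.null(sampling_rate_hz)) {
      abort("File has no `time_s` column; supply `sampling_rate_hz`.")
    }
    fs <- sampling_rate_hz
  }
  grf_series(df$force, fs, side = side, units = units, subject_id = subject_id)
}

#' @rdname read_grf_csv
#' @param series A [grf_series()] to write.
#' @export
write_grf_csv <- function(series, path) {
  if (!inherits(series, "grf_series")) abort("`series` must be a <grf_series>.")
  df <- tibble::tibble(
    time_s = signif(series$time_s, 12),
    force = signif(series$force, 12)
  )
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

subject_required_cols <- c("subject_id", "group", "age_years", "sex",
                           "weight_kg", "height_m")

#' Read a subject demographics/clinical table
#'
#' Expects one row per subject with at least `subject_id`, `group`,
#' `age_years`, `sex`, `weight_kg`, `height_m` (weight is required downstream
#' for body-weight normalization of kinetics). Clinical columns (`updrs_iii`,
#' `mmse`, `ledd_mg`, `disease_duration_years`, `affected_side`) are optional
#' and present only for patient cohorts.
#'
#' @param path CSV file path.
#' @return A tibble, `bmi_kg_m2` recomputed as weight / height^2.
#' @export
read_subject_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(subject_required_cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("Subject table is missing required column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  df$bmi_kg_m2 <- df$weight_kg / df$height_m^2
  tibble::as_tibble(df)
}

#' Write a per-subject feature table to CSV
#'
#' @param rows A tibble (e.g. the 28-column kinematic or 24-column kinetic
#'   feature table, one row per subject).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(rows, path) {
  readr::write_csv(tibble::as_tibble(rows), path, progress = FALSE)
  invisible(path)
}
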