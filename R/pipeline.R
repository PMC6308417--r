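#' Pipeline configuration
#'
#' Bundles every tunable setting of the analysis: sampling rate (100 Hz),
#' moving-average smoothing window (5 samples), contact threshold fraction,
#' outlier-filter window and MAD factor, ReliefF neighbor count (k = 10),
#' the phi-deviation normalization convention, and the seed.
#'
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param smooth_window Moving-average window, odd (samples).
#' @param contact_threshold_frac Contact threshold, fraction of the median
#'   stance peak.
#' @param outlier_window Running-median window (strides).
#' @param mad_factor Outlier threshold in MAD units.
#' @param relieff_k ReliefF/RReliefF neighbor count.
#' @param phase_deviation `"percent"` or `"degrees"`.
#' @param seed Integer seed recorded in every output.
#' @param n_yc,n_amc,n_pd Cohort sizes for simulation.
#' @param profiles Group [gait_profile()]s for simulation.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sampling_rate_hz = 100, smooth_window = 5,
                            contact_threshold_frac = 0.05,
                            outlier_window = 9, mad_factor = 3.0,
                            relieff_k = 10,
                            phase_deviation = c("percent", "degrees"),
                            seed = 1, n_yc = 16, n_amc = 12, n_pd = 11,
                            profiles = default_profiles()) {
  phase_deviation <- match.arg(phase_deviation)
  for (nm in c("sampling_rate_hz", "smooth_window", "contact_threshold_frac",
               "outlier_window", "mad_factor", "relieff_k")) {
    stopifnot_scalar_pos(get(nm), nm)
  }
  structure(list(
    sampling_rate_hz = sampling_rate_hz, smooth_window = smooth_window,
    contact_threshold_frac = contact_threshold_frac,
    outlier_window = outlier_window, mad_factor = mad_factor,
    relieff_k = relieff_k, phase_deviation = phase_deviation, seed = seed,
    n_yc = n_yc, n_amc = n_amc, n_pd = n_pd, profiles = profiles
  ), class = "pipeline_config")
}

#' Extract all gait features for one subject
#'
#' Runs the full per-subject chain: smoothing, contact detection, outlier
#' (turn) removal, stride intervals, phase series, cadence, spatial
#' estimates, the 28-parameter kinematic set and the 24-parameter kinetic
#' set.
#'
#' @param left,right Raw [grf_series()] for the two feet.
#' @param weight_kg Body mass (kg), for kinetic normalization.
#' @param distance_m Walked distance (m), from the manifest.
#' @param duration_s Recording duration (s); defaults to the series length.
#' @param config A [pipeline_config()].
#' @return A list: `kinematics` (1 x 28 tibble), `kinetics` (1 x 24 tibble),
#'   `events`, `intervals`, `cycles`, and a `log` tibble of per-stage counts.
#' @export
extract_gait_features <- function(left, right, weight_kg, distance_m,
                                  duration_s = NULL,
                                  config = pipeline_config()) {
  duration_s <- duration_s %||% (nrow(left) / grf_fs(left))
  sm <- list(left = moving_average(left, config$smooth_window),
             right = moving_average(right, config$smooth_window))
  ev <- lapply(sm, function(s) {
    remove_outlier_strides(
      detect_contacts(s, config$contact_threshold_frac),
      window = config$outlier_window, mad_factor = config$mad_factor
    )
  })
  iv <- stride_intervals(ev$left, ev$right)
  ph <- phase_stats(phase_series(ev$left, ev$right),
                    deviation = config$phase_deviation)
  cad <- estimate_cadence(sm$left, sm$right)
  # every detected foot-strike is a step taken (turn strides are real steps;
  # they are excluded from timing statistics, not from the step count)
  n_steps <- nrow(ev$left) + nrow(ev$right)
  kin <- assemble_kinematics(iv, ph, cad, n_steps, duration_s, distance_m)

  # kinetics are segmented from the raw series: smoothing is for event
  # detection and cadence, and would attenuate and shift the stance peaks
  cyc <- list(
    left = segment_stance_cycles(left, ev$left, weight_kg),
    right = segment_stance_cycles(right, ev$right, weight_kg)
  )
  feats <- lapply(cyc, m_shape_features)
  knt <- assemble_kinetics(feats$left, feats$right)

  log <- tibble::tibble(
    side = c("left", "right"),
    strides_detected = c(nrow(ev$left), nrow(ev$right)),
    strides_removed = c(sum(!ev$left$valid), sum(!ev$right$valid)),
    cycles_skipped = c(attr(cyc$left, "n_skipped"), attr(cyc$right, "n_skipped")),
    cycles_unusable = c(sum(!feats$left$usable), sum(!feats$right$usable))
  )
  list(kinematics = kin, kinetics = knt, events = ev, intervals = iv,
       cycles = cyc, phase = ph, log = log)
}

#' Extract the per-subject feature table for a whole cohort
#'
#' @param cohort A [generate_cohort()] result (or a compatible list with
#'   `subjects`, `grf`).
#' @param config A [pipeline_config()].
#' @return A tibble: one row per subject with demographics (and clinical
#'   columns where present), the 28 kinematic and 24 kinetic parameters, and
#'   the per-subject processing log as attribute `logs`.
#' @export
extract_cohort_features <- function(cohort, config = pipeline_config()) {
  subs <- cohort$subjects
  rows <- vector("list", nrow(subs))
  logs <- vector("list", nrow(subs))
  for (i in seq_len(nrow(subs))) {
    id <- subs$subject_id[i]
    res <- tryCatch(
      extract_gait_features(
        cohort$grf[[id]]$left, cohort$grf[[id]]$right,
        weight_kg = subs$weight_kg[i],
        distance_m = subs$distance_m[i],
        duration_s = subs$duration_s[i],
        config = config
      ),
      error = function(e) {
        abort(sprintf("Feature extraction failed for subject %s: %s",
                      id, conditionMessage(e)))
      }
    )
    rows[[i]] <- dplyr::bind_cols(subs[i, ], res$kinematics, res$kinetics)
    logs[[i]] <- dplyr::mutate(res$log, subject_id = id, .before = 1)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "logs") <- dplyr::bind_rows(logs)
  out
}

#' Run the full simulate - extract - analyze - classify pipeline
#'
#' Generates (or accepts) a cohort, extracts the per-subject feature table,
#' runs group comparisons on demographic, kinematic and kinetic parameters,
#' ranks predictors of the coordination parameters with RReliefF, and
#' classifies group membership with leave-one-out LDA on the four predictor
#' datasets (I kinematics, II kinetics, III both, IV demographics + both).
#' Rerunning with the same config is deterministic.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional pre-built [generate_cohort()] result; by default a
#'   cohort is simulated from the config.
#' @param out_dir Optional directory: feature/comparison/ranking CSVs, a
#'   classification report JSON and a run manifest are written there.
#' @return An object of class `gait_pipeline`: `cohort`, `features`,
#'   `comparisons`, `rankings`, `classification` (list of
#'   [loo_cross_validate()] reports for datasets I-IV), `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be a <pipeline_config>.")
  }
  cohort <- cohort %||% generate_cohort(
    n_yc = config$n_yc, n_amc = config$n_amc, n_pd = config$n_pd,
    profiles = config$profiles, seed = config$seed
  )
  features <- extract_cohort_features(cohort, config)

  demo_cols <- intersect(c("age_years", "weight_kg", "height_m", "bmi_kg_m2"),
                         names(features))
  param_cols <- c(demo_cols, intersect(
    c(kinematic_parameter_names(), kinetic_parameter_names()), names(features)))
  comparisons <- if (length(unique(features$group)) >= 2 &&
                     min(table(features$group)) >= 3) {
    compare_groups(features[param_cols], features$group)
  } else NULL

  rankings <- if (length(unique(features$group)) >= 1) {
    rank_gait_predictors(features, k = config$relieff_k)
  } else NULL

  datasets <- build_predictor_datasets(features)
  classification <- purrr::imap(datasets, function(d, id) {
    suppressWarnings(loo_cross_validate(d, dataset_id = id))
  })

  result <- structure(list(
    cohort = cohort, features = features, comparisons = comparisons,
    rankings = rankings, classification = classification, config = config
  ), class = "gait_pipeline")

  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(result$features, file.path(out_dir, "features.csv"))
  if (!is.null(result$comparisons)) {
    readr::write_csv(result$comparisons,
                     file.path(out_dir, "group_comparisons.csv"),
                     progress = FALSE)
  }
  if (!is.null(result$rankings)) {
    readr::write_csv(result$rankings, file.path(out_dir, "feature_rankings.csv"),
                     progress = FALSE)
  }
  reports <- purrr::map(result$classification, function(r) {
    list(dataset = r$dataset_id,
         confusion = as.data.frame(r$confusion),
         metrics = r$metrics, n_folds = r$n_folds,
         n_regularized = r$n_regularized)
  })
  jsonlite::write_json(reports, file.path(out_dir, "classification.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  manifest <- list(
    package_version = as.character(utils::packageVersion("insolegait")),
    r_version = R.version.string,
    seed = result$config$seed,
    config = result$config[setdiff(names(result$config), "profiles")],
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.gait_pipeline <- function(x, ...) {
  cat(sprintf("<gait_pipeline: %d subjects, seed %s>\n",
              nrow(x$features), format(x$config$seed)))
  accs <- vapply(x$classification, function(r) r$metrics$acc, numeric(1))
  cat("LOO-LDA accuracy (%):",
      paste(sprintf("%s=%.1f", names(accs), accs), collapse = ", "), "\n")
  invisible(x)
}
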