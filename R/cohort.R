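#' Generate a synthetic two-insole free-walking cohort
#'
#' Simulates a full study cohort: per-subject demographics (and clinical
#' variables for the PD group), a stride schedule per subject drawn from the
#' group profile with subject-level variation, and a left and right vertical
#' GRF series assembled from M-shaped stance curves with additive Gaussian
#' measurement noise and turn artifacts at the walkway ends. Everything the
#' downstream pipeline estimates is recorded as ground truth.
#'
#' Subject-level variation (documented in the methods vignette): a common
#' timing scale factor (3% cv) on stride and swing means, an independent
#' per-leg swing perturbation (0.4% cv) generating between-subject asymmetry
#' spread, a lognormal factor (0.15 sd) on double-support jitter and phase
#' noise, and a subject phase set-point drawn around the profile offset. For
#' PD subjects the double-support jitter is additionally coupled to disease
#' duration (`1 + 0.35 * z(duration)`), emulating the dependence of
#' double-support variability on clinical status.
#'
#' @param n_yc,n_amc,n_pd Group sizes (default 16, 12, 11). A group size of 0
#'   omits the group entirely (and with `n_pd = 0` no clinical columns appear).
#' @param profiles Named list of [gait_profile()]s; defaults to
#'   [default_profiles()].
#' @param seed Integer seed; identical `(profiles, seed)` give byte-identical
#'   cohorts.
#' @return An object of class `gait_cohort`: a list with `subjects` (tibble),
#'   `grf` (per subject, `$left`/`$right` [grf_series()] in Newtons),
#'   `truth` (per subject, the [generate_stride_schedule()] output plus the
#'   landmark template and distance), and `profiles`.
#' @export
generate_cohort <- function(n_yc = 16, n_amc = 12, n_pd = 11,
                            profiles = default_profiles(), seed = 1) {
  ns <- c(YC = n_yc, AMC = n_amc, PD = n_pd)
  if (any(ns < 0) || sum(ns) < 1) abort("Group sizes must be >= 0 and sum to >= 1.")
  groups <- rep(names(ns), ns)
  missing_prof <- setdiff(unique(groups), names(profiles))
  if (length(missing_prof) > 0) {
    abort(sprintf("`profiles` is missing group(s): %s",
                  paste(missing_prof, collapse = ", ")))
  }

  with_rng_seed(seed, {
    subjects <- make_demographics(ns)
    grf <- vector("list", nrow(subjects))
    truth <- vector("list", nrow(subjects))
    names(grf) <- names(truth) <- subjects$subject_id

    for (i in seq_len(nrow(subjects))) {
      g <- subjects$group[i]
      base <- profiles[[g]]
      dur_z <- if (g == "PD" && !is.na(subjects$disease_duration_years[i])) {
        (subjects$disease_duration_years[i] - 4) / 1.8
      } else 0
      prof_i <- subject_profile(base, dur_z)
      offset_i <- if (base$phase_offset_lateral_deg > 0) {
        # lateralized set-point: consistent magnitude, random side
        base$phase_offset_deg + sample(c(-1, 1), 1) *
          (base$phase_offset_lateral_deg +
             abs(stats::rnorm(1, 0, base$phase_offset_subject_sd_deg)))
      } else {
        base$phase_offset_deg +
          stats::rnorm(1, 0, base$phase_offset_subject_sd_deg)
      }
      sched_seed <- sample.int(2147483646L, 1)
      noise_seed <- sample.int(2147483646L, 1)
      sched <- generate_stride_schedule(prof_i, seed = sched_seed,
                                        phase_offset_deg = offset_i)
      sig <- synthesize_subject_grf(sched, prof_i,
                                    weight_kg = subjects$weight_kg[i],
                                    subject_id = subjects$subject_id[i],
                                    seed = noise_seed)
      n_turns <- length(sched$turn_strides$left)
      every <- prof_i$turn_every_n_strides
      distance_m <- if (is.finite(every)) {
        prof_i$walkway_length_m * nrow(sched$left) / every
      } else {
        # no turns: straight-line walking at nominal speed
        prof_i$walkway_length_m * nrow(sched$left) / 17
      }
      grf[[i]] <- sig
      truth[[i]] <- list(
        schedule = sched,
        landmarks = prof_i$landmark_fractions,
        peaks = prof_i$peak_magnitudes_bw,
        distance_m = distance_m,
        n_turns = n_turns
      )
    }
    subjects$distance_m <- vapply(truth, function(t) t$distance_m, numeric(1))
    subjects$duration_s <- vapply(seq_along(truth), function(i)
      profiles[[subjects$group[i]]]$duration_s, numeric(1))

    if (ns["PD"] == 0) {
      subjects <- subjects[, setdiff(names(subjects),
        c("updrs_iii", "mmse", "ledd_mg", "disease_duration_years",
          "affected_side"))]
    }
    structure(list(subjects = subjects, grf = grf, truth = truth,
                   profiles = profiles, seed = seed),
              class = "gait_cohort")
  })
}

# Subject-level perturbation of a group profile.
subject_profile <- function(base, dur_z = 0) {
  p <- base
  scale <- 1 + stats::rnorm(1, 0, 0.03)
  asym <- 1 + stats::rnorm(2, 0, 0.0025)
  p$stride_time_mean_s <- p$stride_time_mean_s * scale
  p$swing_time_mean_s <- p$swing_time_mean_s * scale * asym
  ds_mult <- exp(stats::rnorm(1, 0, 0.15)) * max(1 + 0.35 * dur_z, 0.3)
  p$double_support_sd_s <- p$double_support_sd_s * ds_mult
  p$phase_sd_deg <- p$phase_sd_deg * exp(stats::rnorm(1, 0, 0.15))
  validate_gait_profile(p)
}

#' Synthesize the two per-foot GRF series from a stride schedule
#'
#' Assembles left and right vertical GRF recordings (in Newtons) from a
#' [generate_stride_schedule()]: one M-shaped stance curve per stride
#' ([synth_stance_curve()] template), force scaled by 0.8 for turn strides,
#' plus additive Gaussian measurement noise clipped at zero.
#'
#' @param sched A `stride_schedule`.
#' @param profile The [gait_profile()] the schedule was generated from.
#' @param weight_kg Subject body mass (kg); body-weight force is
#'   `weight_kg * 9.81`.
#' @param subject_id Subject identifier for the series metadata.
#' @param seed Optional seed for the measurement noise.
#' @return A list with `left` and `right` [grf_series()].
#' @export
synthesize_grf <- function(sched, profile, weight_kg = 70,
                           subject_id = "S01", seed = NULL) {
  if (!inherits(sched, "stride_schedule")) {
    abort("`sched` must be a <stride_schedule>.")
  }
  synthesize_subject_grf(sched, profile, weight_kg, subject_id, seed)
}

# Assemble the two per-foot GRF series (in Newtons) from a schedule.
synthesize_subject_grf <- function(sched, profile, weight_kg, subject_id,
                                   seed = NULL) {
  p <- profile
  fs <- p$sampling_rate_hz
  n <- floor(p$duration_s * fs)
  bw_n <- weight_kg * 9.81
  with_rng_seed(seed, {
    out <- lapply(c(left = "left", right = "right"), function(side) {
      tab <- sched[[side]]
      force <- numeric(n)
      for (k in seq_len(nrow(tab))) {
        i0 <- ceiling(tab$strike_s[k] * fs) + 1
        i1 <- floor(tab$toe_off_s[k] * fs) + 1
        if (i1 > n) i1 <- n
        if (i1 <= i0) next
        t <- (seq(i0, i1) - 1) / fs
        u <- (t - tab$strike_s[k]) / (tab$toe_off_s[k] - tab$strike_s[k])
        amp <- if (tab$turn[k]) 0.8 else 1
        force[i0:i1] <- amp * stance_template_at(u, p$landmark_fractions,
                                                 p$peak_magnitudes_bw)
      }
      if (p$noise_sd_bw > 0) {
        force <- force + stats::rnorm(n, 0, p$noise_sd_bw)
        force[force < 0] <- 0
      }
      grf_series(force * bw_n, fs, side = side, units = "N",
                 subject_id = subject_id)
    })
    out
  })
}

# Demographics per group, sampled around the study's group medians.
make_demographics <- function(ns) {
  demo <- list(
    YC = list(age = c(29.5, 3.63), weight = c(68, 9.28), height = c(1.68, 0.08),
              p_female = 7 / 16),
    AMC = list(age = c(56.5, 12.4), weight = c(70, 11.03), height = c(1.70, 0.07),
               p_female = 4 / 12),
    PD = list(age = c(57, 7.84), weight = c(81, 12.92), height = c(1.75, 0.09),
              p_female = 1 / 11)
  )
  rows <- lapply(names(ns), function(g) {
    k <- ns[[g]]
    if (k == 0) return(NULL)
    d <- demo[[g]]
    tibble::tibble(
      subject_id = sprintf("%s%02d", g, seq_len(k)),
      group = g,
      age_years = round(rnorm_trunc(k, d$age[1], d$age[2], lower = 18)),
      sex = ifelse(stats::runif(k) < d$p_female, "F", "M"),
      weight_kg = round(rnorm_trunc(k, d$weight[1], d$weight[2], lower = 40), 1),
      height_m = round(rnorm_trunc(k, d$height[1], d$height[2], lower = 1.4), 2),
      updrs_iii = if (g == "PD") round(rnorm_trunc(k, 15, 4.28, lower = 1)) else NA_real_,
      mmse = if (g == "PD") pmin(round(rnorm_trunc(k, 29, 1.63, lower = 20)), 30) else NA_real_,
      ledd_mg = if (g == "PD") round(rnorm_trunc(k, 400, 327, lower = 50)) else NA_real_,
      disease_duration_years = if (g == "PD") {
        round(rnorm_trunc(k, 4, 1.8, lower = 0.5), 1)
      } else NA_real_,
      affected_side = if (g == "PD") {
        ifelse(stats::runif(k) < 4 / 11, "left", "right")
      } else NA_character_
    )
  })
  out <- dplyr::bind_rows(rows)
  out$bmi_kg_m2 <- round(out$weight_kg / out$height_m^2, 2)
  dplyr::relocate(out, "bmi_kg_m2", .after = "height_m")
}

#' @export
print.gait_cohort <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat(sprintf("<gait_cohort: %d subjects (%s), seed %s>\n",
              nrow(x$subjects),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              format(x$seed)))
  invisible(x)
}

#' Write a cohort to disk as plain-text files
#'
#' Writes one GRF CSV per foot per subject (`grf_<id>_<side>.csv`, columns
#' `time_s,force` in Newtons), a cohort manifest CSV (`manifest.csv`, one row
#' per subject including weight, distance and duration), and a ground-truth
#' JSON sidecar per subject (`truth_<id>.json`) with the true event schedule
#' and turn indices.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "gait_cohort")) abort("`cohort` must be a <gait_cohort>.")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(cohort$subjects, file.path(dir, "manifest.csv"),
                   progress = FALSE)
  for (id in names(cohort$grf)) {
    for (side in c("left", "right")) {
      write_grf_csv(cohort$grf[[id]][[side]],
                    file.path(dir, sprintf("grf_%s_%s.csv", id, side)))
    }
    tr <- cohort$truth[[id]]
    sidecar <- list(
      subject_id = id,
      landmarks = tr$landmarks, peaks = tr$peaks,
      distance_m = tr$distance_m, n_turns = tr$n_turns,
      left = as.list(tr$schedule$left), right = as.list(tr$schedule$right)
    )
    jsonlite::write_json(sidecar, file.path(dir, sprintf("truth_%s.json", id)),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
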