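#' Feature-selection analyses of the PD-differentiating gait parameters
#'
#' For each of the four coordination parameters that differentiate the PD
#' group (DST CV, GA, phi deviation, PCI) and each group separately, ranks
#' the demographic + kinematic + kinetic predictors with RReliefF
#' ([relieff_rank()], regression mode, since the responses are continuous).
#' The response itself and its algebraic components are excluded from the
#' predictor pool; for the PD group the clinical variables (UPDRS-III, MMSE,
#' LEDD, disease duration, affected side) are added to the pool.
#'
#' @param features A per-subject feature table: `group` plus demographic,
#'   kinematic, kinetic (and, for PD rows, clinical) columns, as produced by
#'   [run_pipeline()]/[extract_cohort_features()].
#' @param k Number of RReliefF neighbors (default 10, truncated per group if
#'   needed).
#' @param responses Response parameters (default the four above).
#' @return A tibble: `response`, `group`, `predictor`, `weight`, `constant`,
#'   ordered by non-increasing weight within each response x group block
#'   (one block per response and group: 4 x 3 = 12 rankings for a full
#'   cohort).
#' @export
rank_gait_predictors <- function(features, k = 10,
                                 responses = c("DST CV", "GA",
                                               "phi deviation", "PCI")) {
  df <- tibble::as_tibble(features)
  if (!"group" %in% names(df)) abort("`features` needs a `group` column.")
  demo <- c("age_years", "sex", "weight_kg", "height_m", "bmi_kg_m2")
  clinical <- c("updrs_iii", "mmse", "ledd_mg", "disease_duration_years",
                "affected_side")
  gait <- intersect(c(kinematic_parameter_names(), kinetic_parameter_names()),
                    names(df))
  components <- list(
    "DST CV" = c("DST CV"),
    "GA" = c("GA"),
    "phi deviation" = c("phi deviation", "PCI"),
    "PCI" = c("PCI", "phi CV", "phi deviation")
  )
  missing_resp <- setdiff(responses, names(df))
  if (length(missing_resp) > 0) {
    abort(sprintf("Response column(s) not in `features`: %s",
                  paste(missing_resp, collapse = ", ")))
  }
  out <- list()
  for (resp in responses) {
    excl <- components[[resp]] %||% resp
    for (g in unique(df$group)) {
      sub <- df[df$group == g, ]
      pool <- c(intersect(demo, names(df)), setdiff(gait, excl))
      if (g == "PD") pool <- c(pool, intersect(clinical, names(df)))
      kg <- min(k, nrow(sub) - 1L)
      if (kg < 1) abort(sprintf("Group %s too small for ranking.", g))
      if (kg < k) {
        inform(sprintf("Group %s: k truncated to %d.", g, kg))
      }
      rk <- relieff_rank(sub[pool], sub[[resp]], k = kg, mode = "regression")
      rk$response <- resp
      rk$group <- g
      out[[length(out) + 1L]] <- rk
    }
  }
  dplyr::relocate(dplyr::bind_rows(out), "response", "group")
}
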