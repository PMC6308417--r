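#' Tidy a fitted linear discriminant model
#'
#' @param x A [fit_lda()] object.
#' @param ... Unused.
#' @return A tibble with one row per class x predictor: the class mean and
#'   the discriminant weight.
#' @export
tidy.gait_lda <- function(x, ...) {
  p <- ncol(x$means)
  preds <- colnames(x$means) %||% paste0("x", seq_len(p))
  tidyr::expand_grid(class = x$classes, predictor = preds) |>
    dplyr::mutate(
      mean = as.vector(t(x$means)),
      weight = as.vector(x$W)
    )
}

#' @rdname tidy.gait_lda
#' @export
glance.gait_lda <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$classes),
    n_predictors = ncol(x$means),
    regularized = x$regularized
  )
}

#' Tidy a leave-one-out classification report
#'
#' @param x A [loo_cross_validate()] report.
#' @param ... Unused.
#' @return The confusion matrix in long form: `true`, `predicted`, `n`.
#' @export
tidy.gait_loo_report <- function(x, ...) {
  df <- as.data.frame(x$confusion, responseName = "n")
  tibble::tibble(true = as.character(df$true),
                 predicted = as.character(df$predicted),
                 n = df$n)
}

#' @rdname tidy.gait_loo_report
#' @export
glance.gait_loo_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(dataset = x$dataset_id, n_folds = x$n_folds),
    x$metrics,
    tibble::tibble(n_regularized = x$n_regularized)
  )
}
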