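#' Fit a linear discriminant model with pooled full covariance
#'
#' Classical LDA: per-class means, a pooled (within-class) full covariance
#' matrix and empirical class priors. Prediction assigns the class maximizing
#' the linear discriminant score
#' `x' S^-1 mu_k - mu_k' S^-1 mu_k / 2 + log pi_k`.
#' When the pooled covariance is singular (more predictors than training
#' samples), a small ridge `lambda = 1e-6 * mean(diag(S))` is added to the
#' diagonal, with a warning.
#'
#' @param train_matrix Numeric matrix (subjects x predictors).
#' @param train_labels Class labels (>= 2 classes, >= 2 instances each).
#' @return An object of class `gait_lda`: means, pooled covariance, priors,
#'   the discriminant weights, and a `regularized` flag.
#' @export
fit_lda <- function(train_matrix, train_labels) {
  X <- as.matrix(train_matrix)
  storage.mode(X) <- "double"
  y <- factor(train_labels)
  if (nlevels(y) < 2) abort("Need at least 2 classes.")
  if (any(table(y) < 2)) abort("Every class needs at least 2 training instances.")
  n <- nrow(X); p <- ncol(X); g <- nlevels(y)
  means <- t(vapply(levels(y), function(cl) colMeans(X[y == cl, , drop = FALSE]),
                    numeric(p)))
  centered <- X - means[as.integer(y), , drop = FALSE]
  S <- crossprod(centered) / (n - g)
  priors <- as.numeric(table(y)) / n
  regularized <- FALSE
  Sinv <- tryCatch(chol2inv(chol(S)), error = function(e) NULL)
  if (is.null(Sinv) || !all(is.finite(Sinv))) {
    lambda <- 1e-6 * mean(diag(S))
    if (lambda <= 0) lambda <- 1e-6
    S_r <- S + diag(lambda, p)
    Sinv <- tryCatch(chol2inv(chol(S_r)), error = function(e) MASS_ginv(S_r))
    regularized <- TRUE
    warn("Singular pooled covariance: ridge regularization applied.")
  }
  W <- Sinv %*% t(means)                       # p x g discriminant directions
  b <- -0.5 * colSums(t(means) * W) + log(priors)
  structure(list(
    classes = levels(y), means = means, cov = S, cov_inv = Sinv,
    priors = priors, W = W, b = b, regularized = regularized
  ), class = "gait_lda")
}

# Moore-Penrose fallback without depending on MASS at run time.
MASS_ginv <- function(S, tol = sqrt(.Machine$double.eps)) {
  e <- eigen(S, symmetric = TRUE)
  pos <- e$values > tol * max(e$values)
  e$vectors[, pos, drop = FALSE] %*%
    (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
}

#' Linear discriminant scores and class predictions
#'
#' @param object A [fit_lda()] model.
#' @param newdata Numeric matrix of observations.
#' @param type `"class"` (default) or `"scores"`.
#' @param ... Unused.
#' @return Predicted class labels, or the n x classes score matrix.
#' @export
predict.gait_lda <- function(object, newdata, type = c("class", "scores"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  scores <- X %*% object$W + rep(object$b, each = nrow(X))
  colnames(scores) <- object$classes
  if (type == "scores") return(scores)
  object$classes[max.col(scores, ties.method = "first")]
}

#' Build the four predictor datasets for classification
#'
#' Dataset I: the 28 kinematic parameters; II: the 24 kinetic parameters;
#' III: kinematics + kinetics (52); IV: 4 demographics (age, sex coded 0/1,
#' weight, height) + kinematics + kinetics (56). Clinical variables are
#' never included (controls lack them).
#'
#' @param features Per-subject feature table with demographic, kinematic and
#'   kinetic columns plus `group`.
#' @return A named list (`I`..`IV`) of lists with `x` (numeric matrix),
#'   `labels` and `predictors`.
#' @export
build_predictor_datasets <- function(features) {
  df <- tibble::as_tibble(features)
  kin <- kinematic_parameter_names()
  knt <- kinetic_parameter_names()
  missing <- setdiff(c(kin, knt, "group"), names(df))
  if (length(missing) > 0) {
    abort(sprintf("`features` is missing column(s): %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  demo <- tibble::tibble(
    age_years = df$age_years,
    sex = as.numeric(df$sex == "F"),
    weight_kg = df$weight_kg,
    height_m = df$height_m
  )
  as_mat <- function(d) {
    m <- as.matrix(d)
    storage.mode(m) <- "double"
    if (anyNA(m)) abort("Predictor datasets must not contain missing values.")
    m
  }
  labels <- df$group
  list(
    I = list(x = as_mat(df[kin]), labels = labels, predictors = kin),
    II = list(x = as_mat(df[knt]), labels = labels, predictors = knt),
    III = list(x = as_mat(df[c(kin, knt)]), labels = labels,
               predictors = c(kin, knt)),
    IV = list(x = as_mat(dplyr::bind_cols(demo, df[c(kin, knt)])),
              labels = labels,
              predictors = c(names(demo), kin, knt))
  )
}

#' Leave-one-out cross-validated LDA classification
#'
#' n-fold (leave-one-out) cross-validation: each fold holds out one subject,
#' z-score standardization parameters are fit on the training fold only, an
#' LDA model is fit and the held-out subject classified. The confusion matrix
#' is accumulated over folds and summarized with overall accuracy and macro
#' one-vs-rest sensitivity and specificity.
#'
#' @param x Numeric matrix (subjects x predictors) or a dataset entry from
#'   [build_predictor_datasets()].
#' @param labels Class labels (ignored when `x` is a dataset entry).
#' @param dataset_id Optional label for the report.
#' @return An object of class `gait_loo_report`: `confusion` (true x
#'   predicted), `metrics` (ACC/SEN/SPE in percent), `per_class_recall`,
#'   `fold_predictions`, `n_folds`, `n_regularized`.
#' @export
loo_cross_validate <- function(x, labels = NULL, dataset_id = NA_character_) {
  if (is.list(x) && !is.matrix(x) && !is.data.frame(x)) {
    labels <- labels %||% x$labels
    x <- x$x
  }
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  y <- factor(labels)
  n <- nrow(X)
  if (n < nlevels(y) + 2) abort("Too few subjects for leave-one-out CV.")
  classes <- levels(y)
  pred <- character(n)
  skipped <- logical(n)
  n_reg <- 0L
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    ytr <- droplevels(y[tr])
    if (nlevels(ytr) < nlevels(y) || min(table(ytr)) < 2) {
      warn(sprintf(
        "Fold %d skipped: a class (nearly) vanished from the training set.", i))
      skipped[i] <- TRUE
      next
    }
    mu <- colMeans(X[tr, , drop = FALSE])
    sg <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sg[sg == 0] <- 1
    Ztr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sg, "/")
    Zte <- (X[i, ] - mu) / sg
    fit <- withCallingHandlers(
      fit_lda(Ztr, ytr),
      warning = function(w) {
        if (grepl("ridge regularization", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    if (fit$regularized) n_reg <- n_reg + 1L
    pred[i] <- predict(fit, matrix(Zte, nrow = 1))
  }
  keep <- !skipped
  confusion <- table(
    true = factor(y[keep], levels = classes),
    predicted = factor(pred[keep], levels = classes)
  )
  metrics <- report_metrics(confusion)
  structure(list(
    dataset_id = dataset_id,
    confusion = confusion,
    metrics = metrics$summary,
    per_class_recall = metrics$per_class,
    fold_predictions = tibble::tibble(
      fold = seq_len(n), true = as.character(y),
      predicted = ifelse(skipped, NA_character_, pred), skipped = skipped
    ),
    n_folds = sum(keep),
    n_regularized = n_reg
  ), class = "gait_loo_report")
}

#' Classification metrics from a confusion matrix
#'
#' Overall accuracy (trace / total), macro sensitivity (mean per-class
#' recall) and macro specificity (mean per-class true-negative rate,
#' one-vs-rest), all in percent.
#'
#' @param confusion Square count matrix/table, true classes in rows.
#' @return A list: `summary` (one-row tibble `acc`, `sen`, `spe`) and
#'   `per_class` (tibble `class`, `recall`, `specificity`).
#' @export
report_metrics <- function(confusion) {
  C <- as.matrix(confusion)
  if (nrow(C) != ncol(C) || nrow(C) == 0) {
    abort("`confusion` must be a non-empty square matrix.")
  }
  total <- sum(C)
  if (total == 0) abort("`confusion` has no counts.")
  tp <- diag(C)
  rows <- rowSums(C)
  cols <- colSums(C)
  recall <- ifelse(rows > 0, tp / rows, NA_real_)
  tn <- total - rows - cols + tp
  fp <- cols - tp
  spec <- ifelse(tn + fp > 0, tn / (tn + fp), NA_real_)
  list(
    summary = tibble::tibble(
      acc = 100 * sum(tp) / total,
      sen = 100 * mean(recall, na.rm = TRUE),
      spe = 100 * mean(spec, na.rm = TRUE)
    ),
    per_class = tibble::tibble(
      class = rownames(C) %||% as.character(seq_len(nrow(C))),
      recall = 100 * recall,
      specificity = 100 * spec
    )
  )
}

#' @export
print.gait_loo_report <- function(x, ...) {
  cat(sprintf("<gait_loo_report%s: %d folds, ACC %.1f%%, SEN %.1f%%, SPE %.1f%%>\n",
              if (is.na(x$dataset_id)) "" else paste0(" ", x$dataset_id),
              x$n_folds, x$metrics$acc, x$metrics$sen, x$metrics$spe))
  print(x$confusion)
  invisible(x)
}
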