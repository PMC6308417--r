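#' Group comparisons: Kruskal-Wallis omnibus with Wilcoxon post-hocs
#'
#' For every parameter column, runs a tie-corrected Kruskal-Wallis test
#' across groups; when the omnibus test is significant (`p < alpha`),
#' pairwise Wilcoxon rank-sum tests compare two groups at a time. No
#' multiplicity correction is applied. Group medians and standard deviations
#' are reported alongside.
#'
#' @param feature_table A data frame of numeric parameter columns (any
#'   non-numeric columns are dropped with a message).
#' @param group_labels A factor/character vector of group membership, one per
#'   row of `feature_table`.
#' @param alpha Omnibus significance gate for the post-hocs (default 0.05).
#' @return A tibble with one row per parameter: `parameter`, per-group
#'   `median_*` and `sd_*`, `chi_square_kw`, `p_value`, one `p_<A>_vs_<B>`
#'   column per group pair (NA unless the omnibus test passes), and
#'   `constant` flagging parameters with no variation (no test performed).
#' @export
compare_groups <- function(feature_table, group_labels, alpha = 0.05) {
  g <- factor(group_labels)
  if (nlevels(g) < 2) abort("Need at least 2 groups.")
  if (any(table(g) < 3)) abort("Need at least 3 subjects per group.")
  df <- tibble::as_tibble(feature_table)
  if (nrow(df) != length(g)) {
    abort("`feature_table` rows and `group_labels` must align.")
  }
  num <- vapply(df, is.numeric, logical(1))
  if (any(!num)) {
    inform(sprintf("Dropping non-numeric column(s): %s",
                   paste(names(df)[!num], collapse = ", ")))
    df <- df[num]
  }
  lev <- levels(g)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  rows <- purrr::map(names(df), function(par) {
    x <- df[[par]]
    row <- list(parameter = par)
    for (l in lev) {
      row[[paste0("median_", l)]] <- stats::median(x[g == l])
      row[[paste0("sd_", l)]] <- stats::sd(x[g == l])
    }
    if (length(unique(x)) == 1) {
      row$chi_square_kw <- NA_real_
      row$p_value <- NA_real_
      row$constant <- TRUE
      for (pr in pairs) row[[pair_col(pr)]] <- NA_real_
      return(tibble::as_tibble(row))
    }
    kw <- stats::kruskal.test(x, g)
    row$chi_square_kw <- unname(kw$statistic)
    row$p_value <- kw$p.value
    row$constant <- FALSE
    for (pr in pairs) {
      row[[pair_col(pr)]] <- if (is.finite(kw$p.value) && kw$p.value < alpha) {
        suppressWarnings(
          stats::wilcox.test(x[g == pr[1]], x[g == pr[2]], exact = FALSE)$p.value
        )
      } else {
        NA_real_
      }
    }
    tibble::as_tibble(row)
  })
  dplyr::bind_rows(rows)
}

pair_col <- function(pr) sprintf("p_%s_vs_%s", pr[1], pr[2])

# Range-normalized per-feature difference matrix helpers. Nominal features
# (factors/characters) contribute a 0/1 indicator difference.
relief_prepare <- function(predictors) {
  df <- tibble::as_tibble(predictors)
  if (anyNA(df)) abort("Predictors must not contain missing values.")
  X <- matrix(0, nrow(df), ncol(df), dimnames = list(NULL, names(df)))
  nominal <- logical(ncol(df))
  for (j in seq_along(df)) {
    v <- df[[j]]
    if (is.numeric(v)) {
      X[, j] <- v
    } else {
      nominal[j] <- TRUE
      X[, j] <- as.numeric(factor(v))
    }
  }
  rng <- apply(X, 2, function(v) diff(range(v)))
  constant <- rng == 0
  rng[constant] <- 1
  list(X = X, rng = rng, nominal = nominal, constant = constant)
}

relief_diff <- function(prep, i, j) {
  d <- abs(prep$X[i, ] - prep$X[j, ]) / prep$rng
  d[prep$nominal] <- as.numeric(prep$X[i, prep$nominal] != prep$X[j, prep$nominal])
  d[prep$constant] <- 0
  d
}

relief_dist_row <- function(prep, i) {
  D <- abs(sweep(prep$X, 2, prep$X[i, ])) / rep(prep$rng, each = nrow(prep$X))
  if (any(prep$nominal)) {
    D[, prep$nominal] <- (sweep(prep$X[, prep$nominal, drop = FALSE], 2,
                                prep$X[i, prep$nominal]) != 0) * 1
  }
  D[, prep$constant] <- 0
  rowSums(D)
}

#' ReliefF / RReliefF feature weights
#'
#' Nearest-neighbor feature weighting. In `classification` mode this is
#' ReliefF: every instance serves as an anchor; for each anchor the `k`
#' nearest same-class hits and, per other class, the `k` nearest misses
#' (range-normalized Manhattan distance) update each feature's weight —
#' negative for differing among hits, positive for differing among misses,
#' with miss contributions weighted by the class prior relative to the
#' anchor's complement. In `regression` mode this is the RReliefF extension:
#' the `k` nearest neighbors of each anchor contribute with exponential
#' rank-based distance weights, and feature relevance is estimated from the
#' probabilities of differing in feature and in (continuous) response.
#'
#' Weights lie in \[-1, 1\]. Constant predictors receive weight 0 and are
#' flagged. `k` is truncated (with a warning) when a class, or the data set,
#' has too few instances.
#'
#' @param predictors Data frame of predictors (numeric, or nominal as
#'   factor/character) with no missing values.
#' @param response Class labels (`classification`) or a numeric response
#'   (`regression`).
#' @param k Number of neighbors (default 10).
#' @param mode `"classification"` or `"regression"` (default chosen from the
#'   response type).
#' @param sigma Rank-weighting scale for regression mode (default `k`).
#' @return A tibble of class `feature_ranking`: `predictor`, `weight`,
#'   `constant`, sorted by non-increasing weight.
#' @export
relieff_rank <- function(predictors, response, k = 10, mode = NULL,
                         sigma = NULL) {
  prep <- relief_prepare(predictors)
  m <- nrow(prep$X)
  if (m < 2) abort("Need at least 2 instances.")
  if (length(response) != m) abort("`response` must match `predictors` rows.")
  if (anyNA(response)) abort("`response` must not contain missing values.")
  mode <- mode %||% if (is.numeric(response)) "regression" else "classification"
  mode <- match.arg(mode, c("classification", "regression"))
  if (k >= m) {
    warn(sprintf("k = %d >= number of instances; truncated to %d.", k, m - 1L))
    k <- m - 1L
  }
  w <- if (mode == "classification") {
    relieff_classification(prep, factor(response), k)
  } else {
    rrelieff_regression(prep, as.numeric(response), k, sigma %||% k)
  }
  w[prep$constant] <- 0
  out <- tibble::tibble(
    predictor = colnames(prep$X),
    weight = unname(w),
    constant = unname(prep$constant)
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$weight))
  structure(out, class = c("feature_ranking", class(out)), mode = mode, k = k)
}

relieff_classification <- function(prep, y, k) {
  m <- nrow(prep$X)
  p <- ncol(prep$X)
  prior <- table(y) / m
  classes <- levels(y)
  if (any(table(y) < 2)) {
    abort("Every class needs at least 2 instances for ReliefF.")
  }
  w <- numeric(p)
  for (i in seq_len(m)) {
    d <- relief_dist_row(prep, i)
    ord <- order(d, seq_len(m)) # stable: index breaks distance ties
    ord <- ord[ord != i]
    same <- ord[y[ord] == y[i]]
    k_hit <- min(k, length(same))
    hits <- same[seq_len(k_hit)]
    hit_contrib <- Reduce(`+`, lapply(hits, function(h) relief_diff(prep, i, h)))
    w <- w - hit_contrib / (m * k_hit)
    for (cl in classes[classes != y[i]]) {
      other <- ord[y[ord] == cl]
      k_miss <- min(k, length(other))
      if (k_miss == 0) next
      misses <- other[seq_len(k_miss)]
      miss_contrib <- Reduce(`+`, lapply(misses, function(h) relief_diff(prep, i, h)))
      coef <- prior[[cl]] / (1 - prior[[as.character(y[i])]])
      w <- w + coef * miss_contrib / (m * k_miss)
    }
  }
  w
}

rrelieff_regression <- function(prep, y, k, sigma) {
  m <- nrow(prep$X)
  p <- ncol(prep$X)
  y_rng <- diff(range(y))
  if (y_rng == 0) abort("Regression response is constant.")
  n_dy <- 0
  n_df <- numeric(p)
  n_dy_df <- numeric(p)
  total <- 0
  for (i in seq_len(m)) {
    d <- relief_dist_row(prep, i)
    ord <- order(d, seq_len(m))
    ord <- ord[ord != i]
    nb <- ord[seq_len(min(k, length(ord)))]
    wt <- exp(-(seq_along(nb) / sigma)^2)
    wt <- wt / sum(wt)
    dy <- abs(y[i] - y[nb]) / y_rng
    n_dy <- n_dy + sum(wt * dy)
    for (jj in seq_along(nb)) {
      dfv <- relief_diff(prep, i, nb[jj])
      n_df <- n_df + wt[jj] * dfv
      n_dy_df <- n_dy_df + wt[jj] * dy[jj] * dfv
    }
    total <- total + 1
  }
  if (n_dy == 0 || n_dy == total) {
    return(numeric(p))
  }
  n_dy_df / n_dy - (n_df - n_dy_df) / (total - n_dy)
}
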