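#' Coefficient of variation
#'
#' Stride-to-stride variability measure: `100 * sd(x) / mean(x)`, with the
#' sample (n - 1) standard deviation. Scale-invariant: `cv_percent(c * x)`
#' equals `cv_percent(x)` for any `c > 0`.
#'
#' @param x Numeric vector of at least two values with non-zero mean.
#' @return The coefficient of variation, in percent.
#' @export
#' @examples
#' cv_percent(c(1, 3)) # 70.71068
cv_percent <- function(x) {
  if (length(x) < 2) {
    abort("`x` must contain at least 2 values to compute a CV.")
  }
  if (anyNA(x)) abort("`x` must not contain missing values.")
  m <- mean(x)
  if (m == 0) abort("CV is undefined for values with zero mean.")
  100 * stats::sd(x) / m
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. `seed = NULL` leaves the RNG untouched.
with_rng_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    abort("`seed` must be a single finite number.")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(expr)
}

# Truncated normal draw by resampling; `lower` is a hard floor.
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  tries <- 0L
  while (length(bad) > 0 && tries < 100L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
    tries <- tries + 1L
  }
  pmin(pmax(x, lower), upper)
}

# Closed-form least-squares quadratic fit y ~ 1 + j + j^2 (normal
# equations; j should be small centered integers). Returns c(a, b, c) or
# NULL if the system is singular.
quad_ls <- function(j, y) {
  X <- cbind(1, j, j * j)
  co <- tryCatch(solve(crossprod(X), crossprod(X, y)),
                 error = function(e) NULL)
  if (is.null(co) || !all(is.finite(co))) return(NULL)
  as.numeric(co)
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name))
  }
  invisible(x)
}

# Recycle a scalar to a named left/right pair.
as_leg_pair <- function(x, name) {
  if (length(x) == 1) x <- c(left = unname(x), right = unname(x))
  if (length(x) != 2) abort(sprintf("`%s` must have length 1 or 2.", name))
  if (is.null(names(x)) || !all(c("left", "right") %in% names(x))) {
    names(x) <- c("left", "right")
  }
  x[c("left", "right")]
}
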