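test_that("Kruskal-Wallis matches hand values and gates the post-hocs", {
  # identical group distributions: H = 0, p = 1, no post-hoc
  df <- tibble::tibble(x = rep(c(1, 2, 3), 3))
  g <- rep(c("A", "B", "C"), each = 3)
  out <- compare_groups(df, g)
  expect_equal(out$chi_square_kw, 0)
  expect_equal(out$p_value, 1)
  expect_true(all(is.na(unlist(out[grep("_vs_", names(out))]))))

  # fully separated integer groups: H = 7.2 by hand rank computation
  df2 <- tibble::tibble(x = 1:9)
  out2 <- compare_groups(df2, g)
  expect_equal(out2$chi_square_kw, 7.2, tolerance = 1e-10)
  expect_lt(out2$p_value, 0.05)
  expect_false(any(is.na(unlist(out2[grep("_vs_", names(out2))]))))
})

test_that("Kruskal-Wallis H matches a rank-based brute-force oracle on small integer data", {
  withr::with_seed(10, {
    for (i in 1:25) {
      n <- sample(6:9, 1)
      x <- sample(1:5, n, replace = TRUE) # ties likely
      g <- sample(rep(c("A", "B", "C"), length.out = n))
      while (min(table(g)) < 1 || length(unique(x)) == 1) {
        x <- sample(1:5, n, replace = TRUE)
        g <- sample(rep(c("A", "B", "C"), length.out = n))
      }
      h_pkg <- unname(kruskal.test(x, factor(g))$statistic)
      expect_equal(h_pkg, kw_oracle(x, g), tolerance = 1e-10)
    }
  })
  # and compare_groups reports the same statistic it gates on
  df <- tibble::tibble(v = c(3, 1, 4, 1, 5, 9, 2, 6, 5))
  g <- rep(c("A", "B", "C"), each = 3)
  expect_equal(compare_groups(df, g)$chi_square_kw,
               kw_oracle(df$v, g), tolerance = 1e-10)
})

test_that("constant parameters are flagged instead of tested", {
  df <- tibble::tibble(flat = rep(1, 9), vary = c(1:9))
  g <- rep(c("A", "B", "C"), each = 3)
  out <- compare_groups(df, g)
  expect_true(out$constant[out$parameter == "flat"])
  expect_true(is.na(out$p_value[out$parameter == "flat"]))
  expect_false(out$constant[out$parameter == "vary"])
})

test_that("a label-copy predictor ranks first in classification ReliefF", {
  withr::with_seed(4, {
    y <- rep(c("a", "b"), each = 10)
    X <- tibble::tibble(
      copy = as.numeric(factor(y)) + rnorm(20, 0, 0.01),
      junk1 = rnorm(20), junk2 = rnorm(20), junk3 = rnorm(20)
    )
    rk <- relieff_rank(X, y, k = 5, mode = "classification")
    expect_equal(rk$predictor[1], "copy")
    expect_true(all(diff(rk$weight) <= 0))
  })
})

test_that("ReliefF weights match the exhaustive brute-force oracle to 1e-12", {
  withr::with_seed(5, {
    for (i in 1:5) {
      m <- sample(6:10, 1)
      X <- matrix(rnorm(m * 3), m, 3, dimnames = list(NULL, c("a", "b", "c")))
      y <- sample(rep(c("u", "v"), length.out = m))
      while (min(table(y)) < 2) y <- sample(rep(c("u", "v"), length.out = m))
      k <- sample(2:3, 1)
      rk <- relieff_rank(as.data.frame(X), y, k = k, mode = "classification")
      oracle <- relieff_oracle_cls(X, y, k)
      expect_equal(rk$weight[match(colnames(X), rk$predictor)],
                   unname(oracle), tolerance = 1e-12)
    }
  })
})

test_that("RReliefF weights match the exhaustive regression oracle to 1e-12", {
  withr::with_seed(6, {
    for (i in 1:5) {
      m <- sample(7:10, 1)
      X <- matrix(rnorm(m * 3), m, 3, dimnames = list(NULL, c("a", "b", "c")))
      y <- X[, 1] * 2 + rnorm(m, 0, 0.3)
      k <- sample(3:4, 1)
      rk <- relieff_rank(as.data.frame(X), y, k = k, mode = "regression")
      oracle <- relieff_oracle_reg(X, y, k)
      expect_equal(rk$weight[match(colnames(X), rk$predictor)],
                   unname(oracle), tolerance = 1e-12)
    }
  })
})

test_that("ReliefF weights are bounded and insensitive to duplicated predictors", {
  withr::with_seed(7, {
    X <- tibble::tibble(a = rnorm(16), b = rnorm(16), c = rnorm(16))
    y <- rep(c("g1", "g2"), each = 8)
    rk1 <- relieff_rank(X, y, k = 4, mode = "classification")
    expect_true(all(rk1$weight >= -1 & rk1$weight <= 1))
    # a duplicated column changes distances equally for hits and misses of
    # the copied feature only; existing columns keep their weights when the
    # duplicate does not alter the neighbor sets
    X2 <- X
    X2$a2 <- X$a
    rk2 <- relieff_rank(X2, y, k = 4, mode = "classification")
    expect_equal(rk2$weight[match("a", rk2$predictor)],
                 rk2$weight[match("a2", rk2$predictor)], tolerance = 1e-12)
  })
})

test_that("constant predictors get zero weight and large k is truncated", {
  X <- tibble::tibble(flat = rep(1, 8), sig = c(1:8))
  y <- c(1, 2, 3, 4, 5, 6, 7, 8) + 0.1
  expect_warning(rk <- relieff_rank(X, y, k = 20, mode = "regression"),
                 "truncated")
  expect_equal(rk$weight[rk$predictor == "flat"], 0)
  expect_true(rk$constant[rk$predictor == "flat"])
})

test_that("permuting the response destroys an informative predictor's top rank", {
  withr::with_seed(8, {
    y <- rep(c("a", "b"), each = 8)
    X <- tibble::tibble(
      strong = as.numeric(factor(y)) + rnorm(16, 0, 0.05),
      n1 = rnorm(16), n2 = rnorm(16)
    )
    base <- relieff_rank(X, y, k = 4, mode = "classification")
    expect_equal(base$predictor[1], "strong")
    broken <- vapply(1:40, function(i) {
      rk <- relieff_rank(X, sample(y), k = 4, mode = "classification")
      rk$predictor[1] != "strong"
    }, logical(1))
    expect_gte(mean(broken), 0.5)
  })
})

test_that("predictor pools: clinical variables only for the PD group, 12 rankings", {
  coh <- generate_cohort(n_yc = 5, n_amc = 5, n_pd = 5,
                         profiles = short_profiles(50), seed = 6)
  feat <- suppressWarnings(suppressMessages(extract_cohort_features(coh)))
  rk <- suppressMessages(rank_gait_predictors(feat, k = 4))
  expect_equal(nrow(unique(rk[c("response", "group")])), 12)
  clinical <- c("updrs_iii", "mmse", "ledd_mg", "disease_duration_years",
                "affected_side")
  expect_false(any(rk$predictor[rk$group != "PD"] %in% clinical))
  expect_true(all(clinical %in% rk$predictor[rk$group == "PD"]))
  # the response and its algebraic components are excluded from the pool
  expect_false(any(rk$predictor[rk$response == "PCI"] %in%
                     c("PCI", "phi CV", "phi deviation")))
  expect_false(any(rk$predictor[rk$response == "DST CV"] == "DST CV"))
})

test_that("a planted clinical covariate of DST CV is recovered in most PD cohorts", {
  hits <- vapply(1:20, function(s) {
    coh <- generate_cohort(n_yc = 0, n_amc = 0, n_pd = 11,
                           profiles = short_profiles(120), seed = 100 + s)
    feat <- suppressWarnings(suppressMessages(extract_cohort_features(coh)))
    rk <- suppressMessages(rank_gait_predictors(feat, k = 10,
                                                responses = "DST CV"))
    rk$weight[rk$group == "PD" & rk$predictor == "disease_duration_years"] > 0
  }, logical(1))
  expect_gte(mean(hits), 0.80)
})
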