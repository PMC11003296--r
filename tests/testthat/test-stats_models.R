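# Regression layer against closed-form oracles.

test_that("standardized OLS matches the normal-equations oracle", {
  withr::local_seed(42)
  n <- 40L
  df <- tibble::tibble(
    x1 = stats::rnorm(n), x2 = stats::rnorm(n), x3 = stats::rnorm(n)
  )
  df$y <- 0.8 * df$x1 - 0.5 * df$x2 + stats::rnorm(n, 0, 0.3)
  fit <- ols_standardized(df, "y", c("x1", "x2", "x3"))
  Z <- scale(as.matrix(df[, c("x1", "x2", "x3")]))
  beta_or <- normal_eq_beta(cbind(1, Z), df$y)[-1]
  expect_equal(fit$terms$beta, unname(beta_or), tolerance = 1e-9)
  expect_identical(fit$n, n)
  expect_true(all(fit$vif >= 1))

  # exact slope, no intercept: beta recovers it, r = 1, p ~ 0
  ex <- tibble::tibble(x = 1:10, y = 2 * (1:10))
  f2 <- ols_standardized(ex, "y", "x", intercept = FALSE,
                         standardize = FALSE)
  expect_equal(f2$terms$beta, 2, tolerance = 1e-12)
  expect_equal(f2$terms$r, 1, tolerance = 1e-9)
  expect_lt(f2$terms$p, 1e-12)

  # rank-deficient design errors, naming a collinear column
  df$x4 <- df$x1 + df$x2
  expect_error(ols_standardized(df, "y", c("x1", "x2", "x4")),
               "collinear")
})

test_that("null regressions are calibrated (no spurious significance)", {
  withr::local_seed(7)
  n_sig <- 0
  for (rep in 1:60) {
    df <- tibble::tibble(
      y = stats::rnorm(60), x1 = stats::rnorm(60), x2 = stats::rnorm(60)
    )
    fit <- ols_standardized(df, "y", c("x1", "x2"))
    n_sig <- n_sig + any(fit$terms$p < 0.01)
  }
  expect_lte(n_sig / 60, 0.10) # ~2% expected under the null
})

test_that("partial correlation equals the inverse-correlation-matrix oracle", {
  withr::local_seed(17)
  n <- 60
  Z <- tibble::tibble(z1 = stats::rnorm(n), z2 = stats::rnorm(n))
  x <- 0.6 * Z$z1 + stats::rnorm(n)
  y <- 0.4 * x - 0.5 * Z$z2 + stats::rnorm(n)
  got <- partial_correlation(y, x, Z)
  expect_equal(got$r, pcor_matrix_oracle(y, x, Z), tolerance = 1e-9)
  expect_identical(got$df, n - 2 - 2)
  # empty Z reduces to the Pearson correlation
  got0 <- partial_correlation(y, x, NULL)
  expect_equal(got0$r, stats::cor(y, x), tolerance = 1e-12)
  expect_equal(got0$p, stats::cor.test(y, x)$p.value, tolerance = 1e-9)
  # x in span(Z) is degenerate
  expect_error(partial_correlation(y, Z$z1 * 2, Z), "span")
})

test_that("Welch's t matches the textbook formula and its conventions", {
  withr::local_seed(23)
  a <- stats::rnorm(12, 1, 2)
  b <- stats::rnorm(20, 0, 0.5)
  got <- welch_t(a, b)
  want <- welch_oracle(a, b)
  expect_equal(got$t, want$t, tolerance = 1e-9)
  expect_equal(got$df, want$df, tolerance = 1e-9)
  expect_equal(got$p, want$p, tolerance = 1e-9)
  # identical constant groups
  same <- welch_t(rep(3, 5), rep(3, 7))
  expect_identical(c(same$t, same$p), c(0, 1))
  # equal variances: close to the pooled t
  a2 <- stats::rnorm(30)
  b2 <- stats::rnorm(30, 0.5)
  pooled <- stats::t.test(a2, b2, var.equal = TRUE)
  expect_equal(welch_t(a2, b2)$t, unname(pooled$statistic), tolerance = 0.02)
})

test_that("VIF equals 1/(1 - R^2) with orthogonal and collinear extremes", {
  withr::local_seed(31)
  # orthogonal to each other and to the intercept -> VIF exactly 1
  X <- as.data.frame(qr.Q(qr(cbind(1, matrix(stats::rnorm(120), 40))))[, 2:4])
  names(X) <- c("a", "b", "c")
  expect_equal(unname(vif(X)), rep(1, 3), tolerance = 1e-9)
  X$d <- X$a * 2
  expect_identical(unname(vif(X)[["d"]]), Inf)
  Xc <- tibble::tibble(a = stats::rnorm(50))
  Xc$b <- 0.7 * Xc$a + stats::rnorm(50, 0, 0.5)
  r2 <- summary(lm(b ~ a, data = Xc))$r.squared
  expect_equal(unname(vif(Xc)[["b"]]), 1 / (1 - r2), tolerance = 1e-9)
})

test_that("Bonferroni correction scales, caps and preserves order", {
  got <- bonferroni(c(0.01, 0.5), m = 4)
  expect_equal(got$p_adj, c(0.04, 1))
  expect_identical(got$stars, c("*", ""))
  expect_equal(bonferroni(0.5, m = 10)$p_adj, 1)
  withr::local_seed(2)
  p <- stats::runif(20)
  adj <- bonferroni(p, m = 25)$p_adj
  expect_identical(order(adj[order(p)]), seq_len(20)) # monotone
})

test_that("mixed-effects model with one group or zero between-variance degrades to pooled OLS", {
  withr::local_seed(5)
  df <- tibble::tibble(
    g = "only", x = stats::rnorm(50), y = NA_real_
  )
  df$y <- 1.4 * df$x + stats::rnorm(50)
  pooled <- ols_standardized(df, "y", "x")
  single <- mixed_effects(df, "y", "x", group = "g")
  expect_equal(single$terms$beta, pooled$terms$beta, tolerance = 1e-6)
  expect_identical(single$random, "single_group_pooled")

  # zero between-group variance: singular fit falls back, beta matches
  df$g <- rep(c("a", "b", "c"), length.out = 50)
  suppressWarnings(zr <- mixed_effects(df, "y", "x", group = "g"))
  expect_equal(zr$terms$beta, pooled$terms$beta, tolerance = 0.05)
})

test_that("mixed-effects model recovers a planted fixed effect with group intercepts", {
  withr::local_seed(8)
  g <- rep(c("p1", "p2", "p3"), each = 60)
  b_g <- c(p1 = -2, p2 = 0.5, p3 = 1.5)
  x <- stats::rnorm(180)
  y <- 0.7 * x + b_g[g] + stats::rnorm(180, 0, 0.5)
  df <- tibble::tibble(y = y, x = x, g = g)
  fit <- mixed_effects(df, "y", "x", group = "g", standardize = FALSE)
  expect_equal(fit$terms$beta, 0.7, tolerance = 0.1)
  expect_lt(fit$terms$p, 1e-6)
  expect_match(fit$random, "1\\|g")
})

test_that("model comparison obeys penalty arithmetic and response-scale invariance", {
  withr::local_seed(12)
  n <- 80
  df <- tibble::tibble(
    x = stats::rnorm(n), noise = stats::rnorm(n)
  )
  df$y <- 1.2 * df$x + stats::rnorm(n)
  same <- compare_models(df, "y", "x", "x")
  expect_equal(same$delta_aic, 0)
  expect_identical(same$preferred, "none")
  expect_identical(unname(same$verdict["aic"]), "no preference")

  # adding a pure-noise predictor can improve AIC by at most 2
  cmp <- compare_models(df, "y", predictors_a = c("x", "noise"),
                        predictors_b = "x")
  expect_gte(cmp$delta_aic, -2 - 1e-9)
  expect_gte(cmp$delta_bic, cmp$delta_aic) # BIC penalizes more at n > 7

  # affine response transforms leave the deltas unchanged
  df2 <- df
  df2$y <- 3 * df$y + 10
  cmp2 <- compare_models(df2, "y", predictors_a = c("x", "noise"),
                         predictors_b = "x")
  expect_equal(cmp2$delta_aic, cmp$delta_aic, tolerance = 1e-9)
  expect_equal(cmp2$delta_bic, cmp$delta_bic, tolerance = 1e-9)
})

test_that("summation regression recovers exact and planted gains", {
  mk_points <- function(vals, electrodes, participant = "P1",
                        amplitude = 2) {
    tibble::tibble(
      participant = participant, electrodes = electrodes,
      amplitude_x_th = amplitude, frequency_hz = 20,
      area = vals, perimeter = vals, major = vals, minor = vals,
      n_phosphenes_mean = 1, n_trials = 3
    )
  }
  withr::local_seed(14)
  n <- 100L
  e1 <- sprintf("A%d", rep(1:10, 10))
  # build unique synthetic electrode pairs via two pseudo-grids
  singles <- mk_points(stats::runif(20, 50, 150),
                       c(sprintf("B%d", 1:10), sprintf("C%d", 1:10)))
  pair_keys <- t(utils::combn(singles$electrodes, 2))[1:n, ]
  sums <- singles$area[match(pair_keys[, 1], singles$electrodes)] +
    singles$area[match(pair_keys[, 2], singles$electrodes)]
  paired_exact <- mk_points(sums, paste(pmin(pair_keys[, 1], pair_keys[, 2]),
                                        pmax(pair_keys[, 1], pair_keys[, 2]),
                                        sep = "+"))
  res <- summation_regression(paired_exact, singles)
  expect_equal(res$fits$beta, rep(1, 4), tolerance = 1e-9)
  expect_equal(res$fits$r, rep(1, 4), tolerance = 1e-9)

  half <- paired_exact
  for (d in c("area", "perimeter", "major", "minor")) {
    half[[d]] <- 0.5 * half[[d]]
  }
  expect_equal(summation_regression(half, singles)$fits$beta,
               rep(0.5, 4), tolerance = 1e-9)

  noisy <- paired_exact
  for (d in c("area", "perimeter", "major", "minor")) {
    noisy[[d]] <- 0.65 * sums + stats::rnorm(n, 0, 0.05 * mean(sums))
  }
  got <- summation_regression(noisy, singles)$fits$beta
  expect_true(all(got > 0.60 & got < 0.70))

  # unmatched pairs are logged, not fatal
  orphan <- dplyr::bind_rows(paired_exact,
                             mk_points(100, "Z1+Z2"))
  res2 <- summation_regression(orphan, singles)
  expect_identical(res2$unmatched, "Z1+Z2")
  expect_identical(res2$fits$n, rep(n, 4L))
})

test_that("tidy_fit assembles report rows with stars", {
  withr::local_seed(44)
  df <- tibble::tibble(x1 = stats::rnorm(50), x2 = stats::rnorm(50))
  df$y <- 2 * df$x1 + stats::rnorm(50, 0, 0.2)
  fit <- ols_standardized(df, "y", c("x1", "x2"))
  td <- tidy_fit(fit, m = 8)
  expect_identical(nrow(td), 2L)
  expect_identical(td$stars[td$term == "x1"], "***")
  expect_true(all(td$p_adj >= td$p))
})
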