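# Logarithmic curve fitting (Levenberg-Marquardt, robust option), paired
# comparisons, Cohen's d and Spearman correlation.

test_that("noiseless data is recovered exactly and flat data fits a zero slope", {
  y <- 10.94 * log(1:14) + 91.62
  fit <- fit_log_curve(1:14, y)
  expect_true(fit$converged)
  expect_equal(fit$a_hat, 10.94, tolerance = 1e-6)
  expect_equal(fit$b_hat, 91.62, tolerance = 1e-6)
  expect_lt(fit$rmse, 1e-6)

  flat <- fit_log_curve(1:10, rep(42, 10))
  expect_equal(flat$a_hat, 0, tolerance = 1e-8)
  expect_equal(flat$b_hat, 42, tolerance = 1e-8)
  expect_equal(flat$rmse, 0, tolerance = 1e-8)
})

test_that("the LM solution matches linear-least-squares and nlsLM oracles", {
  # the model is linear in (a, b): lm(y ~ log(x)) is an exact closed-form
  # oracle, and minpack.lm is an independent LM implementation
  for (s in 1:5) {
    d <- generate_behavior_dataset(10.94, 91.62, noise_sd = 5, seed = s)
    fit <- fit_log_curve(d$data$day, d$data$score)
    ols <- lm(score ~ log(day), data = d$data)
    expect_equal(fit$a_hat, unname(coef(ols)[2]), tolerance = 1e-8)
    expect_equal(fit$b_hat, unname(coef(ols)[1]), tolerance = 1e-8)
    expect_equal(fit$rmse, summary(ols)$sigma, tolerance = 1e-8)
    # CI agreement with the standard parametric intervals
    ci <- confint(ols)
    expect_equal(fit$ci_a, unname(ci[2, ]), tolerance = 1e-6)
    expect_equal(fit$ci_b, unname(ci[1, ]), tolerance = 1e-6)

    nls_fit <- minpack.lm::nlsLM(
      score ~ a * log(day) + b, data = d$data,
      start = list(a = 1, b = mean(d$data$score)))
    expect_equal(fit$a_hat, unname(coef(nls_fit)["a"]), tolerance = 1e-6)
  }
})

test_that("the LM solution beats a 201x201 grid search on every seeded fixture", {
  for (s in 1:5) {
    d <- generate_behavior_dataset(10.94, 91.62, noise_sd = 5, seed = 100 + s)
    x <- d$data$day; y <- d$data$score
    fit <- fit_log_curve(x, y)
    sse <- function(a, b) sum((y - a * log(x) - b)^2)
    a_grid <- seq(0.5 * 10.94, 1.5 * 10.94, length.out = 201)
    b_grid <- seq(0.5 * 91.62, 1.5 * 91.62, length.out = 201)
    grid_min <- min(outer(a_grid, b_grid, Vectorize(sse)))
    expect_lte(sse(fit$a_hat, fit$b_hat), grid_min + 1e-9, label = s)
  }
})

test_that("the fit is invariant to permutation of the observations", {
  d <- generate_behavior_dataset(8, 95, noise_sd = 4, seed = 11)
  perm <- sample(14)
  f1 <- fit_log_curve(d$data$day, d$data$score)
  f2 <- fit_log_curve(d$data$day[perm], d$data$score[perm])
  expect_equal(f1$a_hat, f2$a_hat, tolerance = 1e-9)
  expect_equal(f1$b_hat, f2$b_hat, tolerance = 1e-9)
})

test_that("input validation: short series and bad day indices are rejected", {
  expect_error(fit_log_curve(1:2, c(1, 2)),
               class = "hwnav_insufficient_data")
  expect_error(fit_log_curve(c(1, 1, 1), c(1, 2, 3)),
               class = "hwnav_insufficient_data")
  expect_error(fit_log_curve(c(0.5, 1, 2), c(1, 2, 3)), ">= 1")
})

test_that("robust fitting resists a gross outlier and agrees otherwise", {
  # on clean fixtures, the robust and plain fits essentially coincide
  for (s in c(20, 23, 24)) {
    dc <- generate_behavior_dataset(10.94, 91.62, noise_sd = 1, seed = s)
    pc <- fit_log_curve(dc$data$day, dc$data$score)
    rc <- fit_log_curve(dc$data$day, dc$data$score, robust = TRUE)
    expect_lt(abs(rc$a_hat - pc$a_hat) / abs(pc$a_hat), 0.005, label = s)
    expect_lt(abs(rc$b_hat - pc$b_hat) / abs(pc$b_hat), 0.005, label = s)
  }

  d <- generate_behavior_dataset(10.94, 91.62, noise_sd = 3, seed = 21)
  x <- d$data$day; y <- d$data$score
  plain <- fit_log_curve(x, y)

  y_out <- y
  y_out[3] <- y_out[3] + 80  # gross outlier
  plain_o <- fit_log_curve(x, y_out)
  rob_o <- fit_log_curve(x, y_out, robust = TRUE)
  # the robust slope moves less from the clean-data fit than the plain one
  expect_lt(abs(rob_o$a_hat - plain$a_hat), abs(plain_o$a_hat - plain$a_hat))
  # the outlier is heavily down-weighted
  expect_lt(rob_o$weights[3], 0.2)
  # MASS::rlm on the linearized model is an independent robust oracle
  rlm_fit <- MASS::rlm(y_out ~ log(x), psi = MASS::psi.bisquare)
  expect_equal(rob_o$a_hat, unname(coef(rlm_fit)[2]), tolerance = 0.01)
})

test_that("paired t test: identity null, degenerate shift, and type-I control", {
  x <- c(5, 7, 9, 4, 8)
  same <- paired_ttest(x, x)
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$cohens_d, 0)
  expect_false(same$degenerate)

  shift <- paired_ttest(x, x + 2)
  expect_true(shift$degenerate)
  expect_true(is.na(shift$p_value))

  expect_error(paired_ttest(1:4, 1:5), class = "hwnav_pairing_error")

  # under H0, rejection rate at alpha = .05 is ~.05
  set.seed(14)
  n_rep <- 5000
  rej <- vapply(seq_len(n_rep), function(i) {
    pre <- rnorm(10); post <- rnorm(10)
    paired_ttest(pre, post)$p_value < 0.05
  }, logical(1))
  mc_err <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(mean(rej) - 0.05), 4 * mc_err)
})

test_that("cross-check of the paired t against stats::t.test", {
  set.seed(8)
  pre <- rnorm(17, 96.4, 11.7); post <- rnorm(17, 122.7, 13.3)
  ours <- paired_ttest(pre, post)
  ref <- t.test(post, pre, paired = TRUE)
  expect_equal(ours$t_stat, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value)
})

test_that("Cohen's d: definition, large-sample value, scale invariance", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(cohens_d(x, x), 0)
  set.seed(3)
  pre <- rnorm(10000, 0, 1); post <- rnorm(10000, 0.8, 1)
  expect_equal(cohens_d(pre, post, "pooled"), 0.8, tolerance = 0.05)
  expect_equal(cohens_d(pre, post, "pooled"),
               cohens_d(10 * pre, 10 * post, "pooled"), tolerance = 1e-12)
  # paired variant uses the difference SD
  d_paired <- cohens_d(pre, post, "paired")
  expect_equal(d_paired, mean(post - pre) / sd(post - pre), tolerance = 1e-12)
  expect_warning(dd <- cohens_d(rep(1, 4), rep(1, 4)), "zero-variance")
  expect_true(is.na(dd))
})

test_that("Spearman correlation: exact ranks, ties, and the t-approximate p", {
  expect_equal(spearman(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman(1:10, -(1:10))$rho, -1)
  expect_equal(spearman(1:10, (1:10)^3)$p_value, 0)

  # ties: definitional average-rank Pearson computation
  x <- c(1, 2, 2, 3, 5, 5, 5, 8)
  y <- c(2, 1, 4, 4, 6, 7, 7, 9)
  s <- spearman(x, y)
  expect_equal(s$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(s$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(s$p_value, ref$p.value, tolerance = 1e-9)

  const <- spearman(rep(1, 5), 1:5)
  expect_true(const$degenerate)
  expect_true(is.na(const$rho))
})
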