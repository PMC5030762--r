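test_that("sum_rank_pmf matches exhaustive enumeration at tiny N, k", {
  p22 <- sum_rank_pmf(2, 2)
  expect_identical(p22$support, 2:4)
  expect_equal(p22$pmf, c(1, 2, 1) / 4)

  p23 <- sum_rank_pmf(2, 3)
  expect_identical(p23$support, 3:6)
  expect_equal(p23$pmf, c(1, 3, 3, 1) / 8)

  p61 <- sum_rank_pmf(6, 1)
  expect_equal(p61$pmf, rep(1 / 6, 6))
})

test_that("sum_rank_pmf has mean k(N+1)/2 and variance k(N^2-1)/12", {
  for (cfg in list(c(4, 3), c(7, 2), c(16, 5), c(10, 8))) {
    N <- cfg[1]; k <- cfg[2]
    p <- sum_rank_pmf(N, k)
    mu <- sum(p$support * p$pmf)
    v <- sum((p$support - mu)^2 * p$pmf)
    expect_equal(mu, k * (N + 1) / 2)
    expect_equal(v, k * (N^2 - 1) / 12)
    expect_equal(sum(p$pmf), 1, tolerance = 1e-12)
  }
})

test_that("diff_distribution is the centered self-convolution", {
  d <- diff_distribution(2, 2)
  expect_identical(d$support, -2:2)
  expect_equal(d$pmf, c(1, 4, 6, 4, 1) / 16)

  # symmetry, normalisation and closed-form variance
  for (cfg in list(c(16, 5), c(5, 3), c(9, 2))) {
    N <- cfg[1]; k <- cfg[2]
    dd <- diff_distribution(N, k)
    expect_equal(sum(dd$pmf), 1, tolerance = 1e-12)
    expect_equal(dd$pmf, rev(dd$pmf), tolerance = 1e-12)
    expect_identical(dd$support, seq.int(-k * (N - 1), k * (N - 1)))
    expect_equal(sum(dd$pmf * dd$support^2), 2 * k * (N^2 - 1) / 12)
  }

  # k_plus_1 convention widens the support by one convolution step
  d6 <- diff_distribution(16, 5, convention = "k_plus_1")
  expect_identical(d6$support, seq.int(-6 * 15, 6 * 15))
  expect_equal(sum(d6$pmf * d6$support^2), 2 * 6 * (16^2 - 1) / 12)
})

test_that("diff_distribution equals brute-force enumeration on small geometries", {
  for (cfg in list(c(2, 2), c(2, 4), c(3, 3), c(4, 2), c(6, 1))) {
    N <- cfg[1]; k <- cfg[2]
    oracle <- enumerate_diff_pmf(N, k)
    dd <- diff_distribution(N, k)
    expect_identical(dd$support, oracle$support)
    expect_lt(max(abs(dd$pmf - oracle$pmf)), 1e-12)
  }
})

test_that("exact_threshold picks the largest point with tail mass <= alpha", {
  # N=2, k=2: even the extreme point has mass 1/16 > 0.05 -> below support
  expect_warning(th <- exact_threshold(2, 2, 0.05), "detection impossible")
  expect_identical(th, -3L)

  # N=2, k=3: tail at -3 is 1/64 <= 0.05, at -2 it is 7/64
  expect_identical(exact_threshold(2, 3, 0.05), -3L)

  expect_identical(exact_threshold(16, 5, 0.05), -25L)
  expect_identical(exact_threshold(16, 5, 0.05, convention = "k_plus_1"), -27L)

  # whole distribution qualifies at alpha = 1
  expect_identical(exact_threshold(4, 2, 1), 2L * 3L)

  expect_error(exact_threshold(16, 5, 0), "alpha")
  expect_error(exact_threshold(16, 5, 1.5), "alpha")
})

test_that("exact_threshold is monotone in alpha, N and k, with tail mass <= alpha", {
  th_a <- sapply(c(0.01, 0.05, 0.1, 0.3), function(a) exact_threshold(12, 4, a))
  expect_true(all(diff(th_a) >= 0))
  th_N <- sapply(c(4, 8, 16, 32), function(N) exact_threshold(N, 5, 0.05))
  expect_true(all(diff(th_N) <= 0))
  th_k <- sapply(3:8, function(k) exact_threshold(16, k, 0.05))
  expect_true(all(diff(th_k) <= 0))

  for (cfg in list(c(8, 3), c(16, 5), c(20, 6))) {
    N <- cfg[1]; k <- cfg[2]
    dd <- diff_distribution(N, k)
    th <- exact_threshold(N, k, 0.05)
    expect_lte(sum(dd$pmf[dd$support <= th]), 0.05 + 1e-12)
  }
})

test_that("rule-of-thumb threshold reproduces the printed closed form", {
  expect_equal(rule_of_thumb_threshold(16, 5), -14.6294)
  expect_equal(rule_of_thumb_threshold(4, 2), -3.32588)
  th_k <- sapply(2:10, function(k) rule_of_thumb_threshold(16, k))
  expect_true(all(diff(th_k) < 0))
})

test_that("fit_rule_of_thumb returns a coherent least-squares summary", {
  fit <- fit_rule_of_thumb(k_range = 2:5, N_range = c(4, 8, 16), alpha = 0.05)
  expect_s3_class(fit, "threshold_fit")
  expect_true(is.finite(fit$intercept) && is.finite(fit$coefficient))
  expect_lt(fit$coefficient, 0)
  expect_equal(fit$grid$theta, fit$grid$fitted + fit$grid$residual)
  expect_equal(sum(fit$grid$residual), 0, tolerance = 1e-8)
  expect_equal(unname(coef(fit)), c(fit$intercept, fit$coefficient))
  expect_error(fit_rule_of_thumb(k_range = 2, N_range = 4), "degenerate grid")

  # the alternative predictor N * sqrt(k) tracks the exact thresholds closely
  fit2 <- fit_rule_of_thumb(k_range = 2:5, N_range = c(4, 8, 16),
                            predictor = "N_sqrtk")
  expect_gt(fit2$r_squared, 0.995)
})
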