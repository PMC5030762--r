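test_that("noiseless planted blocks with well-separated chunks are recovered exactly", {
  # two 2-item chunks at heads 3 and 9: ties resolve deterministically
  sim <- noiseless_block("few_short", heads = c(3, 9))
  fit <- detect_chunks(sim$block)
  expect_identical(fit$chunks$head, c(3L, 9L))
  expect_identical(fit$chunks$length, c(2L, 2L))
  expect_identical(fit$bodies, list(4L, 10L))

  # two 4-item chunks: body extension runs to the planted length and stops
  sim4 <- noiseless_block("few_long", heads = c(3, 9))
  fit4 <- detect_chunks(sim4$block)
  expect_identical(fit4$chunks$head, c(3L, 9L))
  expect_identical(fit4$chunks$length, c(4L, 4L))
})

test_that("a constant block yields zero chunks", {
  fit <- detect_chunks(constant_block(rep(500, 16), k = 5))
  expect_identical(fit$n_chunks, 0L)
  expect_identical(nrow(fit$chunks), 0L)
  # tie rule makes every difference exactly -k, far above the threshold
  expect_true(all(fit$ranks$diffs == -5))
})

test_that("detection is invariant under strictly increasing transforms of the RTs", {
  set.seed(33)
  for (i in 1:10) {
    sim <- generate_block(condition = "many_short", noise = noise_spec(0.1, 5))
    f1 <- detect_chunks(sim$block)
    f2 <- detect_chunks(unclass(sim$block)^3)
    f3 <- detect_chunks(exp(unclass(sim$block) / 300))
    expect_identical(f1$chunks, f2$chunks)
    expect_identical(f1$chunks, f3$chunks)
  }
})

test_that("slowing one item only creates heads near that position", {
  # shifting one item's rank to the top moves every other rank by at most 1,
  # so rank-sum differences move by at most 2k = 10; baselines with any
  # difference that close to theta are skipped as genuinely ambiguous
  set.seed(44)
  tested <- 0L
  for (i in 1:120) {
    m <- matrix(rnorm(80, 760, 25), 5, 16)
    f0 <- detect_chunks(m)
    if (any(abs(f0$ranks$diffs[-c(6, 7)] - f0$theta) <= 10)) next
    tested <- tested + 1L
    m2 <- m
    m2[, 7] <- m2[, 7] + 1000
    f1 <- detect_chunks(m2)
    expect_true(all(setdiff(f1$chunks$head, f0$chunks$head) %in% c(6L, 7L)))
    # item 7 is a head whenever its successor's rank sum is low enough
    if (f1$ranks$summed_ranks[8] - f1$ranks$summed_ranks[7] <= f1$theta)
      expect_true(7L %in% f1$chunks$head)
  }
  expect_gt(tested, 10)
})

test_that("under the uniform-rank null the flagged fraction respects alpha", {
  # 2e4 blocks x 15 comparisons; the k-convention threshold is calibrated
  # against exactly this null, so the fraction cannot exceed alpha
  rate <- null_head_rate(16, 5, alpha = 0.05, blocks = 2e4,
                         convention = "k", seed = 9)
  expect_lte(rate, 0.05)
  expect_gt(rate, 0.02)  # and it is not vacuously conservative
})

test_that("chunks are disjoint, ordered, and never wrap", {
  set.seed(55)
  for (i in 1:30) {
    sim <- suppressWarnings(
      generate_block(condition = "many_long", noise = noise_spec(0.3, 5)))
    fit <- detect_chunks(sim$block)
    if (fit$n_chunks == 0L) next
    pos <- mapply(function(h, l) seq.int(h, h + l - 1L),
                  fit$chunks$head, fit$chunks$length, SIMPLIFY = FALSE)
    all_pos <- unlist(pos)
    expect_true(!anyDuplicated(all_pos))
    expect_true(all(all_pos >= 1L & all_pos <= 16L))
    expect_true(!is.unsorted(fit$chunks$head, strictly = TRUE))
    expect_true(all(fit$chunks$length >= 2L))
  }
})

test_that("detector validates inputs and honours the threshold mode", {
  b <- constant_block(rep(500, 16), k = 5)
  expect_error(detect_chunks(b, alpha = 0), "alpha")
  expect_error(detect_chunks(b, alpha = 1), "alpha")
  expect_error(detect_chunks(matrix(1:3, 1, 3)), "unsupported geometry")

  sim <- noiseless_block("few_short", heads = c(3, 9))
  f_rot <- detect_chunks(sim$block, theta_mode = "rule_of_thumb")
  expect_equal(f_rot$theta, rule_of_thumb_threshold(16, 5))
  expect_identical(f_rot$chunks$head, c(3L, 9L))

  # imputation runs automatically before ranking
  m <- unclass(sim$block)
  m[2, 5] <- NA
  expect_identical(detect_chunks(m)$chunks, detect_chunks(sim$block)$chunks)
})
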