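test_that("centered rank reproduces worked examples and tie handling", {
  expect_equal(centered_rank(c(3, 1, 2))$transformed,
               c(1 / 6, -1 / 2, -1 / 6))
  expect_equal(centered_rank(c(5, 5, 5))$transformed, rep(-0.5, 3))
  expect_equal(centered_rank(7)$transformed, -0.5)
  expect_error(centered_rank(numeric(0)), "empty")
})

test_that("centered rank depends only on the reward ordering", {
  set.seed(4)
  for (n in c(2, 5, 17)) {
    r <- stats::rnorm(n)
    ranked <- centered_rank(r)$transformed
    # invariance under a strictly monotone transform
    expect_identical(ranked, centered_rank(exp(r))$transformed)
    # permutation equivariance
    perm <- sample.int(n)
    expect_identical(centered_rank(r[perm])$transformed, ranked[perm])
    # distinct inputs: exact mean, min and max forced by the rank sums
    expect_equal(mean(ranked), -1 / (2 * n))
    expect_equal(min(ranked), -0.5)
    expect_equal(max(ranked), (n - 1) / n - 0.5)
  }
  # permuting tied entries leaves the multiset of outputs unchanged
  tied <- c(1, 2, 2, 3)
  expect_equal(sort(centered_rank(tied)$transformed),
               sort(centered_rank(rev(tied))$transformed))
})

test_that("zero-mean baseline subtracts the history mean, not the batch mean", {
  st <- reward_transform_state("zero_mean")
  out1 <- zero_mean_transform(c(1, 2, 3), st)
  expect_equal(out1$rewards$transformed, c(1, 2, 3))  # empty history
  out2 <- zero_mean_transform(c(4, 4), out1$state)
  expect_equal(out2$rewards$transformed, c(2, 2))     # history mean = 2
  expect_equal(out2$state$history_count, 5L)

  # a constant reward stream is driven to zero from the second batch on
  st2 <- reward_transform_state("zero_mean")
  for (i in 1:4) {
    out <- zero_mean_transform(rep(3, 8), st2)
    st2 <- out$state
  }
  expect_equal(out$rewards$transformed, rep(0, 8))

  # optional within-batch centering for the first batch
  stb <- reward_transform_state("zero_mean", subtract_batch_mean = TRUE)
  outb <- zero_mean_transform(c(1, 2, 3), stb)
  expect_equal(outb$rewards$transformed, c(-1, 0, 1))
})

test_that("reward transform dispatch covers all three kinds", {
  r <- c(2, 1, 3)
  crt <- apply_reward_transform(r, reward_transform_state("centered_rank"))
  expect_equal(crt$rewards$transformed, c(-1 / 6, -1 / 2, 1 / 6))
  idn <- apply_reward_transform(r, reward_transform_state("identity"))
  expect_equal(idn$rewards$transformed, r)
})

test_that("accuracy reward counts label matches", {
  expect_equal(accuracy_reward(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(accuracy_reward(c(1, 2), c(3, 4)), 0)
  expect_equal(accuracy_reward(c(1, 2, 3, 4), c(1, 2, 3, 9)), 0.75)
  expect_error(accuracy_reward(1:3, 1:4), "length")
})

test_that("soft recall averages reciprocal ranks of the true class", {
  s <- matrix(c(3, 1, 2,
                1, 3, 2), 2, byrow = TRUE)
  expect_equal(soft_recall_reward(s, c(0, 1)), 1)        # both top-ranked
  s2 <- matrix(c(3, 2, 1,
                 2, 3, 1), 2, byrow = TRUE)
  expect_equal(soft_recall_reward(s2, c(0, 0)), (1 + 1 / 2) / 2)
  s10 <- matrix(10:1, 1)
  expect_equal(soft_recall_reward(s10, 9), 0.1)          # last of 10
  # score ties broken by the smaller class index after stable sort
  expect_equal(soft_recall_reward(matrix(c(1, 1, 0), 1), 1), 1 / 2)
  expect_error(soft_recall_reward(s, c(0, 5)), "labels")
})

test_that("cross-entropy reward matches softmax arithmetic", {
  expect_equal(cross_entropy_reward(matrix(0, 1, 4), 0), -log(4))
  expect_equal(cross_entropy_reward(matrix(c(1, 0), 1), 0),
               log(exp(1) / (exp(1) + 1)), tolerance = 1e-9)
  # shifting all scores leaves the reward unchanged (stable softmax)
  s <- matrix(c(2, -1, 0.5), 1)
  expect_equal(cross_entropy_reward(s, 1), cross_entropy_reward(s + 1000, 1))
})

test_that("all classification rewards prefer a better-ranked true class", {
  worse <- matrix(c(0, 1, 2), 1)
  better <- matrix(c(2.5, 1, 2), 1)
  for (kind in c("soft_recall", "accuracy", "cross_entropy")) {
    expect_gt(classification_reward(better, 0, kind),
              classification_reward(worse, 0, kind))
  }
  # top-k accuracy: credit for a near miss when k = 2
  expect_equal(classification_reward(worse, 1, "accuracy", k = 1), 0)
  expect_equal(classification_reward(worse, 1, "accuracy", k = 2), 1)
})
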