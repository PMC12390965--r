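test_that("release probability constructor enforces the admissible domain", {
  p <- release_probs(c(2, 3), init = 0.5, clip_eps = 0.001)
  expect_identical(dim(p), c(2L, 3L))
  expect_true(all(p == 0.5))
  expect_error(release_probs(c(1, 1), init = 0.9995, clip_eps = 0.001),
               "clip_eps")
  expect_error(release_probs(c(0, 3)), "shape")
  expect_error(release_probs(c(2, 2), clip_eps = 0.7), "clip_eps")

  big <- release_probs(c(64, 1568))
  expect_identical(length(big), 64L * 1568L)
  expect_true(all(big == 0.5))

  j1 <- release_probs(c(5, 5), jitter = 0.45, seed = 7)
  j2 <- release_probs(c(5, 5), jitter = 0.45, seed = 7)
  expect_identical(unclass(j1), unclass(j2))
  expect_true(all(j1 >= 0.001 & j1 <= 0.999))
  expect_gt(stats::sd(j1), 0)
})

test_that("release sampling is Bernoulli with a reproducible stream", {
  p <- release_probs(c(1, 2), clip_eps = 0.001)
  p[] <- c(0.999, 0.5)
  s1 <- sample_release(p, 5, seed = 42)
  s2 <- sample_release(p, 5, seed = 42)
  expect_identical(s1, s2)
  expect_true(all(vapply(s1, function(s) all(s %in% c(0, 1)), logical(1))))

  n <- 1e5
  draws <- sample_release(p, n, seed = 1)
  bits <- matrix(unlist(draws), nrow = 2)
  # binomial standard errors at the two probabilities
  expect_lt(abs(mean(bits[1, ]) - 0.999), 3 * sqrt(0.001 * 0.999 / n))
  expect_true(mean(bits[2, ]) > 0.4953 && mean(bits[2, ]) < 0.5047)
})

test_that("plasticity update reproduces hand-computed reward-modulated steps", {
  p <- release_probs(c(1, 1))
  expect_equal(as.numeric(rsrp_update(p, list(matrix(1, 1, 1)), 1, 0.1)),
               0.55)

  p8 <- release_probs(c(1, 1))
  p8[] <- 0.8
  up <- rsrp_update(p8, list(matrix(1, 1, 1), matrix(0, 1, 1)), c(2, -1), 0.1)
  expect_equal(as.numeric(up), 0.86)

  # a step beyond the admissible domain is projected back to 1 - eps
  p999 <- release_probs(c(1, 1))
  p999[] <- 0.999
  clipped <- rsrp_update(p999, list(matrix(1, 1, 1)), 1, 0.5)
  expect_equal(as.numeric(clipped), 0.999)

  # zero reward and zero learning rate are both exact null updates
  samples <- sample_release(p8, 4, seed = 1)
  expect_equal(as.numeric(rsrp_update(p8, samples, rep(0, 4))), rep(0.8, 1))
  expect_equal(as.numeric(rsrp_update(p8, samples, stats::rnorm(4), 0)), 0.8)

  # pure function: the input matrix is untouched
  before <- as.numeric(p8)
  invisible(rsrp_update(p8, samples, rep(1, 4)))
  expect_identical(as.numeric(p8), before)

  expect_error(rsrp_update(p8, samples, c(1, 2)), "must equal")
})

test_that("score-function gradient and Fisher diagonal match closed forms", {
  p <- release_probs(c(1, 1))
  g <- score_function_gradient(p, list(matrix(1, 1, 1)), 1)
  expect_equal(as.numeric(g), 2)

  expect_equal(as.numeric(fisher_diagonal(p)), 4)
  p2 <- release_probs(c(1, 1))
  p2[] <- 0.001
  expect_equal(as.numeric(fisher_diagonal(p2)), 1 / (0.001 * 0.999))
  expect_error(fisher_diagonal(matrix(c(0, 0.5), 1)), "diverges")
})

test_that("Fisher-preconditioned score equals the plasticity update direction", {
  set.seed(31)
  for (rep in 1:10) {
    p <- release_probs(c(3, 4))
    p[] <- stats::runif(12, 0.2, 0.8)
    n <- 7
    samples <- sample_release(p, n, seed = rep)
    rewards <- stats::rnorm(n)
    eta <- 1e-3  # small enough that clipping never engages
    direct <- as.numeric(rsrp_update(p, samples, rewards, eta)) -
      as.numeric(p)
    via_fisher <- eta * as.numeric(score_function_gradient(p, samples,
                                                           rewards)) /
      as.numeric(fisher_diagonal(p))
    expect_equal(direct, via_fisher, tolerance = 1e-12)
  }
})

test_that("Monte-Carlo gradient is unbiased against exhaustive enumeration", {
  k <- 5
  table <- with(list(), {set.seed(17); stats::runif(2^k, -1, 2)})
  fr <- tabular_reward(table)
  p <- release_probs(c(1, k))
  p[] <- c(0.3, 0.5, 0.7, 0.25, 0.6)
  exact <- enumerate_reward(as.numeric(p), fr)

  n <- 4e4
  samples <- sample_release(p, n, seed = 5)
  rewards <- vapply(samples, function(s) tabular_reward_value(fr, s),
                    numeric(1))
  mc <- as.numeric(score_function_gradient(p, samples, rewards))

  # per-coordinate empirical standard error of the estimator
  theta <- matrix(unlist(samples), nrow = k)
  rho <- as.numeric(p)
  per_draw <- (theta - rho) / (rho * (1 - rho)) *
    matrix(rewards, k, n, byrow = TRUE)
  se <- apply(per_draw, 1, stats::sd) / sqrt(n)
  expect_true(all(abs(mc - exact$grad) <= 3 * se))

  # constant rewards: zero gradient in expectation
  mc0 <- as.numeric(score_function_gradient(p, samples, rep(1.7, n)))
  per0 <- (theta - rho) / (rho * (1 - rho)) * 1.7
  se0 <- apply(per0, 1, stats::sd) / sqrt(n)
  expect_true(all(abs(mc0) <= 3 * se0))
})

test_that("constant rewards give zero expected drift of the probabilities", {
  p <- release_probs(c(1, 1))
  p[] <- 0.3
  n_rep <- 1e4
  draws <- sample_release(p, n_rep, seed = 9)
  deltas <- vapply(draws, function(s) {
    as.numeric(rsrp_update(p, list(s), 2, 0.1)) - 0.3
  }, numeric(1))
  se <- stats::sd(deltas) / sqrt(n_rep)
  expect_lt(abs(mean(deltas)), 3 * se)
})

test_that("Bernoulli entropy matches its closed form and is additive", {
  p <- release_probs(c(1, 1))
  expect_equal(bernoulli_entropy(p)$total, log(2), tolerance = 1e-12)

  p2 <- release_probs(c(1, 1))
  p2[] <- 0.001
  # -0.001 log 0.001 - 0.999 log 0.999, evaluated by hand
  expect_equal(bernoulli_entropy(p2)$total, 0.007907255, tolerance = 1e-6)

  p10 <- release_probs(c(2, 5))
  ent <- bernoulli_entropy(p10)
  expect_equal(ent$total, 10 * log(2), tolerance = 1e-12)
  expect_identical(dim(ent$per_synapse), c(2L, 5L))
})

test_that("hedonistic baseline updates the pre-sigmoid parameter", {
  h <- hedonistic_params(matrix(0, 1, 1))
  expect_equal(as.numeric(h$p), 0.5)
  up <- hedonistic_update(h, list(matrix(1, 1, 1)), 1, 0.1)
  expect_equal(as.numeric(up$q), 0.05)
  expect_equal(as.numeric(up$p), stats::plogis(0.05))

  h2 <- hedonistic_params(matrix(2, 1, 1))
  up2 <- hedonistic_update(h2, list(matrix(0, 1, 1)), 1, 1)
  expect_equal(as.numeric(up2$q - h2$q), -stats::plogis(2), tolerance = 1e-9)

  samples <- sample_release(release_probs(c(1, 1)), 3, seed = 2)
  same <- hedonistic_update(h2, samples, rep(0, 3))
  expect_identical(same$q, h2$q)
})

test_that("a single always-rewarded synapse is driven to the upper clip bound", {
  # reward R(theta) = theta, raw rewards; expected drift eta * rho * (1-rho)
  fr <- tabular_reward(c(0, 1))
  reached <- vapply(1:10, function(s) {
    cfg <- train_config("bandit", n_samples = 256, learning_rate = 0.05,
                        iterations = 200, seed = s,
                        reward_transform = "identity")
    fit <- train_bandit(fr, cfg)
    as.numeric(fit$probs)
  }, numeric(1))
  expect_gte(sum(reached == 0.999), 9)
})
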