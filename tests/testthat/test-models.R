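test_that("balanced input concatenates the negated copy and sums to zero", {
  expect_equal(balanced_input(c(1, -2)), c(1, -2, -1, 2))
  expect_equal(balanced_input(rep(0, 3)), rep(0, 6))
  set.seed(2)
  x <- stats::rnorm(7)
  expect_equal(sum(balanced_input(x)), 0)
  m <- matrix(stats::rnorm(6), 3)
  expect_equal(colSums(balanced_input(m)), rep(0, 2))
})

test_that("EI layer forward pass flips the inhibitory half and stays Dale-consistent", {
  l <- ei_layer(2, 1, gain = 1)
  ones <- matrix(1, 1, 2)
  expect_equal(as.numeric(ei_forward(l, c(3, 3), sample = ones)), 0)

  l2 <- ei_layer(2, 1, gain = 2)
  expect_equal(as.numeric(ei_forward(l2, c(3, 5),
                                     sample = matrix(c(1, 0), 1))), 6)
  expect_equal(as.numeric(ei_forward(l2, c(3, 5),
                                     sample = matrix(0, 1, 2))), 0)

  expect_error(ei_forward(l, c(1, 2, 3)), "fan_in")
  expect_error(ei_forward(l, c(-1, 2)), "nonnegative")
  expect_error(ei_layer(3, 2), "even")

  # every realized weight matrix is elementwise nonnegative
  l3 <- ei_layer(6, 4)
  s <- sample_release(l3$probs, 3, seed = 1)
  for (b in s) expect_true(all(layer_weights(l3, b) >= 0))
  expect_true(all(layer_weights(l3) >= 0))
})

test_that("EI multilayer perceptron matches hand arithmetic and is homogeneous", {
  l1 <- ei_layer(2, 2, gain = 1)
  l2 <- ei_layer(2, 2, gain = 1)
  samples <- list(matrix(c(1, 0, 0, 1), 2), matrix(c(1, 0, 0, 1), 2))
  # x = 2 -> balanced (2, -2) -> hidden (2, -2) -> relu (2, 0)
  # -> flip inhibitory half (2, 0) -> scores (2, 0)
  expect_equal(as.numeric(mlp_forward(list(l1, l2), 2, samples)), c(2, 0))

  expect_equal(as.numeric(mlp_forward(list(l1, l2), 0, samples)), c(0, 0))

  layers <- list(ei_layer(4, 4), ei_layer(4, 3))
  x <- c(0.3, 0.8)
  s <- lapply(layers, function(l) sample_release(l$probs, 1, seed = 3)[[1]])
  base <- mlp_forward(layers, x, s)
  expect_equal(as.numeric(mlp_forward(layers, 2.5 * x, s)),
               2.5 * as.numeric(base))
})

test_that("LIF dynamics: threshold, reset, decay, fixed point and floor", {
  pars <- lif_params(mem_decay = 0.9, syn_decay = 0.5, threshold = 1,
                     reset = 0, v_min = -1)
  st <- lif_init(1)
  st1 <- lif_step(pars, st, 2)
  expect_equal(st1$i_syn, 2)       # 0.5 * 0 + 2
  expect_equal(st1$spikes, 1)      # v = 0.9 * 0 + 2 >= 1
  expect_equal(st1$v, 0)           # reset

  # sub-threshold: pure geometric membrane decay, no spikes
  st <- structure(list(v = 0.5, i_syn = 0, spikes = 0), class = "lif_state")
  for (t in 1:5) {
    st <- lif_step(pars, st, 0)
    expect_equal(st$v, 0.5 * 0.9^t)
    expect_equal(st$spikes, 0)
  }

  # constant sub-threshold input converges to c / ((1 - alpha)(1 - beta))
  st <- lif_init(1)
  for (t in 1:400) st <- lif_step(pars, st, 0.01)
  expect_equal(st$v, 0.01 / (0.5 * 0.1), tolerance = 1e-6)
  expect_equal(st$i_syn, 0.01 / 0.5, tolerance = 1e-6)

  # sustained inhibition is floored at v_min
  st <- lif_init(1)
  for (t in 1:50) st <- lif_step(pars, st, -3)
  expect_equal(st$v, -1)

  expect_error(lif_params(mem_decay = 1.2), "mem_decay")
  expect_error(lif_params(threshold = 0, reset = 0), "threshold")
  expect_error(lif_params(v_min = 0.5), "v_min")
})

test_that("spiking rollout: zero input silence, determinism, episode-fixed samples", {
  spec <- rsnn_spec(3, 8, 2, seed = 5)
  zeros <- matrix(0, 10, 3)
  out <- rsnn_rollout(spec, zeros)
  expect_equal(out$readout, matrix(0, 10, 2))

  inputs <- matrix(stats::rnorm(30, sd = 2), 10, 3)
  s <- lapply(spec$layers, function(l)
    sample_release(l$probs, 1, seed = 7)[[1]])
  a <- rsnn_rollout(spec, inputs, samples = s)
  b <- rsnn_rollout(spec, inputs, samples = s)
  expect_identical(a, b)   # one sample, held fixed, fully deterministic

  # spikes enter the readout only through +-1 contributions: actions discrete
  expect_true(all(a$actions %in% c(0L, 1L)))
  expect_true(all(is.finite(a$readout)))
})

test_that("network specification separates trainable and frozen layers", {
  full <- rsnn_spec(4, 16, 2)
  expect_setequal(full$trainable, c("input", "recurrent", "readout"))
  res <- rsnn_spec(4, 16, 2, reservoir = TRUE)
  expect_setequal(res$trainable, c("input", "readout"))
  expect_lt(length(res$trainable), length(full$trainable))
  expect_error(rsnn_spec(4, 15, 2), "even")
  # hidden neurons split half excitatory / half inhibitory by construction
  expect_equal(full$hidden_dim %% 2L, 0L)
})
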