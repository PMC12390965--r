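test_that("training configuration validates its fields", {
  expect_error(train_config("rl", optimizer = "adam"), "reserved")
  expect_error(train_config("rl", clip_eps = 0.7), "clip_eps")
  expect_error(train_config("rl", n_samples = 0))
  cfg <- rsrp_preset("full")
  expect_identical(cfg$n_samples, 10240L)
  expect_identical(cfg$hidden, 256L)
  expect_equal(cfg$learning_rate, 0.15)
})

test_that("training trajectories are bit-reproducible from (config, seed)", {
  fr <- make_target_pattern_reward(6, seed = 3)
  cfg <- train_config("bandit", n_samples = 64, iterations = 30, seed = 12,
                      learning_rate = 0.1)
  a <- train_bandit(fr, cfg)
  b <- train_bandit(fr, cfg)
  expect_identical(unclass(a$probs), unclass(b$probs))
  expect_identical(a$log$reward_mean, b$log$reward_mean)
  expect_identical(a$log$transformed_checksum, b$log$transformed_checksum)
})

test_that("a zero learning rate is an exact null training run", {
  ds <- make_digit_patterns(5, 0.1, seed = 1)
  cfg <- rsrp_preset("desk_classification", seed = 1, learning_rate = 0,
                     iterations = 3, eval_interval = 1)
  layers0 <- rsrp:::build_mlp(64, 32, 10, 2, 0.001, 0.45, seed = 1)
  untrained <- evaluate_classifier(layers0, ds)
  fit <- train_classification(cfg, ds)
  for (l in seq_along(fit$layers)) {
    expect_identical(as.numeric(fit$layers[[l]]$probs),
                     as.numeric(layers0[[l]]$probs))
  }
  expect_equal(fit$final_eval, untrained)
})

test_that("population evaluation on shared batches is deterministic", {
  ds <- make_digit_patterns(5, 0.1, seed = 4)
  layers <- rsrp:::build_mlp(64, 8, 10, 2, 0.001, 0.45, seed = 2)
  cfg <- train_config("classification", n_samples = 6, batch_size = 8,
                      data_sampling = "shared_batch", seed = 3)
  a <- evaluate_population_classification(layers, ds, cfg, iteration = 1)
  b <- evaluate_population_classification(layers, ds, cfg, iteration = 1)
  expect_identical(a$rewards$raw, b$rewards$raw)
  expect_identical(a$samples, b$samples)
  expect_error(
    evaluate_population_classification(
      layers, list(features = matrix(0, 0, 64), labels = integer(0)), cfg),
    "empty")
})

test_that("a hand-built perfect classifier earns the maximal sparse reward", {
  # two one-hot classes; hidden E pair copies (x1, x2), I pair copies
  # (x2, x1); readout computes (x1 - x2, x2 - x1)
  set_bits <- function(shape, ones, eps = 1e-6) {
    p <- release_probs(shape, init = 0.5, clip_eps = eps)
    p[] <- eps
    p[ones] <- 1 - eps
    p
  }
  w1 <- set_bits(c(4, 4), cbind(1:4, c(1, 2, 2, 1)))
  w2 <- set_bits(c(2, 4), cbind(c(1, 2, 1, 2), c(1, 2, 3, 4)))
  layers <- list(ei_layer(4, 4, gain = 1, probs = w1),
                 ei_layer(4, 2, gain = 1, probs = w2))
  ds <- list(features = rbind(diag(2), diag(2)), labels = c(0L, 1L, 0L, 1L))
  expect_equal(evaluate_classifier(layers, ds), 1)

  cfg <- train_config("classification", n_samples = 8, batch_size = 4,
                      reward = "accuracy", data_sampling = "shared_batch",
                      seed = 5)
  ev <- evaluate_population_classification(layers, ds, cfg)
  expect_equal(ev$rewards$raw, rep(1, 8))
})

test_that("per-trial batches with full batch size reduce to the shared mode", {
  ds <- make_digit_patterns(2, 0.1, seed = 8)
  layers <- rsrp:::build_mlp(64, 8, 10, 2, 0.001, 0.45, seed = 2)
  base <- train_config("classification", n_samples = 5,
                       batch_size = nrow(ds$features), seed = 6)
  per_trial <- base; per_trial$data_sampling <- "per_trial_random"
  shared <- base; shared$data_sampling <- "shared_batch"
  a <- evaluate_population_classification(layers, ds, per_trial, 1)
  b <- evaluate_population_classification(layers, ds, shared, 1)
  expect_equal(a$rewards$raw, b$rewards$raw)
})

test_that("epoch batches partition the data without replacement", {
  nb <- rsrp:::batch_cursor(10, 5, seed = 3)
  expect_setequal(c(nb(), nb()), 1:10)
  # reshuffles for the next epoch but still partitions it
  expect_setequal(c(nb(), nb()), 1:10)
})

test_that("a frozen reservoir leaves recurrent probabilities untouched", {
  cfg <- train_config("rl", n_samples = 16, iterations = 3, hidden = 8,
                      seed = 2, reservoir = TRUE, eval_interval = 10,
                      learning_rate = 0.3)
  spec0 <- rsnn_spec(4, 8, 2, reservoir = TRUE, seed = cfg$seed)
  fit <- train_rl(cfg)
  expect_identical(as.numeric(fit$spec$layers$recurrent$probs),
                   as.numeric(spec0$layers$recurrent$probs))
  # but the trainable layers did move
  expect_false(identical(as.numeric(fit$spec$layers$readout$probs),
                         as.numeric(spec0$layers$readout$probs)))
})

test_that("training log keeps one record per iteration with finite entropies", {
  fr <- make_target_pattern_reward(4, seed = 1)
  cfg <- train_config("bandit", n_samples = 32, iterations = 12, seed = 7)
  fit <- train_bandit(fr, cfg)
  expect_identical(nrow(fit$log), 12L)
  expect_identical(fit$log$iteration, 1:12)
  expect_true(all(fit$log$entropy_synapses >= 0))
  expect_true(all(is.finite(fit$log$reward_mean)))
})

test_that("checkpoints round-trip probabilities bit-exactly", {
  ds <- make_digit_patterns(3, 0.1, seed = 5)
  cfg <- rsrp_preset("desk_classification", seed = 2, iterations = 4,
                     eval_interval = 2)
  fit <- train_classification(cfg, ds)
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(fit, path)
  back <- load_checkpoint(path)
  expect_identical(length(back$layers), length(fit$layers))
  for (l in seq_along(fit$layers)) {
    expect_identical(as.numeric(back$layers[[l]]$probs),
                     as.numeric(fit$layers[[l]]$probs))
    expect_identical(back$layers[[l]]$gain, fit$layers[[l]]$gain)
  }
  expect_identical(back$seed, 2L)

  log_path <- withr::local_tempfile(fileext = ".csv")
  write_training_log(fit, log_path)
  log <- utils::read.csv(log_path)
  expect_identical(nrow(log), 4L)
})

test_that("sampling sweep tabulates one accuracy per grid cell and seed", {
  ds <- make_digit_patterns(5, 0.1, seed = 3)
  grid <- data.frame(ss = c(2, 4), ds = c(4, 2))
  cfg <- rsrp_preset("desk_classification", iterations = 3,
                     eval_interval = 5)
  out <- sampling_size_sweep(grid, ds, cfg, seeds = 1:2)
  expect_identical(nrow(out), 4L)
  expect_setequal(names(out), c("ss", "ds", "seed", "accuracy"))
  expect_true(all(out$accuracy >= 0 & out$accuracy <= 1))
})
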