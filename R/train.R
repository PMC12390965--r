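#' Training configuration
#'
#' Bundles every tunable of the two-stage training loop: population
#' evaluation (the network interacts with its task under N independent
#' release samples) followed by the plasticity update on the transformed
#' rewards. Reinforcement-learning defaults follow the reference settings
#' eta = 0.15, eps = 0.001; `n_samples` and the architecture default to the
#' desk preset (see [rsrp_preset()]).
#'
#' @param task `"rl"`, `"classification"` or `"bandit"`.
#' @param n_samples synaptic sampling size N (release-sample sets per
#'   update).
#' @param learning_rate eta >= 0 (0 gives an exact null update).
#' @param clip_eps release-probability clipping threshold.
#' @param iterations number of update steps.
#' @param reward_transform `"centered_rank"`, `"zero_mean"` or `"identity"`.
#' @param reward classification reward signal: `"soft_recall"`, `"accuracy"`
#'   or `"cross_entropy"`.
#' @param topk top-k tolerance of the accuracy reward.
#' @param batch_size data sampling size (instances per reward evaluation,
#'   classification only).
#' @param data_sampling `"per_trial_random"` (a fresh batch per release
#'   sample, drawn without replacement within an epoch) or `"shared_batch"`
#'   (all samples of an update step see the same batch).
#' @param seed master seed; every episode, batch and sampling round derives
#'   its own stream from it via [derive_seed()].
#' @param hidden hidden-layer width(s).
#' @param reservoir freeze the recurrent layer (RL only).
#' @param gain_scale numerator of the `c / sqrt(fan_in)` weight gain
#'   (scalar, or length 3 for the spiking network's input/recurrent/readout
#'   layers).
#' @param init_jitter half-width of the uniform jitter of the initial
#'   release probabilities around 0.5 (see [rsnn_spec()]).
#' @param obs_scale per-channel observation divisors for the RL task;
#'   `NULL` uses [cartpole_obs_scale()].
#' @param lif [lif_params()] for the spiking network.
#' @param readout_decay readout integrator leak.
#' @param eval_interval iterations between deterministic evaluations.
#' @param n_eval_episodes episodes (RL) averaged per evaluation.
#' @param eval_max_steps episode cap used in evaluation.
#' @param stop_at_return optional early-stop: halt once the deterministic
#'   evaluation return reaches this value (e.g. the environment cap).
#' @param optimizer reserved hook; only plain `"sgd"` updates are
#'   implemented.
#' @return a `train_config` list.
#' @export
train_config <- function(task = c("rl", "classification", "bandit"),
                         n_samples = 512L, learning_rate = 0.15,
                         clip_eps = 0.001, iterations = 100L,
                         reward_transform = c("centered_rank", "zero_mean",
                                              "identity"),
                         reward = c("soft_recall", "accuracy",
                                    "cross_entropy"),
                         topk = 1L, batch_size = 16L,
                         data_sampling = c("per_trial_random",
                                           "shared_batch"),
                         seed = 1L, hidden = 64L, reservoir = FALSE,
                         gain_scale = 2, init_jitter = 0.45,
                         obs_scale = NULL, lif = lif_params(),
                         readout_decay = 0.5, eval_interval = 5L,
                         n_eval_episodes = 5L, eval_max_steps = 500L,
                         stop_at_return = NULL,
                         optimizer = c("sgd", "momentum", "adam")) {
  task <- match.arg(task)
  reward_transform <- match.arg(reward_transform)
  reward <- match.arg(reward)
  data_sampling <- match.arg(data_sampling)
  optimizer <- match.arg(optimizer)
  if (optimizer != "sgd") {
    stop("optimizer '", optimizer, "' is a reserved configuration hook; ",
         "only plain sgd updates are implemented")
  }
  stopifnot(n_samples >= 1, learning_rate >= 0, iterations >= 1,
            clip_eps > 0, clip_eps < 0.5, batch_size >= 1)
  structure(list(task = task, n_samples = as.integer(n_samples),
                 learning_rate = learning_rate, clip_eps = clip_eps,
                 iterations = as.integer(iterations),
                 reward_transform = reward_transform, reward = reward,
                 topk = as.integer(topk),
                 batch_size = as.integer(batch_size),
                 data_sampling = data_sampling, seed = as.integer(seed),
                 hidden = as.integer(hidden), reservoir = reservoir,
                 gain_scale = gain_scale, init_jitter = init_jitter,
                 obs_scale = obs_scale, lif = lif,
                 readout_decay = readout_decay,
                 eval_interval = as.integer(eval_interval),
                 n_eval_episodes = as.integer(n_eval_episodes),
                 eval_max_steps = as.integer(eval_max_steps),
                 stop_at_return = stop_at_return, optimizer = optimizer),
            class = "train_config")
}

#' Named configuration presets
#'
#' `"full"` is the full-scale reinforcement-learning configuration (hidden
#' 256, N = 10,240, learning rate 0.15); `"desk"` is the scaled-down
#' configuration used throughout the test suite and examples (hidden 64,
#' N = 512), sized so a full training run completes in minutes on one CPU.
#' The desk preset uses a larger learning rate (0.7): with a 20x smaller
#' population the per-iteration gradient estimate is noisier, and covering
#' the same distance in probability space within 100 iterations takes
#' fewer, larger steps; the learning rate is tuned per configuration.
#'
#' `"desk_classification"` is the matching sparse-reward classification
#' configuration for the synthetic digit task (hidden 32, 64 release
#' samples of 16-instance batches per update, 400 updates).
#'
#' @param name `"desk"`, `"full"` or `"desk_classification"`.
#' @param ... overrides passed to [train_config()].
#' @return a [train_config()].
#' @export
rsrp_preset <- function(name = c("desk", "full", "desk_classification"),
                        ...) {
  name <- match.arg(name)
  defaults <- switch(name,
    desk = list(task = "rl", hidden = 64L, n_samples = 512L,
                iterations = 100L, learning_rate = 0.7,
                gain_scale = c(2, 1, 2), stop_at_return = 500),
    full = list(task = "rl", hidden = 256L, n_samples = 10240L,
                iterations = 100L, learning_rate = 0.15,
                gain_scale = c(2, 1, 2)),
    desk_classification = list(task = "classification", hidden = 32L,
                               n_samples = 64L, batch_size = 16L,
                               learning_rate = 1.2, iterations = 400L,
                               eval_interval = 100L)
  )
  overrides <- list(...)
  do.call(train_config, utils::modifyList(defaults, overrides))
}

# --- population evaluation: reinforcement learning ------------------------

# Per-sample initial cart-pole states, each from its own derived seed so the
# population is reproducible and independent of evaluation order.
population_init_states <- function(master_seed, iteration, n) {
  t(vapply(seq_len(n), function(i) {
    with_seed(derive_seed(master_seed, iteration, i),
              stats::runif(4, -0.05, 0.05))
  }, numeric(4)))
}

# list of N sample matrices -> (fan_out x fan_in x N) weight array
samples_to_weight_array <- function(layer, samples) {
  arr <- array(unlist(samples, use.names = FALSE),
               dim = c(layer$fan_out, layer$fan_in, length(samples)))
  layer$gain * arr
}

expected_weight_array <- function(layer) {
  array(layer_weights(layer), dim = c(layer$fan_out, layer$fan_in, 1L))
}

#' Evaluate a population of release samples on the cart-pole task
#'
#' Draws N release-sample sets (one per episode, each held fixed across all
#' timesteps of its episode), runs one full cart-pole episode per sample
#' through the recurrent spiking network, and returns the samples together
#' with the episodic returns as raw rewards.
#'
#' @param spec an [rsnn_spec()].
#' @param config a [train_config()].
#' @param iteration iteration number (enters the derived seeds).
#' @param compiled use the C++ population rollout (default); the pure-R path
#'   is equivalent and kept for cross-checking.
#' @return list with `samples` (per layer, a list of N binary matrices) and
#'   `rewards` (a [reward_vector()] of episodic returns).
#' @export
evaluate_population_rl <- function(spec, config, iteration = 1L,
                                   compiled = TRUE) {
  n <- config$n_samples
  samples <- lapply(stats::setNames(seq_along(spec$layers),
                                    names(spec$layers)), function(li) {
    sample_release(spec$layers[[li]]$probs, n,
                   seed = derive_seed(config$seed, iteration, 7000 + li))
  })
  init_states <- population_init_states(config$seed, iteration, n)
  if (compiled) {
    returns <- cartpole_population_returns_cpp(
      samples_to_weight_array(spec$layers$input, samples$input),
      samples_to_weight_array(spec$layers$recurrent, samples$recurrent),
      samples_to_weight_array(spec$layers$readout, samples$readout),
      init_states, spec$obs_scale,
      spec$lif$mem_decay, spec$lif$syn_decay, spec$lif$threshold,
      spec$lif$reset, spec$lif$v_min, spec$readout_decay,
      config$eval_max_steps)
  } else {
    env <- cartpole_env(max_steps = config$eval_max_steps)
    returns <- vapply(seq_len(n), function(i) {
      pol <- rsnn_policy(spec, samples = lapply(samples, `[[`, i))
      env_seed <- derive_seed(config$seed, iteration, i)
      run_episode(env, pol, max_steps = config$eval_max_steps,
                  seed = env_seed)$total_return
    }, numeric(1))
  }
  list(samples = samples, rewards = reward_vector(returns))
}

#' Deterministic evaluation of a spiking policy on cart-pole
#'
#' Runs `n_episodes` fresh episodes with the expected weights (`gain * rho`,
#' the analog realization of the learned release distribution) and the
#' deterministic argmax policy.
#'
#' @param spec an [rsnn_spec()].
#' @param n_episodes number of evaluation episodes.
#' @param seed seed from which per-episode reset seeds are derived.
#' @param max_steps episode cap.
#' @param compiled use the C++ rollout.
#' @return list with `mean_return` and the per-episode `returns`.
#' @export
evaluate_rsnn_cartpole <- function(spec, n_episodes = 5L, seed = 1L,
                                   max_steps = 500L, compiled = TRUE) {
  init_states <- t(vapply(seq_len(n_episodes), function(j) {
    with_seed(derive_seed(seed, 999983, j), stats::runif(4, -0.05, 0.05))
  }, numeric(4)))
  if (compiled) {
    returns <- cartpole_population_returns_cpp(
      expected_weight_array(spec$layers$input),
      expected_weight_array(spec$layers$recurrent),
      expected_weight_array(spec$layers$readout),
      init_states, spec$obs_scale,
      spec$lif$mem_decay, spec$lif$syn_decay, spec$lif$threshold,
      spec$lif$reset, spec$lif$v_min, spec$readout_decay,
      as.integer(max_steps))
  } else {
    env <- cartpole_env(max_steps = max_steps)
    returns <- vapply(seq_len(n_episodes), function(j) {
      pol <- rsnn_policy(spec)
      run_episode(env, pol, max_steps = max_steps,
                  seed = derive_seed(seed, 999983, j))$total_return
    }, numeric(1))
  }
  list(mean_return = mean(returns), returns = as.numeric(returns))
}

new_log_row <- function(iteration, rewards, transformed, entropies,
                        eval_metric) {
  row <- data.frame(iteration = iteration,
                    reward_mean = mean(rewards), reward_min = min(rewards),
                    reward_max = max(rewards),
                    transformed_checksum = sum(transformed),
                    eval_metric = eval_metric,
                    time = as.numeric(Sys.time()))
  for (nm in names(entropies)) row[[paste0("entropy_", nm)]] <- entropies[[nm]]
  row
}

layer_entropies <- function(layers) {
  vapply(layers, function(l) bernoulli_entropy(l$probs)$total, numeric(1))
}

#' Train a recurrent spiking network on cart-pole with release plasticity
#'
#' The two-stage loop: (1) population evaluation — N release-sample sets,
#' one full episode each; (2) plasticity optimization — transform the
#' episodic returns (centered rank by default), apply the natural-gradient
#' update to every trainable layer, clip. Deterministic evaluation with
#' expected weights runs every `eval_interval` iterations and at the end;
#' when `stop_at_return` is set, training halts early once the evaluation
#' return reaches it.
#'
#' @param config a [train_config()] with `task = "rl"`.
#' @param spec optional pre-built [rsnn_spec()] (otherwise constructed from
#'   the config; input 4, output 2 for cart-pole).
#' @param compiled use the C++ population rollout.
#' @param verbose print per-evaluation progress.
#' @return an `rsrp_training` object: `log` (one row per iteration), `spec`
#'   with final release probabilities, `final_eval`, `iterations_run`,
#'   `config`.
#' @export
train_rl <- function(config, spec = NULL, compiled = TRUE, verbose = FALSE) {
  stopifnot(config$task == "rl")
  spec <- spec %||% rsnn_spec(
    input_dim = 4L, hidden_dim = config$hidden, output_dim = 2L,
    reservoir = config$reservoir, gain_scale = config$gain_scale,
    clip_eps = config$clip_eps, lif = config$lif,
    readout_decay = config$readout_decay,
    init_jitter = config$init_jitter,
    obs_scale = config$obs_scale %||% cartpole_obs_scale(),
    seed = config$seed)
  tstate <- reward_transform_state(config$reward_transform)
  log <- NULL
  final_eval <- NA_real_
  iterations_run <- 0L
  for (iter in seq_len(config$iterations)) {
    ev <- evaluate_population_rl(spec, config, iteration = iter,
                                 compiled = compiled)
    tr <- apply_reward_transform(ev$rewards, tstate)
    tstate <- tr$state
    if (any(!is.finite(tr$rewards$transformed))) {
      stop("non-finite rewards at iteration ", iter, "; raw range [",
           min(ev$rewards$raw), ", ", max(ev$rewards$raw), "]")
    }
    for (nm in spec$trainable) {
      spec$layers[[nm]]$probs <- rsrp_update(
        spec$layers[[nm]]$probs, ev$samples[[nm]], tr$rewards,
        learning_rate = config$learning_rate)
    }
    iterations_run <- iter
    eval_metric <- NA_real_
    last <- iter == config$iterations
    if (iter %% config$eval_interval == 0L || last) {
      eval_metric <- evaluate_rsnn_cartpole(
        spec, n_episodes = config$n_eval_episodes, seed = config$seed,
        max_steps = config$eval_max_steps, compiled = compiled)$mean_return
      final_eval <- eval_metric
      if (verbose) {
        message(sprintf("iter %3d: population mean %.1f, eval %.1f",
                        iter, mean(ev$rewards$raw), eval_metric))
      }
    }
    log <- rbind(log, new_log_row(iter, ev$rewards$raw,
                                  tr$rewards$transformed,
                                  layer_entropies(spec$layers), eval_metric))
    if (!is.null(config$stop_at_return) && !is.na(eval_metric) &&
        eval_metric >= config$stop_at_return) {
      break
    }
  }
  structure(list(log = log, spec = spec, config = config,
                 final_eval = final_eval, iterations_run = iterations_run),
            class = "rsrp_training")
}

#' @export
print.rsrp_training <- function(x, ...) {
  cat(sprintf("release-plasticity training (%s): %d iterations, final eval %s\n",
              x$config$task, x$iterations_run,
              format(x$final_eval, digits = 4)))
  invisible(x)
}

# --- population evaluation: classification --------------------------------

build_mlp <- function(input_dim, hidden, n_classes, gain_scale, clip_eps,
                      init_jitter = 0.45, seed = 0L) {
  dims <- c(2L * input_dim, hidden, n_classes)
  lapply(seq_len(length(dims) - 1L), function(l) {
    probs <- release_probs(c(dims[l + 1L], dims[l]), init = 0.5,
                           clip_eps = clip_eps, jitter = init_jitter,
                           seed = derive_seed(seed, 424243, l))
    ei_layer(dims[l], dims[l + 1L], gain = gain_scale[1L] / sqrt(dims[l]),
             probs = probs)
  })
}

# Epoch-based batch cursor: consecutive chunks of a permutation, reshuffled
# when exhausted (per-trial batches are drawn without replacement within an
# epoch).
batch_cursor <- function(n, batch_size, seed) {
  perm <- with_seed(seed, sample.int(n))
  pos <- 1L
  epoch <- 1L
  function() {
    if (pos + batch_size - 1L > n) {
      epoch <<- epoch + 1L
      perm <<- with_seed(derive_seed(seed, epoch), sample.int(n))
      pos <<- 1L
    }
    idx <- perm[pos:(pos + batch_size - 1L)]
    pos <<- pos + batch_size
    idx
  }
}

#' Evaluate a population of release samples on a classification batch
#'
#' Draws N release-sample sets for every layer and computes one scalar
#' reward per sample from the configured classification reward signal. In
#' `shared_batch` mode every sample is scored on the same batch; in
#' `per_trial_random` mode each sample sees a freshly drawn batch.
#'
#' @param layers list of [ei_layer()]s.
#' @param dataset a [synthetic dataset][make_digit_patterns()] (or any list
#'   with `features` and `labels`).
#' @param config a [train_config()].
#' @param iteration iteration number.
#' @param next_batch optional batch-cursor closure (created internally by
#'   [train_classification()]); defaults to seeded random batches.
#' @return list with `samples` (per layer) and `rewards`.
#' @export
evaluate_population_classification <- function(layers, dataset, config,
                                               iteration = 1L,
                                               next_batch = NULL) {
  n_data <- nrow(dataset$features)
  if (n_data < 1L) stop("dataset is empty")
  n <- config$n_samples
  bs <- min(config$batch_size, n_data)
  samples <- lapply(seq_along(layers), function(li) {
    sample_release(layers[[li]]$probs, n,
                   seed = derive_seed(config$seed, iteration, 7000 + li))
  })
  if (is.null(next_batch)) {
    next_batch <- batch_cursor(n_data, bs,
                               derive_seed(config$seed, iteration, 31))
  }
  shared_idx <- if (config$data_sampling == "shared_batch") next_batch()
  feats <- t(dataset$features)  # d x n, columns are instances
  rewards <- vapply(seq_len(n), function(i) {
    idx <- if (config$data_sampling == "shared_batch") shared_idx else
      next_batch()
    scores <- mlp_forward(layers, feats[, idx, drop = FALSE],
                          samples = lapply(samples, `[[`, i))
    classification_reward(t(scores), dataset$labels[idx],
                          kind = config$reward, k = config$topk)
  }, numeric(1))
  list(samples = samples, rewards = reward_vector(rewards))
}

#' Accuracy of the expected-weight classifier
#'
#' Deterministic evaluation: forward pass with analog weights `gain * rho`
#' and argmax prediction.
#'
#' @param layers list of [ei_layer()]s.
#' @param dataset dataset with `features` and `labels`.
#' @return fraction of correctly classified instances.
#' @export
evaluate_classifier <- function(layers, dataset) {
  scores <- mlp_forward(layers, t(dataset$features))
  pred <- max.col(t(scores), ties.method = "first") - 1L
  mean(pred == dataset$labels)
}

#' Train a classifier with sparse-reward release plasticity
#'
#' Per update step, N release-sample sets each produce one scalar reward
#' from a data batch (no per-instance error signal, no backpropagation); the
#' transformed rewards drive the natural-gradient update of every layer's
#' release probabilities.
#'
#' @param config a [train_config()] with `task = "classification"`.
#' @param dataset training dataset (`features` n x d, `labels` in `[0, C)`).
#' @param eval_data held-out dataset for the logged accuracy (defaults to
#'   `dataset`).
#' @param layers optional pre-built layer list.
#' @param verbose print per-evaluation progress.
#' @return an `rsrp_training` object; `final_eval` is the final held-out
#'   accuracy and `layers` holds the trained layers.
#' @export
train_classification <- function(config, dataset, eval_data = NULL,
                                 layers = NULL, verbose = FALSE) {
  stopifnot(config$task == "classification")
  eval_data <- eval_data %||% dataset
  n_classes <- length(unique(dataset$labels))
  layers <- layers %||% build_mlp(ncol(dataset$features), config$hidden,
                                  n_classes, config$gain_scale,
                                  config$clip_eps, config$init_jitter,
                                  seed = config$seed)
  tstate <- reward_transform_state(config$reward_transform)
  n_data <- nrow(dataset$features)
  next_batch <- batch_cursor(n_data, min(config$batch_size, n_data),
                             derive_seed(config$seed, 17))
  log <- NULL
  final_eval <- NA_real_
  for (iter in seq_len(config$iterations)) {
    ev <- evaluate_population_classification(layers, dataset, config,
                                             iteration = iter,
                                             next_batch = next_batch)
    tr <- apply_reward_transform(ev$rewards, tstate)
    tstate <- tr$state
    if (any(!is.finite(tr$rewards$transformed))) {
      stop("non-finite rewards at iteration ", iter)
    }
    for (l in seq_along(layers)) {
      layers[[l]]$probs <- rsrp_update(layers[[l]]$probs, ev$samples[[l]],
                                       tr$rewards,
                                       learning_rate = config$learning_rate)
    }
    eval_metric <- NA_real_
    if (iter %% config$eval_interval == 0L || iter == config$iterations) {
      eval_metric <- evaluate_classifier(layers, eval_data)
      final_eval <- eval_metric
      if (verbose) {
        message(sprintf("iter %3d: reward mean %.3f, accuracy %.3f",
                        iter, mean(ev$rewards$raw), eval_metric))
      }
    }
    names_l <- paste0("layer", seq_along(layers))
    ent <- stats::setNames(
      vapply(layers, function(l) bernoulli_entropy(l$probs)$total,
             numeric(1)), names_l)
    log <- rbind(log, new_log_row(iter, ev$rewards$raw,
                                  tr$rewards$transformed, as.list(ent),
                                  eval_metric))
  }
  structure(list(log = log, layers = layers, config = config,
                 final_eval = final_eval,
                 iterations_run = config$iterations),
            class = "rsrp_training")
}

# --- bandit trainer (tabulated reward over K synapses) --------------------

#' Train release probabilities against a tabulated reward
#'
#' Small-scale parameter-recovery loop: K synapses, reward given by a
#' [tabular_reward()] lookup over the 2^K release patterns. Used to verify
#' that the plasticity rule climbs the exact reward landscape.
#'
#' @param reward_fn a [tabular_reward()].
#' @param config a [train_config()] with `task = "bandit"`.
#' @return an `rsrp_training` object; `probs` holds the final 1 x K release
#'   probabilities and `final_eval` the exact expected reward J(rho).
#' @export
train_bandit <- function(reward_fn, config) {
  stopifnot(config$task == "bandit")
  k <- reward_fn$K
  probs <- release_probs(c(1L, k), clip_eps = config$clip_eps)
  tstate <- reward_transform_state(config$reward_transform)
  log <- NULL
  for (iter in seq_len(config$iterations)) {
    samples <- sample_release(probs, config$n_samples,
                              seed = derive_seed(config$seed, iter, 1))
    raw <- vapply(samples, function(s) tabular_reward_value(reward_fn, s),
                  numeric(1))
    tr <- apply_reward_transform(reward_vector(raw), tstate)
    tstate <- tr$state
    probs <- rsrp_update(probs, samples, tr$rewards,
                         learning_rate = config$learning_rate)
    log <- rbind(log, new_log_row(iter, raw, tr$rewards$transformed,
                                  list(synapses = bernoulli_entropy(probs)$total),
                                  NA_real_))
  }
  final_eval <- enumerate_reward(as.numeric(probs), reward_fn)$J
  structure(list(log = log, probs = probs, config = config,
                 final_eval = final_eval,
                 iterations_run = config$iterations),
            class = "rsrp_training")
}

# --- sampling-size sweep ---------------------------------------------------

#' Sweep synaptic vs data sampling sizes
#'
#' Trains one classifier per (synaptic sampling size `ss`, data sampling
#' size `ds`) cell and seed, and tabulates the final held-out accuracy, for
#' studying the product law: performance tracks the total number of forward
#' trials `ss * ds` per update step.
#'
#' @param grid data frame with columns `ss` and `ds`.
#' @param dataset training dataset.
#' @param config base [train_config()] (its `n_samples` and `batch_size` are
#'   overridden per cell).
#' @param eval_data held-out dataset.
#' @param seeds master seeds replicated per cell.
#' @return data frame with columns `ss`, `ds`, `seed`, `accuracy`.
#' @export
sampling_size_sweep <- function(grid, dataset, config, eval_data = NULL,
                                seeds = 1:5) {
  stopifnot(all(c("ss", "ds") %in% names(grid)))
  out <- NULL
  for (r in seq_len(nrow(grid))) {
    for (s in seeds) {
      cfg <- config
      cfg$n_samples <- as.integer(grid$ss[r])
      cfg$batch_size <- as.integer(grid$ds[r])
      cfg$seed <- as.integer(s)
      fit <- train_classification(cfg, dataset, eval_data = eval_data)
      out <- rbind(out, data.frame(ss = grid$ss[r], ds = grid$ds[r],
                                   seed = s, accuracy = fit$final_eval))
    }
  }
  out
}
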