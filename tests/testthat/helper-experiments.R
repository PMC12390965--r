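# Shared fixtures and cached experiment runs. Heavy training experiments are
# computed once per test session and reused by the blocks that assert
# different properties of the same runs.

digit_train_set <- function() make_digit_patterns(50, pixel_noise = 0.1,
                                                  seed = 11)
digit_eval_set <- function() make_digit_patterns(50, pixel_noise = 0.1,
                                                 seed = 99)

.experiment_cache <- new.env(parent = emptyenv())

cached_experiment <- function(key, expr) {
  if (!exists(key, envir = .experiment_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .experiment_cache)
  }
  get(key, envir = .experiment_cache, inherits = FALSE)
}

# One digit-classification training run; returns final accuracy and the
# per-layer entropy trajectory endpoints.
digit_run <- function(seed, transform) {
  cfg <- rsrp_preset("desk_classification", seed = seed,
                     reward_transform = transform)
  fit <- train_classification(cfg, digit_train_set(),
                              eval_data = digit_eval_set())
  list(accuracy = fit$final_eval,
       entropy_first = c(layer1 = fit$log$entropy_layer1[1],
                         layer2 = fit$log$entropy_layer2[1]),
       entropy_last = c(layer1 = utils::tail(fit$log$entropy_layer1, 1),
                        layer2 = utils::tail(fit$log$entropy_layer2, 1)))
}

# The reward-transform ablation: 3 transforms x 5 seeds, shared between the
# entropy-trend and transform-ordering assertions.
ablation_runs <- function() {
  cached_experiment("ablation", {
    out <- list()
    for (tr in c("centered_rank", "zero_mean", "identity")) {
      out[[tr]] <- lapply(1:5, digit_run, transform = tr)
    }
    out
  })
}

# Nearest-class-centroid classifier, an independent baseline for dataset
# separability checks.
nearest_center_accuracy <- function(train, test) {
  classes <- sort(unique(train$labels))
  centers <- t(vapply(classes, function(c) {
    colMeans(train$features[train$labels == c, , drop = FALSE])
  }, numeric(ncol(train$features))))
  d2 <- outer(rowSums(test$features^2), rep(1, nrow(centers))) -
    2 * test$features %*% t(centers) +
    outer(rep(1, nrow(test$features)), rowSums(centers^2))
  pred <- classes[max.col(-d2, ties.method = "first")]
  mean(pred == test$labels)
}
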