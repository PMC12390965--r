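#' Per-trial reward container
#'
#' Holds the N raw episode/trial rewards and, after a transform such as
#' [centered_rank()], the shaped rewards actually fed to the plasticity rule.
#'
#' @param raw numeric vector of raw rewards R_i (task units), length N >= 1.
#' @param transformed optional numeric vector R'_i of the same length.
#' @return a `reward_vector` object.
#' @export
reward_vector <- function(raw, transformed = NULL) {
  raw <- as.numeric(raw)
  if (length(raw) < 1L) stop("reward vector must contain at least one trial")
  if (!is.null(transformed)) {
    transformed <- as.numeric(transformed)
    if (length(transformed) != length(raw)) {
      stop("`transformed` must match `raw` in length")
    }
  }
  structure(list(raw = raw, transformed = transformed),
            class = "reward_vector")
}

#' @export
length.reward_vector <- function(x) length(x$raw)

#' @export
print.reward_vector <- function(x, ...) {
  cat(sprintf("reward vector, N = %d: raw mean %.4g", length(x$raw),
              mean(x$raw)))
  if (!is.null(x$transformed)) {
    cat(sprintf(", transformed mean %.4g", mean(x$transformed)))
  }
  cat("\n")
  invisible(x)
}

# Rewards used by the learning rule: transformed when present, else raw.
effective_rewards <- function(rewards) {
  if (inherits(rewards, "reward_vector")) {
    rewards$transformed %||% rewards$raw
  } else {
    as.numeric(rewards)
  }
}

#' Centered-rank reward transform
#'
#' Replaces raw rewards by their ordinal rankings, centered near zero:
#' `R'_i = -1/2 + (1/N) * sum_j d(R_i > R_j)` with `d` the strict-inequality
#' indicator. Tied rewards receive equal transformed values, and the output
#' depends only on the ordering of the inputs, making the learning rule
#' invariant to any monotone rescaling of the task reward.
#'
#' @param rewards numeric vector or [reward_vector()] of raw rewards.
#' @return a [reward_vector()] with `transformed` filled; order matches input.
#' @export
centered_rank <- function(rewards) {
  raw <- if (inherits(rewards, "reward_vector")) rewards$raw else
    as.numeric(rewards)
  n <- length(raw)
  if (n < 1L) stop("centered rank of an empty reward vector is undefined")
  # rank(ties = "min") - 1 counts the strictly dominated rewards
  dominated <- rank(raw, ties.method = "min") - 1
  reward_vector(raw, transformed = -0.5 + dominated / n)
}

#' Reward-transform state
#'
#' Dispatchable state for the reward shaping applied between population
#' evaluation and the plasticity update. `centered_rank` is stateless;
#' `zero_mean` keeps a running mean of all previously seen raw rewards;
#' `identity` passes raw rewards through (the no-regularization ablation).
#'
#' @param kind one of `"centered_rank"`, `"zero_mean"`, `"identity"`.
#' @param subtract_batch_mean for `zero_mean` only: when `TRUE` the first
#'   batch (empty history) is centered by its own mean instead of passing
#'   through unchanged.
#' @return a `reward_transform_state` object.
#' @export
reward_transform_state <- function(kind = c("centered_rank", "zero_mean",
                                            "identity"),
                                   subtract_batch_mean = FALSE) {
  kind <- match.arg(kind)
  structure(list(kind = kind, history_mean = 0, history_count = 0L,
                 subtract_batch_mean = subtract_batch_mean),
            class = "reward_transform_state")
}

#' Historical zero-mean reward baseline
#'
#' Subtracts the running mean of all rewards observed in earlier batches
#' (the "history reward") from the current raw rewards, then folds the
#' current batch into the history. With an empty history the first batch
#' passes through unchanged (baseline 0) unless the state was built with
#' `subtract_batch_mean = TRUE`.
#'
#' @param rewards numeric vector or [reward_vector()].
#' @param state a [reward_transform_state()] of kind `"zero_mean"`.
#' @return list with `rewards` (a [reward_vector()] with `transformed`) and
#'   the updated `state`.
#' @export
zero_mean_transform <- function(rewards, state) {
  raw <- if (inherits(rewards, "reward_vector")) rewards$raw else
    as.numeric(rewards)
  baseline <- if (state$history_count > 0L) {
    state$history_mean
  } else if (isTRUE(state$subtract_batch_mean)) {
    mean(raw)
  } else {
    0
  }
  out <- reward_vector(raw, transformed = raw - baseline)
  n_new <- state$history_count + length(raw)
  state$history_mean <- (state$history_mean * state$history_count +
                           sum(raw)) / n_new
  state$history_count <- n_new
  list(rewards = out, state = state)
}

#' Apply the configured reward transform
#'
#' @param rewards numeric vector or [reward_vector()].
#' @param state a [reward_transform_state()].
#' @return list with `rewards` (transformed) and updated `state`.
#' @export
apply_reward_transform <- function(rewards, state) {
  switch(state$kind,
    centered_rank = list(rewards = centered_rank(rewards), state = state),
    zero_mean = zero_mean_transform(rewards, state),
    identity = {
      raw <- if (inherits(rewards, "reward_vector")) rewards$raw else
        as.numeric(rewards)
      list(rewards = reward_vector(raw, transformed = raw), state = state)
    },
    stop("unknown reward transform kind: ", state$kind)
  )
}

#' Accuracy reward
#'
#' Fraction of instances whose predicted label matches the true label; the
#' sparse "hit" reward for classification.
#'
#' @param predicted_labels,true_labels equal-length label vectors.
#' @return scalar in \[0, 1\].
#' @export
accuracy_reward <- function(predicted_labels, true_labels) {
  if (length(predicted_labels) != length(true_labels)) {
    stop("predicted and true label vectors differ in length")
  }
  mean(predicted_labels == true_labels)
}

# 1-based rank of the true-class score within each row sorted descending.
# Ties broken by smallest column index (stable descending order).
true_label_ranks <- function(scores, true_labels) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  n_class <- ncol(scores)
  if (length(true_labels) != n) {
    stop("`true_labels` must have one entry per score row")
  }
  if (any(true_labels < 0 | true_labels >= n_class)) {
    stop("labels must lie in [0, ", n_class, ")")
  }
  col <- as.integer(true_labels) + 1L
  s_true <- scores[cbind(seq_len(n), col)]
  above <- rowSums(scores > s_true)
  tied_before <- rowSums(scores == s_true &
                           col(scores) < matrix(col, n, n_class))
  above + tied_before + 1L
}

#' Soft-recall reward (mean reciprocal rank)
#'
#' Smoothed recall over a batch: each instance contributes the reciprocal of
#' the 1-based rank of its true class within the network's descending score
#' ordering, averaged over the batch (every instance yields exactly one
#' prediction, so the TP + FP denominator equals the batch size). Lies in
#' (0, 1], reaching 1 only when every true class is top-ranked; unlike the
#' accuracy reward it grants partial credit for near-misses.
#'
#' @param scores numeric matrix, one row per instance, one column per class.
#' @param true_labels integer labels in `[0, ncol(scores))`.
#' @return scalar reward in (0, 1\].
#' @export
soft_recall_reward <- function(scores, true_labels) {
  mean(1 / true_label_ranks(scores, true_labels))
}

#' Cross-entropy reward
#'
#' Negative mean categorical cross-entropy of the softmax-normalized scores
#' (max-subtracted for numerical stability); higher is better, approaching 0
#' from below as the true class dominates.
#'
#' @inheritParams soft_recall_reward
#' @return scalar reward in (-Inf, 0).
#' @export
cross_entropy_reward <- function(scores, true_labels) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (length(true_labels) != n) stop("one label per score row required")
  if (any(true_labels < 0 | true_labels >= ncol(scores))) {
    stop("labels must lie in [0, ", ncol(scores), ")")
  }
  m <- apply(scores, 1L, max)
  lse <- m + log(rowSums(exp(scores - m)))
  s_true <- scores[cbind(seq_len(n), as.integer(true_labels) + 1L)]
  mean(s_true - lse)
}

#' Classification reward from a score matrix
#'
#' Dispatches to the configured reward signal. For `"accuracy"` the
#' prediction is the top-`k` hit: an instance scores 1 when its true class
#' is among the k highest-scoring classes (k = 1 recovers plain accuracy).
#'
#' @param scores score matrix (instances x classes).
#' @param true_labels labels in `[0, ncol(scores))`.
#' @param kind `"soft_recall"`, `"accuracy"` or `"cross_entropy"`.
#' @param k top-k tolerance for the accuracy reward.
#' @return scalar reward.
#' @export
classification_reward <- function(scores, true_labels,
                                  kind = c("soft_recall", "accuracy",
                                           "cross_entropy"),
                                  k = 1L) {
  kind <- match.arg(kind)
  switch(kind,
    soft_recall = soft_recall_reward(scores, true_labels),
    accuracy = mean(true_label_ranks(scores, true_labels) <= k),
    cross_entropy = cross_entropy_reward(scores, true_labels)
  )
}
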