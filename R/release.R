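#' Construct a matrix of synaptic release probabilities
#'
#' The learned object of the plasticity rule: one Bernoulli release
#' probability per synapse, arranged as a `fan_out x fan_in` matrix. Every
#' entry is constrained to the admissible domain `[clip_eps, 1 - clip_eps]`
#' so that the Fisher preconditioner `1 / (rho * (1 - rho))` stays finite.
#'
#' @param shape integer vector `c(fan_out, fan_in)`.
#' @param init initial release probability, identical for every synapse.
#'   Defaults to 0.5, the maximum-entropy Bernoulli.
#' @param clip_eps clipping threshold epsilon in (0, 0.5); probabilities are
#'   kept inside `[clip_eps, 1 - clip_eps]`.
#' @param jitter optional half-width of uniform perturbation added to `init`
#'   (truncated to the admissible domain); 0 gives the deterministic
#'   constant constructor.
#' @param seed RNG seed used when `jitter > 0`.
#' @return a `release_probs` object: a numeric matrix with a `clip_eps`
#'   attribute.
#' @export
release_probs <- function(shape, init = 0.5, clip_eps = 0.001,
                          jitter = 0, seed = NULL) {
  if (length(shape) != 2L || any(!is.finite(shape)) || any(shape < 1) ||
      any(shape != round(shape))) {
    stop("`shape` must be two positive integers c(fan_out, fan_in)")
  }
  if (!is.numeric(clip_eps) || length(clip_eps) != 1L ||
      clip_eps <= 0 || clip_eps >= 0.5) {
    stop("`clip_eps` must be a scalar in (0, 0.5)")
  }
  if (!is.numeric(init) || length(init) != 1L ||
      init < clip_eps || init > 1 - clip_eps) {
    stop("`init` must lie in [clip_eps, 1 - clip_eps] = [",
         clip_eps, ", ", 1 - clip_eps, "]")
  }
  values <- matrix(init, nrow = shape[1L], ncol = shape[2L])
  if (jitter > 0) {
    values <- with_seed(seed, {
      values + matrix(stats::runif(length(values), -jitter, jitter),
                      nrow = shape[1L])
    })
    values <- pmin(pmax(values, clip_eps), 1 - clip_eps)
  }
  new_release_probs(values, clip_eps)
}

new_release_probs <- function(values, clip_eps) {
  stopifnot(is.matrix(values))
  structure(values, clip_eps = clip_eps, class = c("release_probs", "matrix"))
}

#' @export
print.release_probs <- function(x, ...) {
  cat(sprintf("release probabilities: %d x %d synapses, eps = %g\n",
              nrow(x), ncol(x), clip_eps_of(x)))
  cat(sprintf("  range [%.4f, %.4f], mean %.4f, total entropy %.4f nats\n",
              min(x), max(x), mean(x), bernoulli_entropy(x)$total))
  invisible(x)
}

clip_eps_of <- function(probs) {
  eps <- attr(probs, "clip_eps")
  if (is.null(eps)) 0.001 else eps
}

#' Sample binary release outcomes
#'
#' Draws `n_samples` independent release samples theta from the Bernoulli
#' distribution of each synapse. A release sample fixes, for one trial (one
#' episode in reinforcement learning, one forward pass in classification),
#' which synapses transmit (`1`) and which fail (`0`).
#'
#' @param probs a [release_probs()] matrix.
#' @param n_samples number of independent samples N >= 1.
#' @param seed optional RNG seed; identical `(probs, n_samples, seed)`
#'   reproduce bit-identical samples.
#' @return list of `n_samples` binary matrices shaped like `probs`.
#' @export
sample_release <- function(probs, n_samples, seed = NULL) {
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 1) {
    stop("`n_samples` must be a positive count")
  }
  n_samples <- as.integer(n_samples)
  with_seed(seed, {
    lapply(seq_len(n_samples), function(i) {
      bits <- (stats::runif(length(probs)) < as.numeric(probs)) * 1
      matrix(bits, nrow = nrow(probs), ncol = ncol(probs))
    })
  })
}

# Stack a list of release samples into a (n_synapses x N) matrix.
stack_samples <- function(samples) {
  matrix(unlist(samples, use.names = FALSE), ncol = length(samples))
}

check_samples_rewards <- function(probs, samples, rewards) {
  if (length(samples) != length(rewards)) {
    stop("number of release samples (", length(samples),
         ") must equal number of rewards (", length(rewards), ")")
  }
  d <- dim(probs)
  for (s in samples) {
    if (!identical(dim(s), d)) stop("release sample shape does not match probs")
  }
  invisible(TRUE)
}

#' Natural-gradient plasticity update of release probabilities
#'
#' One step of the reward-optimized release plasticity rule: the update
#' direction is the Fisher-preconditioned (natural-gradient) score-function
#' estimate, which for independent Bernoulli synapses collapses to
#' `delta = (eta / N) * sum_i (theta_i - rho) * R_i`, followed by clipping
#' to `[eps, 1 - eps]`. If the reward vector carries transformed rewards
#' (e.g. after [centered_rank()]), those drive the update; otherwise the raw
#' rewards do. Pure function: the input matrix is not modified.
#'
#' @param probs a [release_probs()] matrix rho.
#' @param samples list of N release samples from [sample_release()].
#' @param rewards a [reward_vector()] or plain numeric vector of length N.
#' @param learning_rate step size eta >= 0 (default 0.15).
#' @return updated `release_probs` matrix.
#' @export
rsrp_update <- function(probs, samples, rewards, learning_rate = 0.15) {
  if (!is.numeric(learning_rate) || learning_rate < 0) {
    stop("`learning_rate` must be >= 0 (0 gives the null update)")
  }
  r <- effective_rewards(rewards)
  check_samples_rewards(probs, samples, r)
  n <- length(r)
  theta <- stack_samples(samples)
  delta <- (learning_rate / n) *
    (as.numeric(theta %*% r) - as.numeric(probs) * sum(r))
  eps <- clip_eps_of(probs)
  out <- pmin(pmax(as.numeric(probs) + delta, eps), 1 - eps)
  new_release_probs(matrix(out, nrow = nrow(probs)), eps)
}

#' Score-function (likelihood-ratio) gradient estimate
#'
#' Monte-Carlo estimate of the gradient of the expected reward with respect
#' to the release probabilities, `(1/N) sum_i R_i (theta_i - rho) /
#' (rho (1 - rho))`, requiring no differentiation of the network that maps
#' release samples to rewards.
#'
#' @inheritParams rsrp_update
#' @return gradient matrix shaped like `probs`.
#' @export
score_function_gradient <- function(probs, samples, rewards) {
  r <- effective_rewards(rewards)
  check_samples_rewards(probs, samples, r)
  n <- length(r)
  rho <- as.numeric(probs)
  if (any(rho <= 0) || any(rho >= 1)) {
    stop("release probabilities must lie strictly inside (0, 1)")
  }
  theta <- stack_samples(samples)
  g <- (as.numeric(theta %*% r) - rho * sum(r)) / (n * rho * (1 - rho))
  matrix(g, nrow = nrow(probs))
}

#' Diagonal of the Fisher information matrix
#'
#' Independent Bernoulli synapses give a diagonal Fisher information matrix
#' with entries `1 / (rho (1 - rho))`; its inverse converts the raw
#' score-function gradient into the natural-gradient update direction.
#'
#' @param probs a [release_probs()] matrix (entries strictly inside (0, 1)).
#' @return matrix of Fisher diagonal entries shaped like `probs`.
#' @export
fisher_diagonal <- function(probs) {
  rho <- as.numeric(probs)
  if (any(rho <= 0) || any(rho >= 1)) {
    stop("Fisher information diverges at rho = 0 or 1; clip probabilities first")
  }
  matrix(1 / (rho * (1 - rho)), nrow = nrow(probs))
}

#' Bernoulli entropy of the release distribution
#'
#' Per-synapse entropy `H(rho) = -rho log rho - (1 - rho) log(1 - rho)` in
#' nats and its sum over all synapses. The total entropy quantifies the
#' residual uncertainty of the synaptic parameters; it shrinks as learning
#' drives probabilities toward 0 or 1.
#'
#' @param probs a [release_probs()] matrix (entries strictly inside (0, 1)).
#' @return list with `total` (scalar, nats) and `per_synapse` (matrix).
#' @export
bernoulli_entropy <- function(probs) {
  rho <- as.numeric(probs)
  if (any(rho <= 0) || any(rho >= 1)) {
    stop("entropy requires probabilities strictly inside (0, 1)")
  }
  h <- -rho * log(rho) - (1 - rho) * log(1 - rho)
  list(total = sum(h), per_synapse = matrix(h, nrow = nrow(probs)))
}

#' Hedonistic-synapse baseline parameters
#'
#' The earlier stochastic-release rule parameterizes the release probability
#' through a sigmoid, `p = sigma(q)`, and updates the unconstrained `q` with
#' the plain (non-natural) score-function gradient; kept here as a baseline
#' for comparison with the natural-gradient rule.
#'
#' @param q matrix of unconstrained pre-sigmoid parameters.
#' @return a `hedonistic_params` object with fields `q` and `p = sigma(q)`.
#' @export
hedonistic_params <- function(q) {
  if (!is.matrix(q)) q <- matrix(q, nrow = 1L)
  structure(list(q = q, p = stats::plogis(q)), class = "hedonistic_params")
}

#' One hedonistic plasticity step
#'
#' Updates `q` by the reward-weighted eligibility `e = theta - p` summed over
#' samples: `delta_q = (eta / N) sum_i (theta_i - p) R_i`, then rederives
#' `p = sigma(q)`. No clipping is needed: the sigmoid keeps p in (0, 1).
#'
#' @param params a [hedonistic_params()] object.
#' @param samples list of N binary release samples shaped like `params$q`.
#' @param rewards numeric or [reward_vector()] of length N.
#' @param learning_rate step size eta > 0.
#' @return updated `hedonistic_params`.
#' @export
hedonistic_update <- function(params, samples, rewards, learning_rate = 0.15) {
  r <- effective_rewards(rewards)
  check_samples_rewards(params$q, samples, r)
  n <- length(r)
  theta <- stack_samples(samples)
  dq <- (learning_rate / n) *
    (as.numeric(theta %*% r) - as.numeric(params$p) * sum(r))
  hedonistic_params(params$q + matrix(dq, nrow = nrow(params$q)))
}
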