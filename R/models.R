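#' Balanced input encoding
#'
#' Concatenates a feature vector with its negated copy, `x' = c(x, -x)`, so
#' the signal entering an excitatory-inhibitory balanced layer always sums
#' to zero — the on/off pair encoding of sensory systems. Accepts a vector
#' or a `d x B` matrix of column instances.
#'
#' @param x numeric vector or matrix (features in rows).
#' @return vector/matrix of doubled length; columns always sum to zero.
#' @export
balanced_input <- function(x) {
  if (is.matrix(x)) rbind(x, -x) else c(x, -x)
}

#' Excitatory-inhibitory balanced synaptic layer
#'
#' A layer whose weight matrix is realized from binary release samples as
#' `W = gain * theta`, hence elementwise nonnegative (Dale-consistent);
#' inhibition enters only through the sign flip applied to the second half
#' of the presynaptic activation. The default gain `2 / sqrt(fan_in)` keeps
#' pre-activation variance O(1) regardless of width.
#'
#' @param fan_in presynaptic dimension (must be even: excitatory and
#'   inhibitory halves).
#' @param fan_out postsynaptic dimension.
#' @param gain weight scale g > 0; default `2 / sqrt(fan_in)`.
#' @param probs optional [release_probs()] of shape `c(fan_out, fan_in)`;
#'   defaults to the constant-0.5 initialization.
#' @param clip_eps clipping threshold used when `probs` is constructed here.
#' @return an `ei_layer` object.
#' @export
ei_layer <- function(fan_in, fan_out, gain = NULL, probs = NULL,
                     clip_eps = 0.001) {
  if (fan_in %% 2L != 0L) {
    stop("`fan_in` must be even: equal excitatory and inhibitory halves")
  }
  gain <- gain %||% (2 / sqrt(fan_in))
  if (gain <= 0) stop("`gain` must be > 0")
  probs <- probs %||% release_probs(c(fan_out, fan_in), clip_eps = clip_eps)
  if (!identical(dim(probs), c(as.integer(fan_out), as.integer(fan_in))) &&
      !identical(dim(probs), c(fan_out, fan_in))) {
    if (nrow(probs) != fan_out || ncol(probs) != fan_in) {
      stop("`probs` shape must be c(fan_out, fan_in)")
    }
  }
  structure(list(fan_in = as.integer(fan_in), fan_out = as.integer(fan_out),
                 gain = gain, probs = probs),
            class = "ei_layer")
}

#' Realize layer weights from a release sample
#'
#' `W = gain * theta` for a binary sample, or the expected weights
#' `W = gain * rho` when `sample` is `NULL` (deterministic evaluation mode).
#'
#' @param layer an [ei_layer()].
#' @param sample binary matrix from [sample_release()], or `NULL`.
#' @return nonnegative weight matrix.
#' @export
layer_weights <- function(layer, sample = NULL) {
  w <- if (is.null(sample)) as.numeric(layer$probs) else as.numeric(sample)
  matrix(layer$gain * w, nrow = layer$fan_out)
}

# Flip the sign of the inhibitory (second) half of a nonnegative activation.
ei_sign_flip <- function(x) {
  if (is.matrix(x)) {
    n <- nrow(x)
    x[(n / 2 + 1):n, ] <- -x[(n / 2 + 1):n, , drop = FALSE]
  } else {
    n <- length(x)
    x[(n / 2 + 1):n] <- -x[(n / 2 + 1):n]
  }
  x
}

#' Forward pass through an EI-balanced layer
#'
#' Computes `y = W x'` where `x'` negates the second (inhibitory) half of
#' the nonnegative presynaptic activation `x` and `W = gain * theta` is
#' nonnegative. With `balanced = TRUE` the input is taken as already signed
#' (e.g. the output of [balanced_input()]) and used as-is.
#'
#' @param layer an [ei_layer()].
#' @param x activation vector (or matrix of column instances) of length
#'   `fan_in`; nonnegative unless `balanced = TRUE`.
#' @param sample release sample, or `NULL` for expected weights.
#' @param balanced set when `x` is already a signed balanced encoding.
#' @return pre-activation vector/matrix of length `fan_out`.
#' @export
ei_forward <- function(layer, x, sample = NULL, balanced = FALSE) {
  n_in <- if (is.matrix(x)) nrow(x) else length(x)
  if (n_in != layer$fan_in) {
    stop("input length ", n_in, " does not match fan_in ", layer$fan_in)
  }
  if (!balanced && any(x < 0)) {
    stop("EI layer input must be nonnegative (spike counts or rectified ",
         "activations); use balanced = TRUE for signed balanced encodings")
  }
  xp <- if (balanced) x else ei_sign_flip(x)
  layer_weights(layer, sample) %*% (if (is.matrix(xp)) xp else cbind(xp))
}

#' EI-balanced multilayer perceptron forward pass
#'
#' Classification network: the input is balanced (`c(x, -x)`), passed through
#' the first layer, then alternating rectification and EI forward passes;
#' the final layer emits linear class scores. No bias terms anywhere, so the
#' map is positively homogeneous in its input.
#'
#' @param layers list of [ei_layer()]s; `layers[[1]]$fan_in` must equal twice
#'   the raw feature dimension.
#' @param x feature vector or `d x B` matrix of column instances.
#' @param samples list of release samples (one per layer), or `NULL` for
#'   expected-weight (deterministic) evaluation.
#' @return class-score matrix (`n_classes x B`).
#' @export
mlp_forward <- function(layers, x, samples = NULL) {
  a <- balanced_input(x)
  n_layers <- length(layers)
  for (l in seq_len(n_layers)) {
    s <- if (is.null(samples)) NULL else samples[[l]]
    a <- ei_forward(layers[[l]], a, sample = s, balanced = (l == 1L))
    if (l < n_layers) a <- relu(a)
  }
  a
}

#' Leaky integrate-and-fire neuron parameters
#'
#' Discrete-time LIF dynamics with exponential synapses:
#' `i_syn <- syn_decay * i_syn + input`, `v <- mem_decay * v + i_syn`,
#' spike where `v >= threshold`, spiking units reset to `reset`, and the
#' membrane is floored at `v_min` (a hyperpolarization bound playing the
#' role of an inhibitory reversal potential). Without the floor, sustained
#' inhibition drives `v` arbitrarily negative and the neuron takes many
#' steps to respond when its input flips sign — a switching hysteresis that
#' cripples closed-loop control.
#'
#' @param mem_decay membrane decay beta per step, in (0, 1).
#' @param syn_decay synaptic-current decay alpha per step, in (0, 1).
#' @param threshold firing threshold (must exceed `reset`).
#' @param reset post-spike membrane potential.
#' @param v_min lower bound on the membrane potential (<= `reset`;
#'   `-Inf` disables the floor).
#' @param steps_per_env_step LIF integration steps per environment step.
#' @return a `lif_params` object.
#' @export
lif_params <- function(mem_decay = 0.9, syn_decay = 0.5, threshold = 1,
                       reset = 0, v_min = -1, steps_per_env_step = 1L) {
  if (mem_decay <= 0 || mem_decay >= 1) stop("`mem_decay` must be in (0, 1)")
  if (syn_decay <= 0 || syn_decay >= 1) stop("`syn_decay` must be in (0, 1)")
  if (threshold <= reset) stop("`threshold` must exceed `reset`")
  if (v_min > reset) stop("`v_min` must not exceed `reset`")
  structure(list(mem_decay = mem_decay, syn_decay = syn_decay,
                 threshold = threshold, reset = reset, v_min = v_min,
                 steps_per_env_step = as.integer(steps_per_env_step)),
            class = "lif_params")
}

#' Initial LIF state
#'
#' @param n number of neurons.
#' @return a `lif_state` with zero membrane potential, synaptic current and
#'   spike output.
#' @export
lif_init <- function(n) {
  structure(list(v = numeric(n), i_syn = numeric(n), spikes = numeric(n)),
            class = "lif_state")
}

#' One LIF integration step
#'
#' @param params a [lif_params()].
#' @param state a [lif_state][lif_init()].
#' @param input_current input current vector for this step.
#' @return updated `lif_state`.
#' @export
lif_step <- function(params, state, input_current) {
  i_syn <- params$syn_decay * state$i_syn + input_current
  v <- params$mem_decay * state$v + i_syn
  spikes <- as.numeric(v >= params$threshold)
  v[spikes == 1] <- params$reset
  v <- pmax(v, params$v_min)
  structure(list(v = v, i_syn = i_syn, spikes = spikes), class = "lif_state")
}

#' Recurrent spiking network specification
#'
#' A recurrent hidden layer of LIF neurons connected directly to both input
#' and output: balanced input -> input layer -> recurrent LIF hidden layer
#' (half excitatory, half inhibitory) -> non-spiking leaky-integrator
#' readout. All three connection matrices are nonnegative release-sample
#' realizations; in reservoir mode the recurrent probabilities are frozen at
#' their random initialization and excluded from training.
#'
#' @param input_dim raw observation dimension (before balanced doubling).
#' @param hidden_dim number of hidden LIF neurons (even; default 256).
#' @param output_dim number of readout units (e.g. actions).
#' @param reservoir freeze the recurrent layer (train input/readout only).
#' @param gain_scale numerator c of the per-layer gain `c / sqrt(fan_in)`;
#'   either one scalar for all layers or a length-3 vector
#'   `(input, recurrent, readout)`.
#' @param clip_eps release-probability clipping threshold.
#' @param lif a [lif_params()].
#' @param readout_decay leak of the readout integrator, in \[0, 1).
#' @param init_jitter half-width of the uniform jitter around 0.5 applied to
#'   every layer's initial release probabilities (the overall mean stays at
#'   0.5). Heterogeneous initial tuning is what lets hidden neurons carry
#'   stable, distinguishable features from the first iteration — with a
#'   constant initialization all neurons are exchangeable, the expected
#'   network is silent under balanced input, and closed-loop learning cannot
#'   bootstrap. Set to 0 for the constant initialization.
#' @param obs_scale per-channel divisors applied to observations before the
#'   balanced encoding, normalizing heterogeneous state units to comparable
#'   magnitude; length `input_dim` (default all 1).
#' @param seed seed for the jittered initialization.
#' @return an `rsnn_spec` object with `layers` (input, recurrent, readout)
#'   and a `trainable` character vector.
#' @export
rsnn_spec <- function(input_dim, hidden_dim = 256L, output_dim,
                      reservoir = FALSE, gain_scale = c(2, 1, 2),
                      clip_eps = 0.001,
                      lif = lif_params(), readout_decay = 0.5,
                      init_jitter = 0.45, obs_scale = NULL, seed = NULL) {
  if (hidden_dim %% 2L != 0L) {
    stop("`hidden_dim` must be even (equal E and I populations)")
  }
  if (length(gain_scale) == 1L) gain_scale <- rep(gain_scale, 3L)
  if (length(gain_scale) != 3L) {
    stop("`gain_scale` must be one scalar or c(input, recurrent, readout)")
  }
  obs_scale <- obs_scale %||% rep(1, input_dim)
  if (length(obs_scale) != input_dim || any(obs_scale <= 0)) {
    stop("`obs_scale` must be ", input_dim, " positive divisors")
  }
  bal_dim <- 2L * as.integer(input_dim)
  shapes <- list(input = c(hidden_dim, bal_dim),
                 recurrent = c(hidden_dim, hidden_dim),
                 readout = c(output_dim, hidden_dim))
  gains <- list(input = gain_scale[1L] / sqrt(bal_dim),
                recurrent = gain_scale[2L] / sqrt(hidden_dim),
                readout = gain_scale[3L] / sqrt(hidden_dim))
  layers <- lapply(stats::setNames(nm = names(shapes)), function(nm) {
    sh <- shapes[[nm]]
    probs <- release_probs(sh, init = 0.5, clip_eps = clip_eps,
                           jitter = init_jitter,
                           seed = derive_seed(seed %||% 0, 424243,
                                              match(nm, names(shapes))))
    ei_layer(sh[2L], sh[1L], gain = gains[[nm]], probs = probs)
  })
  trainable <- if (reservoir) c("input", "readout") else
    c("input", "recurrent", "readout")
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dim = as.integer(hidden_dim),
                 output_dim = as.integer(output_dim),
                 reservoir = reservoir, layers = layers,
                 trainable = trainable, lif = lif,
                 readout_decay = readout_decay,
                 obs_scale = as.numeric(obs_scale)),
            class = "rsnn_spec")
}

#' @export
print.rsnn_spec <- function(x, ...) {
  cat(sprintf(
    "recurrent spiking network: %d -> (balanced %d) -> %d LIF -> %d%s\n",
    x$input_dim, 2L * x$input_dim, x$hidden_dim, x$output_dim,
    if (x$reservoir) " [frozen reservoir]" else ""))
  invisible(x)
}

# Weight matrices for every layer of an rsnn_spec; samples NULL -> expected.
rsnn_weights <- function(spec, samples = NULL) {
  lapply(stats::setNames(nm = names(spec$layers)), function(nm) {
    layer_weights(spec$layers[[nm]],
                  if (is.null(samples)) NULL else samples[[nm]])
  })
}

# Draw one release sample per layer.
rsnn_sample <- function(spec, seed = NULL) {
  with_seed(seed, {
    lapply(spec$layers, function(l) sample_release(l$probs, 1L)[[1L]])
  })
}

#' Roll a recurrent spiking network over a sequence of observations
#'
#' Reference (single-sample) rollout: one set of release samples is drawn
#' per episode and held fixed across all timesteps. Per environment step the
#' observation is balanced, injected as current together with the recurrent
#' drive from the previous step's spikes (excitatory spikes positive,
#' inhibitory negated), the hidden LIF layer advances one step, and a
#' non-spiking leaky integrator accumulates the readout.
#'
#' @param spec an [rsnn_spec()].
#' @param episode_inputs `T x input_dim` matrix of observations (rows =
#'   timesteps).
#' @param samples named list of release samples (input/recurrent/readout),
#'   e.g. from `sample_release` on each layer; `NULL` uses expected weights.
#' @param weights optional precomputed weight list overriding `samples`.
#' @return list with `readout` (`T x output_dim` matrix) and `actions`
#'   (argmax per step, 0-based).
#' @export
rsnn_rollout <- function(spec, episode_inputs, samples = NULL,
                         weights = NULL) {
  w <- weights %||% rsnn_weights(spec, samples)
  episode_inputs <- as.matrix(episode_inputs)
  if (ncol(episode_inputs) != spec$input_dim) {
    stop("episode inputs must have ", spec$input_dim, " columns")
  }
  n_steps <- nrow(episode_inputs)
  st <- lif_init(spec$hidden_dim)
  y <- numeric(spec$output_dim)
  readout <- matrix(0, n_steps, spec$output_dim)
  actions <- integer(n_steps)
  for (t in seq_len(n_steps)) {
    u <- balanced_input(episode_inputs[t, ] / spec$obs_scale)
    s_signed <- ei_sign_flip(st$spikes)
    current <- as.numeric(w$input %*% u) + as.numeric(w$recurrent %*% s_signed)
    st <- lif_step(spec$lif, st, current)
    y <- spec$readout_decay * y +
      as.numeric(w$readout %*% ei_sign_flip(st$spikes))
    readout[t, ] <- y
    actions[t] <- which.max(y) - 1L
  }
  list(readout = readout, actions = actions)
}

#' Stateful policy closure from a spiking network
#'
#' Wraps an [rsnn_spec()] and a fixed set of weights into a
#' `policy(observation) -> action` closure holding LIF and readout state
#' across calls, for use with [run_episode()]. Call `attr(policy, "reset")()`
#' between episodes.
#'
#' @param spec an [rsnn_spec()].
#' @param samples release samples for the episode, or `NULL` for expected
#'   weights (deterministic evaluation).
#' @param weights optional precomputed weight list.
#' @return a policy function; actions are 0-based (argmax of the readout).
#' @export
rsnn_policy <- function(spec, samples = NULL, weights = NULL) {
  w <- weights %||% rsnn_weights(spec, samples)
  st <- lif_init(spec$hidden_dim)
  y <- numeric(spec$output_dim)
  policy <- function(observation) {
    u <- balanced_input(observation / spec$obs_scale)
    current <- as.numeric(w$input %*% u) +
      as.numeric(w$recurrent %*% ei_sign_flip(st$spikes))
    st <<- lif_step(spec$lif, st, current)
    y <<- spec$readout_decay * y +
      as.numeric(w$readout %*% ei_sign_flip(st$spikes))
    which.max(y) - 1L
  }
  attr(policy, "reset") <- function() {
    st <<- lif_init(spec$hidden_dim)
    y <<- numeric(spec$output_dim)
  }
  policy
}
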