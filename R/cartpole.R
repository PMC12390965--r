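# Classic cart-pole balancing task, bundled so reinforcement-learning code
# and tests need no external simulator. Standard constants and semi-implicit
# Euler discretization (position updated with the old velocity).

cartpole_constants <- function() {
  list(gravity = 9.8, mass_cart = 1.0, mass_pole = 0.1, half_length = 0.5,
       force_mag = 10.0, dt = 0.02, x_limit = 2.4,
       theta_limit = 12 * pi / 180, max_steps = 500L)
}

#' Cart-pole environment
#'
#' A cart on a frictionless track balancing an inverted pole. State is
#' `(x, x_dot, theta, theta_dot)`; actions are discrete pushes of +-10 N
#' (`0` = push left, `1` = push right). Each step yields reward +1; the
#' episode terminates when `|x| > 2.4` m, `|theta| > 12` degrees (strict
#' comparisons) or after 500 steps, so the episodic return equals the number
#' of steps survived and is capped at 500.
#'
#' @param max_steps episode step cap (default 500).
#' @return an environment object with methods `reset(seed)` (returns the
#'   observation), `step(action)` (returns `list(observation, reward, done,
#'   info)`), and `state()`; this reset/step contract also admits external
#'   simulators in [run_episode()].
#' @export
cartpole_env <- function(max_steps = 500L) {
  k <- cartpole_constants()
  k$max_steps <- as.integer(max_steps)
  state <- NULL
  steps <- 0L
  done <- TRUE

  reset <- function(seed = NULL) {
    state <<- with_seed(seed, stats::runif(4, -0.05, 0.05))
    steps <<- 0L
    done <<- FALSE
    state
  }

  step <- function(action) {
    if (done) stop("cannot step a terminated episode; call reset() first")
    action <- normalize_cartpole_action(action)
    state <<- cartpole_dynamics(state, action, k)
    steps <<- steps + 1L
    done <<- abs(state[1L]) > k$x_limit || abs(state[3L]) > k$theta_limit ||
      steps >= k$max_steps
    list(observation = state, reward = 1.0, done = done,
         info = list(steps = steps))
  }

  structure(list(reset = reset, step = step,
                 state = function() list(x = state[1L], x_dot = state[2L],
                                         theta = state[3L],
                                         theta_dot = state[4L],
                                         steps = steps, done = done),
                 constants = k),
            class = "cartpole_env")
}

normalize_cartpole_action <- function(action) {
  if (is.character(action)) {
    action <- match(match.arg(action, c("push_left", "push_right", "left",
                                        "right")),
                    c("push_left", "push_right", "left", "right"))
    action <- (action - 1L) %% 2L
  }
  if (!action %in% c(0, 1)) stop("cart-pole action must be 0 (left) or 1 (right)")
  as.integer(action)
}

# One Euler step of the standard cart-pole equations of motion.
cartpole_dynamics <- function(state, action, k = cartpole_constants()) {
  x <- state[1L]; x_dot <- state[2L]; theta <- state[3L]; theta_dot <- state[4L]
  force <- if (action == 1L) k$force_mag else -k$force_mag
  total_mass <- k$mass_cart + k$mass_pole
  pml <- k$mass_pole * k$half_length
  cth <- cos(theta); sth <- sin(theta)
  temp <- (force + pml * theta_dot^2 * sth) / total_mass
  theta_acc <- (k$gravity * sth - cth * temp) /
    (k$half_length * (4 / 3 - k$mass_pole * cth^2 / total_mass))
  x_acc <- temp - pml * theta_acc * cth / total_mass
  # position updated with the old velocity, then velocities with accelerations
  c(x + k$dt * x_dot,
    x_dot + k$dt * x_acc,
    theta + k$dt * theta_dot,
    theta_dot + k$dt * theta_acc)
}

#' Run one episode of an environment under a policy
#'
#' Generic rollout for any environment satisfying the reset/step contract of
#' [cartpole_env()]: `reset(seed)` returns an observation and `step(action)`
#' returns `list(observation, reward, done, ...)`. If the policy carries a
#' `"reset"` attribute (as [rsnn_policy()] does) it is invoked first.
#'
#' @param env environment object.
#' @param policy function mapping an observation to an action.
#' @param max_steps hard cap on steps for this rollout.
#' @param seed environment reset seed.
#' @return an `episode_result`: list with `total_return` and `length`.
#' @export
run_episode <- function(env, policy, max_steps = 500L, seed = NULL) {
  reset_policy <- attr(policy, "reset")
  if (is.function(reset_policy)) reset_policy()
  obs <- env$reset(seed)
  total <- 0
  len <- 0L
  while (len < max_steps) {
    out <- env$step(policy(obs))
    total <- total + out$reward
    len <- len + 1L
    if (isTRUE(out$done)) break
    obs <- out$observation
  }
  structure(list(total_return = total, length = len),
            class = "episode_result")
}

#' Default observation scaling for the cart-pole spiking policy
#'
#' Per-channel divisors `(x, x_dot, theta, theta_dot)` applied before the
#' balanced input encoding. The pole angle is divided by 0.1 rad (about half
#' its termination bound) and the angular velocity by 0.3 rad/s, so the
#' variables that must be regulated fastest dominate the input currents and
#' drive spiking from the first steps of an episode; cart position and
#' velocity stay in raw units as slower drift feedback. In raw units the
#' cart position (range +-2.4 m) would swamp the far more informative pole
#' angle (range +-0.21 rad).
#'
#' @return numeric vector of length 4.
#' @export
cartpole_obs_scale <- function() {
  c(1, 1, 0.1, 0.3)
}
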