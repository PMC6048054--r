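## DDPG actor-critic agents.
##
## An agent couples a deterministic policy mu(s | theta_mu) with an
## action-value critic Q(a, s | theta_Q).  The critic is regressed onto the
## bootstrapped Bellman target y = r + gamma * Q'(s', mu'(s')) computed with
## slowly tracking target copies of both networks; the actor ascends the
## deterministic policy gradient obtained by chaining dQ/da through the actor.

#' Specification of a dense two-hidden-layer network
#'
#' Both the actor and the critic use exactly two ReLU hidden layers.  Actor
#' outputs are squashed to `[-bound, bound]` with a scaled `tanh`; critic
#' outputs are linear.
#'
#' @param input_dim Positive integer, input dimension.
#' @param hidden_dims Integer vector of length 2, hidden layer widths.
#' @param output_dim Positive integer, output dimension.
#' @param squash `"none"` (critic) or `"bounded"` (actor).
#' @param bound Positive scalar, half-width of the bounded output range.
#' @return An object of class `mlp_spec`.
#' @export
mlp_spec <- function(input_dim, hidden_dims = c(400L, 300L), output_dim = 1L,
                     squash = c("none", "bounded"), bound = 1) {
  squash <- match.arg(squash)
  if (length(hidden_dims) != 2L)
    stop("hidden_dims must name exactly two hidden layers")
  if (any(c(input_dim, hidden_dims, output_dim) < 1))
    stop("all layer sizes must be positive integers")
  if (bound <= 0) stop("bound must be positive")
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dims = as.integer(hidden_dims),
                 output_dim = as.integer(output_dim),
                 squash = squash, bound = bound),
            class = "mlp_spec")
}

#' Create a DDPG agent
#'
#' Constructs an actor-critic pair with target copies initialised equal to the
#' live networks, Adam optimiser state, an internal Ornstein-Uhlenbeck
#' exploration process and a FIFO replay buffer.  Hidden layers use ReLU
#' units; final layers are initialised with small uniform weights (magnitude
#' at most `3e-3`) so initial actions and values are near zero.
#'
#' @param state_dim,action_dim Dimensions of the state and action vectors.
#' @param hidden Widths of the two hidden layers.
#' @param a_max Action bound: actions live in `[-a_max, a_max]`.
#' @param gamma Discount factor in `[0, 1]` (0 gives the myopic limit).
#' @param tau Polyak coefficient in `[0, 1]` for the target-network
#'   exponential moving average.
#' @param lr Adam learning rate, shared by actor and critic.
#' @param buffer_capacity Replay buffer capacity (FIFO eviction when full).
#' @param batch_size Minibatch size for gradient updates.
#' @param ou_theta,ou_sigma,ou_dt Ornstein-Uhlenbeck mean-reversion rate,
#'   diffusion scale and step size.  `ou_sigma` is interpreted in action
#'   units, i.e. it is not rescaled by `a_max`.
#' @param actor_weight_decay Decoupled (AdamW-style) weight decay applied to
#'   the actor after each update.  A small value keeps the policy near zero
#'   output wherever the policy gradient gives no persistent direction,
#'   which counteracts saturation drift of the bounded actor head.
#' @param eps_uniform While exploring, probability per step of replacing the
#'   noise-perturbed action with a uniform draw from the full action range.
#'   Keeps the replay buffer covering both action extremes after the policy
#'   has committed to one of them; set to 0 for pure
#'   Ornstein-Uhlenbeck exploration.
#' @return An object of class `ddpg_agent`.
#' @export
ddpg_agent <- function(state_dim, action_dim = 1L, hidden = c(400L, 300L),
                       a_max = 1, gamma = 0.99, tau = 0.001, lr = 1e-4,
                       buffer_capacity = 1e5, batch_size = 32L,
                       ou_theta = 0.15, ou_sigma = 0.2 * a_max, ou_dt = 1,
                       eps_uniform = 0.1, actor_weight_decay = 0) {
  if (length(hidden) != 2L) stop("hidden must give exactly two layer widths")
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  if (tau < 0 || tau > 1) stop("tau must lie in [0, 1]")
  if (lr <= 0) stop("lr must be positive")
  if (a_max <= 0) stop("a_max must be positive")
  if (ou_theta <= 0 || ou_sigma < 0 || ou_dt <= 0)
    stop("OU parameters must be positive (sigma may be zero)")
  ptr <- cpp_agent_new(as.integer(state_dim), as.integer(action_dim),
                       as.integer(hidden[1]), as.integer(hidden[2]),
                       a_max, gamma, tau, lr,
                       as.integer(buffer_capacity), as.integer(batch_size),
                       ou_theta, ou_sigma, ou_dt, eps_uniform,
                       actor_weight_decay)
  structure(list(ptr = ptr,
                 state_dim = as.integer(state_dim),
                 action_dim = as.integer(action_dim),
                 hidden = as.integer(hidden), a_max = a_max,
                 gamma = gamma, tau = tau, lr = lr,
                 buffer_capacity = as.integer(buffer_capacity),
                 batch_size = as.integer(batch_size),
                 ou_theta = ou_theta, ou_sigma = ou_sigma, ou_dt = ou_dt,
                 eps_uniform = eps_uniform,
                 actor_weight_decay = actor_weight_decay),
            class = "ddpg_agent")
}

#' @export
print.ddpg_agent <- function(x, ...) {
  cat(sprintf(
    "<ddpg_agent> state_dim=%d action_dim=%d hidden=%d/%d a_max=%g\n",
    x$state_dim, x$action_dim, x$hidden[1], x$hidden[2], x$a_max))
  cat(sprintf("  gamma=%g tau=%g lr=%g batch=%d buffer=%d (filled: %d)\n",
              x$gamma, x$tau, x$lr, x$batch_size, x$buffer_capacity,
              buffer_size(x)))
  invisible(x)
}

#' Select an action with the deterministic policy
#'
#' Returns `mu(state)`; with `explore = TRUE`, Ornstein-Uhlenbeck noise is
#' added and the result clipped to the action bounds.
#'
#' @param agent A [ddpg_agent()].
#' @param state Numeric state vector of length `state_dim`.
#' @param explore Add exploration noise?
#' @return Numeric action vector of length `action_dim`.
#' @export
select_action <- function(agent, state, explore = FALSE) {
  if (length(state) != agent$state_dim)
    stop("state dimension mismatch: expected ", agent$state_dim,
         ", got ", length(state))
  as.numeric(cpp_agent_act(agent$ptr, as.numeric(state), isTRUE(explore)))
}

#' Store a transition in the agent's replay buffer
#'
#' @param agent A [ddpg_agent()].
#' @param state,action,reward,next_state,terminal Components of the
#'   `(s_t, a_t, r_t, s_{t+1})` 4-tuple plus an end-of-episode flag.
#' @export
remember <- function(agent, state, action, reward, next_state,
                     terminal = FALSE) {
  cpp_agent_push(agent$ptr, as.numeric(state), as.numeric(action),
                 as.numeric(reward), as.numeric(next_state),
                 as.numeric(isTRUE(terminal) || (is.numeric(terminal) && terminal != 0)))
  invisible(agent)
}

#' Number of transitions currently stored
#' @param agent A [ddpg_agent()].
#' @export
buffer_size <- function(agent) cpp_agent_buffer_size(agent$ptr)

#' Sample a uniform minibatch from the agent's replay buffer
#'
#' @param agent A [ddpg_agent()].
#' @param n Batch size; sampling is uniform without replacement within the
#'   batch.
#' @return A list with matrices `S`, `A`, `S2` (rows are transitions) and
#'   vectors `R`, `D`.
#' @export
buffer_sample <- function(agent, n = agent$batch_size) {
  cpp_agent_sample(agent$ptr, as.integer(n))
}

as_batch <- function(agent, batch) {
  stopifnot(is.list(batch))
  S <- as.matrix(batch$S); S2 <- as.matrix(batch$S2)
  A <- as.matrix(batch$A)
  if (nrow(S) == 0) stop("batch is empty")
  list(S = S, A = A, R = as.numeric(batch$R), S2 = S2,
       D = as.numeric(batch$D))
}

#' Bellman targets for a batch of transitions
#'
#' Computes `y = r + gamma * Q'(s', mu'(s'))` with the target networks; the
#' bootstrap term is dropped for terminal transitions.
#'
#' @param agent A [ddpg_agent()].
#' @param batch A transition batch as returned by [buffer_sample()].
#' @return Numeric vector of targets.
#' @export
td_target <- function(agent, batch) {
  b <- as_batch(agent, batch)
  as.numeric(cpp_agent_td_target(agent$ptr, b$S2, b$R, b$D))
}

#' One critic update
#'
#' Performs a single Adam step on the critic along the gradient of the mean
#' squared TD error, with the targets held constant.
#'
#' @inheritParams td_target
#' @return The pre-update TD loss.
#' @export
critic_update <- function(agent, batch = NULL) {
  if (is.null(batch)) batch <- buffer_sample(agent)
  b <- as_batch(agent, batch)
  cpp_agent_critic_update(agent$ptr, b$S, b$A, b$R, b$S2, b$D)
}

#' One actor update
#'
#' Performs a single Adam ascent step on the actor along the sampled
#' deterministic policy gradient, with the critic parameters frozen.
#'
#' @inheritParams td_target
#' @return Mean `Q(s, mu(s))` over the batch before the update.
#' @export
actor_update <- function(agent, batch = NULL) {
  if (is.null(batch)) batch <- buffer_sample(agent)
  b <- as_batch(agent, batch)
  cpp_agent_actor_update(agent$ptr, b$S)
}

#' Polyak update of the target networks
#'
#' Every target parameter is moved as `p_t <- tau * p_live + (1 - tau) * p_t`.
#'
#' @param agent A [ddpg_agent()].
#' @export
polyak_update <- function(agent) {
  cpp_agent_polyak(agent$ptr)
  invisible(agent)
}

#' One full DDPG learning step
#'
#' Samples a minibatch internally, then runs one critic update, one actor
#' update and one Polyak update.  A no-op while the buffer holds fewer than
#' `batch_size` transitions.
#'
#' @param agent A [ddpg_agent()].
#' @return Invisibly, `c(critic_loss, mean_q)` (NA before the buffer fills).
#' @export
agent_train_step <- function(agent) {
  invisible(as.numeric(cpp_agent_train_step(agent$ptr)))
}

#' Reset the agent's exploration-noise state to zero
#' @param agent A [ddpg_agent()].
#' @export
reset_noise <- function(agent) {
  cpp_agent_reset_noise(agent$ptr)
  invisible(agent)
}

#' Adjust exploration intensity
#'
#' Sets the Ornstein-Uhlenbeck diffusion scale and the uniform-action
#' mixture probability; used to anneal exploration over training.
#'
#' @param agent A [ddpg_agent()].
#' @param sigma New OU diffusion scale.
#' @param eps_uniform New uniform-action probability.
#' @export
set_exploration <- function(agent, sigma, eps_uniform = agent$eps_uniform) {
  cpp_agent_set_exploration(agent$ptr, sigma, eps_uniform)
  invisible(agent)
}

.net_codes <- c(actor = 0L, critic = 1L, target_actor = 2L, target_critic = 3L)

#' Get or set flat network parameters
#'
#' Parameters are flattened in the order `W1, b1, W2, b2, W3, b3`
#' (column-major).  Useful for checkpointing and for finite-difference
#' verification of the analytic gradients.
#'
#' @param agent A [ddpg_agent()].
#' @param which One of `"actor"`, `"critic"`, `"target_actor"`,
#'   `"target_critic"`.
#' @return `agent_params` returns a numeric vector.
#' @export
agent_params <- function(agent, which = "actor") {
  code <- .net_codes[[match.arg(which, names(.net_codes))]]
  as.numeric(cpp_agent_get_params(agent$ptr, code))
}

#' @rdname agent_params
#' @param value Numeric replacement vector of matching length.
#' @export
agent_set_params <- function(agent, which = "actor", value) {
  code <- .net_codes[[match.arg(which, names(.net_codes))]]
  cpp_agent_set_params(agent$ptr, code, as.numeric(value))
  invisible(agent)
}

#' TD loss and policy objective without updating parameters
#'
#' `critic_loss()` evaluates the mean squared TD error of the live critic
#' against frozen Bellman targets; `actor_objective()` evaluates
#' `mean_s Q(s, mu(s))`.  `critic_grad()` and `actor_grad()` return the
#' corresponding analytic flat gradients.  These are the hooks used by the
#' finite-difference gradient checks.
#'
#' @inheritParams td_target
#' @export
critic_loss <- function(agent, batch) {
  b <- as_batch(agent, batch)
  cpp_agent_critic_loss(agent$ptr, b$S, b$A, b$R, b$S2, b$D)
}

#' @rdname critic_loss
#' @export
actor_objective <- function(agent, batch) {
  b <- as_batch(agent, batch)
  cpp_agent_actor_objective(agent$ptr, b$S)
}

#' @rdname critic_loss
#' @param state,action Matrices (rows are samples) at which to evaluate the
#'   critic.
#' @export
critic_value <- function(agent, state, action) {
  as.numeric(cpp_agent_critic_value(agent$ptr, rbind(state), rbind(action)))
}

#' @rdname critic_loss
#' @export
critic_grad <- function(agent, batch) {
  b <- as_batch(agent, batch)
  as.numeric(cpp_agent_critic_grad(agent$ptr, b$S, b$A, b$R, b$S2, b$D))
}

#' @rdname critic_loss
#' @export
actor_grad <- function(agent, batch) {
  b <- as_batch(agent, batch)
  as.numeric(cpp_agent_actor_grad(agent$ptr, b$S))
}

#' Save / load an agent checkpoint
#'
#' Parameters of all four networks are written as flat arrays (CSV) together
#' with a JSON manifest holding shapes and hyperparameters.  Optimiser and
#' exploration-noise state are not persisted.
#'
#' @param agent A [ddpg_agent()].
#' @param dir Directory to write to / read from (created if missing).
#' @export
save_agent <- function(agent, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (w in names(.net_codes)) {
    utils::write.csv(data.frame(value = agent_params(agent, w)),
                     file.path(dir, paste0(w, ".csv")), row.names = FALSE)
  }
  manifest <- agent[setdiff(names(agent), "ptr")]
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_agent
#' @export
load_agent <- function(dir) {
  m <- jsonlite::read_json(file.path(dir, "manifest.json"),
                           simplifyVector = TRUE)
  agent <- ddpg_agent(state_dim = m$state_dim, action_dim = m$action_dim,
                      hidden = m$hidden, a_max = m$a_max, gamma = m$gamma,
                      tau = m$tau, lr = m$lr,
                      buffer_capacity = m$buffer_capacity,
                      batch_size = m$batch_size, ou_theta = m$ou_theta,
                      ou_sigma = m$ou_sigma, ou_dt = m$ou_dt,
                      eps_uniform = m$eps_uniform,
                      actor_weight_decay = m$actor_weight_decay %||% 0)
  for (w in names(.net_codes)) {
    v <- utils::read.csv(file.path(dir, paste0(w, ".csv")))$value
    agent_set_params(agent, w, v)
  }
  agent
}
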