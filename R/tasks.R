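## Control environments.
##
## The three tasks expose a uniform interface to the DDPG engine:
##   task_reset(task)          -> matrix of per-agent state vectors
##   task_step(task, actions)  -> list(states, rewards, done, info)
## Tasks are mutable environment objects; one row of `states` per agent.

#' Spike-match reward
#'
#' +1 for a correctly induced spike, -1 for any mismatch, 0 for correct
#' silence.
#'
#' @param s_next Induced spike indicator(s) at t + 1 (0/1).
#' @param h_next Target spike indicator(s) at t + 1 (0/1).
#' @return Reward(s) in \{-1, 0, 1\}.
#' @export
spike_reward <- function(s_next, h_next) {
  if (!all(s_next %in% c(0, 1)) || !all(h_next %in% c(0, 1)))
    stop("spike_reward requires binary inputs")
  ifelse(s_next == h_next, ifelse(s_next == 1, 1, 0), -1)
}

#' Half-circle phase reward
#'
#' +1 when the target and controlled phases fall in the same half of the
#' unit circle ([0, pi) or [pi, 2*pi), half-open), -1 otherwise.  The
#' underlying distance is 0 within the correct half and infinite otherwise,
#' so the numeric epsilon of the thresholded form is irrelevant.
#'
#' @param phi_targ,phi_ctrl Phases (wrapped internally to [0, 2*pi)).
#' @return Reward(s) in \{-1, 1\}.
#' @export
phase_reward <- function(phi_targ, phi_ctrl) {
  same <- (wrap_phase(phi_targ) < pi) == (wrap_phase(phi_ctrl) < pi)
  ifelse(same, 1, -1)
}

#' Shaped synchronization reward
#'
#' `r_i = (q + eps * q'_i - eta * ||a_i||_1) / (2 + eps)`: global order
#' parameter, entrainment with the reference oscillator, and an action-norm
#' regulariser.  The regulariser is applied as a penalty (its stated purpose
#' is to discourage large actions); `literal_eta = TRUE` restores the
#' literal printed form with a positive sign.
#'
#' @param q Global order parameter in [0, 1].
#' @param q_ref Per-oscillator synchronization with the reference, in [0, 1].
#' @param a Per-oscillator action (scalar per agent; the L1 norm is taken).
#' @param eps,eta Shaping weights in [0, 1].
#' @param literal_eta Use the literal positive action-norm term?
#' @return Reward(s).
#' @export
sync_reward <- function(q, q_ref, a, eps = 0.1, eta = 1.0,
                        literal_eta = FALSE) {
  if (eps < 0 || eps > 1 || eta < 0 || eta > 1)
    stop("eps and eta must lie in [0, 1]")
  sgn <- if (isTRUE(literal_eta)) 1 else -1
  (q + eps * q_ref + sgn * eta * abs(a)) / (2 + eps)
}

#' Raster accuracy
#'
#' Fraction of (cell, timestep) entries where the induced raster matches the
#' target spike trains.
#'
#' @param raster,targets Binary matrices of equal shape.
#' @return Accuracy in [0, 1].
#' @export
accuracy <- function(raster, targets) {
  raster <- as.matrix(raster); targets <- as.matrix(targets)
  if (!all(dim(raster) == dim(targets))) stop("shape mismatch")
  mean(raster == targets)
}

#' @export
task_reset <- function(task, ...) UseMethod("task_reset")

#' Reset / advance a control task
#'
#' `task_reset()` reinitialises the underlying simulator (SLIF cells at the
#' resting potential with fresh targets; Kuramoto phases redrawn uniformly
#' with zeroed control accumulators) and returns the initial per-agent
#' states.  `task_step()` injects one action per agent, advances the
#' simulator one step and returns the next states, per-agent rewards, a
#' `done` flag and task-specific metrics in `info`.
#'
#' @param task A task object created by [spike_train_task()],
#'   [latent_task()] or [sync_task()].
#' @param actions Numeric vector, one action per agent.
#' @param ... Unused.
#' @return See description.
#' @name task_interface
NULL

#' @rdname task_interface
#' @export
task_step <- function(task, actions, ...) UseMethod("task_step")

#' Number of agents attached to a task
#' @param task A task object.
#' @export
n_agents <- function(task) task$n_agents

#' State dimension seen by each agent
#' @param task A task object.
#' @export
state_dim <- function(task) task$state_dim

# ---------------------------------------------------------------------------
# Fully-actuated spike-train induction
# ---------------------------------------------------------------------------

#' Fully-actuated spike-train induction task
#'
#' One DDPG agent per cell injects a scalar current to reproduce an
#' arbitrary Poisson-drawn target spike train.  Each agent sees its own
#' cell's recent spike history concatenated with a lookahead into its target
#' train; rewards follow [spike_reward()] per cell.
#'
#' @param network A directed [slif_network()].
#' @param episode_len Episode length in timesteps.
#' @param history_len,lookahead_len State window lengths (defaults 10 + 10).
#' @param target_rate Per-step target spike probability (Bernoulli
#'   approximation of a low-rate Poisson train).
#' @param a_max Injected-current bound.
#' @return A task environment (class `spike_train_task`).
#' @export
spike_train_task <- function(network, episode_len = 100L, history_len = 10L,
                             lookahead_len = 10L, target_rate = 0.15,
                             a_max = 300) {
  task <- new.env(parent = emptyenv())
  task$network <- network
  task$episode_len <- as.integer(episode_len)
  task$history_len <- as.integer(history_len)
  task$lookahead_len <- as.integer(lookahead_len)
  task$target_rate <- target_rate
  task$a_max <- a_max
  task$n_agents <- network$n_cells
  task$state_dim <- task$history_len + task$lookahead_len
  class(task) <- c("spike_train_task", "nc_task", "environment")
  task
}

.spike_states <- function(task) {
  n <- task$n_agents
  look <- task$targets[, (task$t + 1):(task$t + task$lookahead_len),
                       drop = FALSE]
  cbind(task$hist, look)
}

#' @export
task_reset.spike_train_task <- function(task, ...) {
  n <- task$network$n_cells
  task$state <- slif_state(task$network)
  task$targets <- matrix(
    stats::rbinom(n * (task$episode_len + task$lookahead_len), 1,
                  task$target_rate),
    n, task$episode_len + task$lookahead_len)
  task$hist <- matrix(0, n, task$history_len)
  task$raster <- matrix(0L, n, task$episode_len)
  task$t <- 0L
  .spike_states(task)
}

#' @export
task_step.spike_train_task <- function(task, actions, ...) {
  if (length(actions) != task$n_agents)
    stop("expected one action per cell (", task$n_agents, ")")
  u <- pmin(pmax(as.numeric(actions), -task$a_max), task$a_max)
  task$state <- slif_step(task$network, task$state, u)
  task$t <- task$t + 1L
  s <- task$state$spiked
  task$raster[, task$t] <- s
  rewards <- spike_reward(s, task$targets[, task$t])
  task$hist <- cbind(task$hist[, -1, drop = FALSE], s, deparse.level = 0)
  done <- task$t >= task$episode_len
  list(states = .spike_states(task), rewards = as.numeric(rewards),
       done = done, info = list(spiked = s, t = task$t))
}

# ---------------------------------------------------------------------------
# Under-actuated latent-trajectory induction
# ---------------------------------------------------------------------------

# common input used to excite the network while collecting the PCA
# calibration raster: a random telegraph current (bursts) per actuated cell
.telegraph_input <- function(steps, p_switch = 0.1, level = 100) {
  on <- logical(steps)
  cur <- FALSE
  for (t in seq_len(steps)) {
    if (stats::runif(1) < p_switch) cur <- !cur
    on[t] <- cur
  }
  ifelse(on, level, 0)
}

#' Calibration raster for latent-phase fitting
#'
#' Rolls out the SLIF network under random excitation and records the spike
#' raster used to fit the principal components.  `mode = "actuated"` drives
#' only the actuated cells with independent random telegraph currents (the
#' realisable stimulation protocol); `mode = "block_poisson"` delivers an
#' independent Poisson burst train to every cell of each community (a
#' common-drive protocol that exposes the community structure to PCA).
#'
#' @param network A block-topology [slif_network()].
#' @param steps Calibration length in timesteps.
#' @param actuated Indices of actuated cells (one per community), used by
#'   `mode = "actuated"`.
#' @param mode Excitation protocol, see above.
#' @param level Input current amplitude.
#' @param rate Poisson burst rate per step for `mode = "block_poisson"`.
#' @return Binary cells-by-time raster.
#' @export
calibration_raster <- function(network, steps = 1500L, actuated = NULL,
                               mode = c("actuated", "block_poisson"),
                               level = 100, rate = 0.05) {
  mode <- match.arg(mode)
  n <- network$n_cells
  state <- slif_state(network)
  raster <- matrix(0L, n, steps)
  if (mode == "actuated") {
    stopifnot(!is.null(actuated))
    drive <- matrix(0, n, steps)
    for (c in actuated) drive[c, ] <- .telegraph_input(steps, level = level)
  } else {
    comms <- unique(network$communities)
    drive <- matrix(0, n, steps)
    for (cm in comms) {
      events <- stats::rbinom(steps, 1, rate)
      burst <- stats::filter(events, rep(1, 3), sides = 1)
      burst[is.na(burst)] <- 0
      drive[network$communities == cm, ] <-
        matrix(level * pmin(as.numeric(burst), 1), sum(network$communities == cm),
               steps, byrow = TRUE)
    }
  }
  for (t in seq_len(steps)) {
    state <- slif_step(network, state, drive[, t])
    raster[, t] <- state$spiked
  }
  raster
}

#' Under-actuated latent-trajectory induction task
#'
#' One randomly chosen cell per community is actuated by its own DDPG agent;
#' the goal is to trace a target oscillation in the phase space spanned by
#' the first `pc_dim` principal components of the population activity.  At
#' construction a calibration run with random telegraph stimulation is
#' performed and the principal components are fitted and frozen; during
#' control the instantaneous projection is converted to a phase
#' ([estimate_phase()]) and compared against the target schedule with the
#' half-circle reward ([phase_reward()], shared across agents).  Each
#' agent's state is its cell's spike history concatenated with a lookahead
#' of Bernoulli samples drawn at a rate proportional to the target
#' principal-component amplitude (rescaled to `[0, r_max]`).
#'
#' @param network A block-topology [slif_network()].
#' @param pc_dim Latent dimension (1 or 2); must not exceed the number of
#'   communities.
#' @param period Target oscillation period in timesteps.
#' @param episode_len Episode length in timesteps.
#' @param history_len,lookahead_len State window lengths.
#' @param r_max Peak lookahead sampling rate.
#' @param a_max Injected-current bound.
#' @param smoothing_window Moving-average width for rate estimation.
#' @param calibration_steps Length of the calibration run.
#' @return A task environment (class `latent_task`).
#' @export
latent_task <- function(network, pc_dim = 1L, period = if (pc_dim == 1) 40L else 60L,
                        episode_len = 100L, history_len = 10L,
                        lookahead_len = 10L, r_max = 1, a_max = 300,
                        smoothing_window = 5L, calibration_steps = 1500L) {
  pc_dim <- as.integer(pc_dim)
  k <- length(unique(network$communities))
  if (pc_dim > k) stop("pc_dim must not exceed the number of communities")
  task <- new.env(parent = emptyenv())
  task$network <- network
  task$pc_dim <- pc_dim
  task$period <- as.integer(period)
  task$lag <- max(1L, as.integer(round(period / 4)))
  task$episode_len <- as.integer(episode_len)
  task$history_len <- as.integer(history_len)
  task$lookahead_len <- as.integer(lookahead_len)
  task$r_max <- r_max
  task$a_max <- a_max
  task$smoothing_window <- as.integer(smoothing_window)
  # the trailing moving average delays the underlying rate phase by
  # (w - 1) / 2 steps; the online estimator compensates for this known bias
  task$phase_lead <- 2 * pi * ((smoothing_window - 1) / 2) / period
  task$n_agents <- k
  task$state_dim <- task$history_len + task$lookahead_len
  task$actuated <- vapply(seq_len(k), function(cm) {
    cand <- which(network$communities == cm)
    if (length(cand) == 1) cand else sample(cand, 1)
  }, integer(1))
  raster <- calibration_raster(network, calibration_steps,
                               actuated = task$actuated, mode = "actuated",
                               level = a_max)
  task$pc_model <- fit_pca(raster, k = pc_dim,
                           smoothing_window = smoothing_window)
  class(task) <- c("latent_task", "nc_task", "environment")
  task
}

.latent_states <- function(task) {
  look <- task$bits[, (task$t + 1):(task$t + task$lookahead_len),
                    drop = FALSE]
  cbind(task$hist, look)
}

#' @export
task_reset.latent_task <- function(task, ...) {
  n <- task$network$n_cells
  Ttot <- task$episode_len + task$lookahead_len
  task$state <- slif_state(task$network)
  task$schedule <- target_schedule(task$pc_dim, task$period, Ttot)
  # per-community target amplitude in [-1, 1] -> lookahead sampling rate
  amp <- if (task$pc_dim == 2L) task$schedule$curve
         else matrix(cos(task$schedule$phase), ncol = 1)
  rate <- task$r_max * (amp + 1) / 2
  ridx <- pmin(seq_len(task$n_agents), task$pc_dim)
  probm <- t(rate[, ridx, drop = FALSE])   # agents x time
  task$bits <- matrix(stats::rbinom(length(probm), 1, probm),
                      nrow(probm), ncol(probm))
  task$hist <- matrix(0, task$n_agents, task$history_len)
  task$window <- matrix(0, n, task$smoothing_window)
  task$raster <- matrix(0L, n, task$episode_len)
  task$traj <- matrix(NA_real_, task$episode_len, task$pc_dim)
  task$phase <- numeric(task$episode_len)
  task$prev_phase <- 0
  task$t <- 0L
  .latent_states(task)
}

#' @export
task_step.latent_task <- function(task, actions, ...) {
  if (length(actions) != task$n_agents)
    stop("expected one action per community (", task$n_agents, ")")
  u <- numeric(task$network$n_cells)
  u[task$actuated] <- pmin(pmax(as.numeric(actions), -task$a_max), task$a_max)
  task$state <- slif_step(task$network, task$state, u)
  task$t <- task$t + 1L
  s <- task$state$spiked
  task$raster[, task$t] <- s
  task$window <- cbind(task$window[, -1, drop = FALSE], s, deparse.level = 0)
  proj <- project(task$pc_model, task$window)
  task$traj[task$t, ] <- proj
  # instantaneous controlled phase
  if (task$pc_dim == 2L) {
    mag <- sqrt(sum(proj^2))
    phi <- if (mag > 1e-12) wrap_phase(atan2(proj[2], proj[1]) + task$phase_lead)
           else task$prev_phase
  } else {
    tl <- task$t - task$lag
    xl <- if (tl >= 1) task$traj[tl, 1] else NA_real_
    mag <- if (is.na(xl)) 0 else sqrt(proj[1]^2 + xl^2)
    phi <- if (mag > 1e-12) wrap_phase(atan2(xl, proj[1]) + task$phase_lead)
           else task$prev_phase
  }
  task$prev_phase <- phi
  task$phase[task$t] <- phi
  r <- phase_reward(task$schedule$phase[task$t], phi)
  task$hist <- cbind(task$hist[, -1, drop = FALSE],
                     s[task$actuated], deparse.level = 0)
  done <- task$t >= task$episode_len
  list(states = .latent_states(task),
       rewards = rep(as.numeric(r), task$n_agents), done = done,
       info = list(phase = phi, target_phase = task$schedule$phase[task$t],
                   projection = proj, t = task$t))
}

# ---------------------------------------------------------------------------
# Kuramoto synchronization below the critical coupling
# ---------------------------------------------------------------------------

#' Kuramoto synchronization task
#'
#' One DDPG agent per non-reference oscillator applies a bounded phase
#' increment each step.  All agents observe the same state: the flattened
#' phase history of all oscillators over `history_len` steps (scaled by
#' 1 / (2*pi)) concatenated with the flattened adjacency matrix.  Rewards
#' follow [sync_reward()], computed on the post-step phases; the reference
#' oscillator is chosen uniformly at random once at task construction and
#' receives zero control.
#'
#' @param network A [km_network()].
#' @param episode_len Episode length in timesteps.
#' @param history_len Phase-history window (steps).
#' @param eps,eta Reward shaping weights.
#' @param a_max Bound on the per-step control increment (radians).
#' @param literal_eta Use the literal positive action-norm reward term?
#' @param reference Index of the reference oscillator (default: drawn at
#'   random).
#' @return A task environment (class `sync_task`).
#' @export
sync_task <- function(network, episode_len = 500L, history_len = 40L,
                      eps = 0.1, eta = 1.0, a_max = 0.5,
                      literal_eta = FALSE, reference = NULL) {
  task <- new.env(parent = emptyenv())
  task$network <- network
  task$episode_len <- as.integer(episode_len)
  task$history_len <- as.integer(history_len)
  task$eps <- eps
  task$eta <- eta
  task$a_max <- a_max
  task$literal_eta <- isTRUE(literal_eta)
  task$reference <- if (is.null(reference)) sample.int(network$n_osc, 1)
                    else as.integer(reference)
  task$controlled <- setdiff(seq_len(network$n_osc), task$reference)
  task$n_agents <- network$n_osc - 1L
  task$state_dim <- task$history_len * network$n_osc + network$n_osc^2
  task$adj_flat <- as.numeric(network$adjacency)
  class(task) <- c("sync_task", "nc_task", "environment")
  task
}

.sync_shared_state <- function(task) {
  c(as.numeric(task$hist) / (2 * pi), task$adj_flat)
}

.sync_states <- function(task) {
  shared <- .sync_shared_state(task)
  matrix(shared, task$n_agents, length(shared), byrow = TRUE)
}

#' @export
task_reset.sync_task <- function(task, ...) {
  task$state <- km_state(task$network)
  task$hist <- matrix(0, task$network$n_osc, task$history_len)
  task$hist[, task$history_len] <- task$state$phi
  task$t <- 0L
  .sync_states(task)
}

#' @export
task_step.sync_task <- function(task, actions, ...) {
  if (length(actions) != task$n_agents)
    stop("expected one action per controlled oscillator (", task$n_agents, ")")
  a <- numeric(task$network$n_osc)
  a[task$controlled] <- pmin(pmax(as.numeric(actions), -task$a_max),
                             task$a_max)
  task$state <- km_step(task$network, task$state, a)
  task$t <- task$t + 1L
  phi <- task$state$phi
  op <- order_parameter(phi)
  q_ref <- reference_sync(phi[task$controlled], phi[task$reference])
  rewards <- sync_reward(op$q, q_ref, a[task$controlled], task$eps, task$eta,
                         task$literal_eta)
  task$hist <- cbind(task$hist[, -1, drop = FALSE], phi, deparse.level = 0)
  done <- task$t >= task$episode_len
  list(states = .sync_states(task), rewards = as.numeric(rewards),
       done = done,
       info = list(q = op$q, psi = op$psi, q_ref = q_ref, phi = phi,
                   t = task$t))
}
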