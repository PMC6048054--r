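## Experiment drivers: configuration handling, the training loop, evaluation
## protocol, uncontrolled baselines, logging and test fixtures.

.task_names <- c("spike_train", "latent_1d", "latent_2d", "kuramoto_sync")

.config_defaults <- function(task, preset) {
  common <- list(gamma = 0.99, tau = 0.001, batch_size = 32L,
                 ou_theta = 0.15, ou_sigma_scale = 0.2, eps_uniform = 0.1,
                 actor_weight_decay = 0,
                 explore_decay = TRUE, explore_floor = 0.05,
                 explore_groups = 1L, n_restarts = 1L,
                 update_every = 1L, updates_per_step = 1L,
                 warmup_updates_per_step = NULL, warmup_frac = 0.4,
                 eval_every = 10L, eval_episodes = 1L,
                 baseline_episodes = 10L, buffer_capacity = 1e5)
  per <- switch(task,
    spike_train = list(
      n_cells = if (preset == "paper") 20L else 5L,
      hidden = if (preset == "paper") c(400L, 300L) else c(64L, 64L),
      lr = if (preset == "paper") 0.01 else 0.001,
      tau = if (preset == "paper") 0.001 else 0.01,
      updates_per_step = 1L,
      actor_weight_decay = if (preset == "paper") 0 else 3,
      eval_episodes = 3L, episodes = 500L, episode_len = 100L, a_max = 500,
      target_rate = 0.15, history_len = 10L, lookahead_len = 10L),
    latent_1d = list(
      n_cells = 4L, n_communities = 1L,
      hidden = if (preset == "paper") c(400L, 300L) else c(64L, 64L),
      lr = if (preset == "paper") 0.01 else 0.001,
      tau = if (preset == "paper") 0.001 else 0.01,
      updates_per_step = if (preset == "paper") 1L else 3L,
      actor_weight_decay = 0,
      n_restarts = if (preset == "paper") 1L else 3L,
      eps_uniform = if (preset == "paper") 0.1 else 0.2,
      explore_floor = if (preset == "paper") 0.05 else 0.2,
      eval_episodes = 3L, episodes = 300L, episode_len = 120L, a_max = 500,
      period = 40L, r_max = if (preset == "paper") 0.5 else 1, history_len = 10L, lookahead_len = 10L,
      smoothing_window = 5L, calibration_steps = 1500L, pc_dim = 1L),
    latent_2d = list(
      n_cells = if (preset == "paper") 32L else 8L, n_communities = 2L,
      hidden = if (preset == "paper") c(400L, 300L) else c(64L, 64L),
      lr = if (preset == "paper") 0.01 else 0.001,
      tau = if (preset == "paper") 0.001 else 0.01,
      updates_per_step = if (preset == "paper") 1L else 3L,
      actor_weight_decay = 0,
      eval_episodes = 3L, episodes = if (preset == "paper") 300L else 100L,
      episode_len = 120L, a_max = 500, period = 60L, r_max = 0.5,
      history_len = 10L, lookahead_len = 10L, smoothing_window = 5L,
      calibration_steps = 1500L, pc_dim = 2L),
    kuramoto_sync = list(
      n_osc = if (preset == "paper") 20L else 10L,
      hidden = if (preset == "paper") c(1200L, 1000L) else c(64L, 64L),
      lr = if (preset == "paper") 1e-4 else 1e-3,
      tau = if (preset == "paper") 0.001 else 0.01,
      gamma = if (preset == "paper") 0.99 else 0.9,
      episodes = 300L,
      episode_len = if (preset == "paper") 500L else 150L,
      update_every = if (preset == "paper") 1L else 6L,
      buffer_capacity = if (preset == "paper") 1e5 else 2e4,
      K = 0.1, omega_sd = 10,
      km_dt = if (preset == "paper") 0.01 else 0.002,
      actor_weight_decay = if (preset == "paper") 0 else 0.1,
      eps = 0.1, eta = 1.0,
      a_max = 0.5, history_len = 40L, literal_eta = FALSE,
      eval_episodes = 2L),
    stop("unknown task: ", task))
  utils::modifyList(common, per)
}

#' Experiment configuration
#'
#' Resolves a full parameter set for one of the four studies.  Every field
#' defaults to the published setting where one is stated (20 SLIF cells and
#' 500 episodes fully actuated; 4 cells for the 1-D and 32 for the 2-D
#' latent task; 20 oscillators with K = 0.1, eps = 0.1, eta = 1.0; batch 32,
#' gamma = 0.99, tau = 0.001; learning rates 0.01 for SLIF control and 1e-4
#' for Kuramoto control; hidden sizes 400/300 for SLIF and 1200/1000 for
#' Kuramoto).  The `"desk"` preset scales system size, hidden widths and
#' episode lengths down so the full pipeline runs in minutes on one CPU.
#'
#' @param task One of `"spike_train"`, `"latent_1d"`, `"latent_2d"`,
#'   `"kuramoto_sync"`.
#' @param preset `"desk"` (reduced scale, default) or `"paper"`.
#' @param seed Integer seed for all randomness (required for
#'   reproducibility; logged with results).
#' @param out_dir Optional output directory for CSV/JSON logs.
#' @param ... Named overrides of any default field.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(task = .task_names, preset = c("desk", "paper"),
                              seed = 1L, out_dir = NULL, ...) {
  task <- match.arg(task)
  preset <- match.arg(preset)
  cfg <- .config_defaults(task, preset)
  dots <- list(...)
  unknown <- setdiff(names(dots), c(names(cfg), "seed", "out_dir"))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(cfg, dots)
  cfg$task <- task
  cfg$preset <- preset
  cfg$seed <- as.integer(seed)
  cfg$out_dir <- out_dir
  if (cfg$gamma <= 0 || cfg$gamma > 1) stop("gamma must lie in (0, 1]")
  if (cfg$episodes < 0) stop("episodes must be non-negative")
  structure(cfg, class = "experiment_config")
}

#' Read a configuration echoed to JSON
#' @param path Path to a `config.json` written by [run_experiment()].
#' @return An `experiment_config`.
#' @export
config_from_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- cfg[!grepl("^\\.", names(cfg))]
  cfg <- cfg[!vapply(cfg, function(x) is.list(x) && length(x) == 0, logical(1))]
  do.call(experiment_config,
          c(list(task = cfg$task, preset = cfg$preset, seed = cfg$seed,
                 out_dir = cfg$out_dir),
            cfg[setdiff(names(cfg), c("task", "preset", "seed", "out_dir"))]))
}

# build the simulator + task environment described by a config
.build_task <- function(cfg) {
  switch(cfg$task,
    spike_train = {
      net <- slif_network(cfg$n_cells, "directed")
      spike_train_task(net, episode_len = cfg$episode_len,
                       history_len = cfg$history_len,
                       lookahead_len = cfg$lookahead_len,
                       target_rate = cfg$target_rate, a_max = cfg$a_max)
    },
    latent_1d = ,
    latent_2d = {
      net <- slif_network(cfg$n_cells, "block",
                          n_communities = cfg$n_communities)
      latent_task(net, pc_dim = cfg$pc_dim, period = cfg$period,
                  episode_len = cfg$episode_len,
                  history_len = cfg$history_len,
                  lookahead_len = cfg$lookahead_len, r_max = cfg$r_max,
                  a_max = cfg$a_max, smoothing_window = cfg$smoothing_window,
                  calibration_steps = cfg$calibration_steps)
    },
    kuramoto_sync = {
      net <- km_network(cfg$n_osc, K = cfg$K, omega_sd = cfg$omega_sd,
                        dt = cfg$km_dt)
      sync_task(net, episode_len = cfg$episode_len,
                history_len = cfg$history_len, eps = cfg$eps, eta = cfg$eta,
                a_max = cfg$a_max, literal_eta = cfg$literal_eta)
    })
}

.build_agents <- function(cfg, task) {
  lapply(seq_len(n_agents(task)), function(i)
    ddpg_agent(state_dim = state_dim(task), action_dim = 1L,
               hidden = cfg$hidden, a_max = cfg$a_max, gamma = cfg$gamma,
               tau = cfg$tau, lr = cfg$lr,
               buffer_capacity = cfg$buffer_capacity,
               batch_size = cfg$batch_size, ou_theta = cfg$ou_theta,
               ou_sigma = cfg$ou_sigma_scale * cfg$a_max, ou_dt = 1,
               eps_uniform = cfg$eps_uniform,
               actor_weight_decay = cfg$actor_weight_decay))
}

# roll out one episode; optionally explore, store transitions and learn
.rollout <- function(task, agents, cfg, explore = FALSE, learn = FALSE,
                     zero_actions = FALSE, explore_mask = NULL) {
  if (is.null(cfg$.ups)) cfg$.ups <- cfg$updates_per_step
  nA <- n_agents(task)
  ptrs <- lapply(agents, `[[`, "ptr")
  states <- task_reset(task)
  if (is.null(explore_mask)) explore_mask <- rep(explore, nA)
  if (any(explore_mask)) for (p in ptrs) cpp_agent_reset_noise(p)
  total_r <- 0; steps <- 0L
  q_sum <- 0; qref_sum <- 0; qref_all <- NULL
  collect_qref <- inherits(task, "sync_task")
  if (collect_qref) qref_all <- numeric(0)
  repeat {
    acts <- if (zero_actions) numeric(nA)
            else vapply(seq_len(nA), function(i)
              cpp_agent_act(ptrs[[i]], states[i, ], explore_mask[i])[1],
              numeric(1))
    out <- task_step(task, acts)
    steps <- steps + 1L
    total_r <- total_r + mean(out$rewards)
    if (collect_qref) {
      q_sum <- q_sum + out$info$q
      qref_sum <- qref_sum + mean(out$info$q_ref)
      qref_all <- c(qref_all, out$info$q_ref)
    }
    if (learn) {
      for (i in seq_len(nA))
        cpp_agent_push(ptrs[[i]], states[i, ], acts[i], out$rewards[i],
                       out$states[i, ], as.numeric(out$done))
      if (steps %% cfg$update_every == 0L)
        for (k in seq_len(cfg$.ups))
          for (p in ptrs) cpp_agent_train_step(p)
    }
    states <- out$states
    if (out$done) break
  }
  metric <- metric2 <- NA_real_
  agent_metric <- NULL
  if (inherits(task, "spike_train_task")) {
    tg <- task$targets[, seq_len(task$episode_len), drop = FALSE]
    metric <- accuracy(task$raster, tg)
    agent_metric <- rowMeans(task$raster == tg)
  } else if (inherits(task, "latent_task")) {
    keep <- seq_len(task$episode_len) > task$period
    metric <- mean(task$phase[keep] %/% pi == task$schedule$phase[keep] %/% pi)
  } else if (collect_qref) {
    metric <- q_sum / steps
    metric2 <- qref_sum / steps
  }
  if (is.null(agent_metric)) agent_metric <- rep(metric, nA)
  list(mean_reward = total_r / steps, metric = metric, metric2 = metric2,
       agent_metric = agent_metric, qref = qref_all)
}

#' Run a training experiment
#'
#' Builds the configured system and one DDPG agent per actuator, then runs
#' training episodes with Ornstein-Uhlenbeck exploration and learning
#' updates, interleaved with periodic evaluation episodes with exploration
#' disabled.  Deterministic given `cfg$seed`.  For the synchronization task
#' the per-oscillator reference-synchronization values are also collected
#' before and after training, and a zero-action baseline is measured on the
#' same network.
#'
#' @param cfg An [experiment_config()].
#' @param quiet Suppress progress messages?
#' @return A `run_summary` list: per-episode mean training reward, the
#'   evaluation metric trajectory (`accuracy` for SLIF tasks, time-averaged
#'   `q` for synchronization), `final_metric`, pre/post reference-sync
#'   samples and baseline statistics where applicable, the resolved config
#'   and the seed.
#' @export
run_experiment <- function(cfg, quiet = TRUE) {
  stopifnot(inherits(cfg, "experiment_config"))
  t0 <- Sys.time()
  set.seed(cfg$seed)
  task <- .build_task(cfg)
  agents <- .build_agents(cfg, task)
  is_sync <- inherits(task, "sync_task")

  baseline_metric <- NA_real_
  if (is_sync && cfg$baseline_episodes > 0) {
    base <- vapply(seq_len(cfg$baseline_episodes), function(i)
      .rollout(task, agents, cfg, zero_actions = TRUE)$metric, numeric(1))
    baseline_metric <- mean(base)
  }
  pre <- .rollout(task, agents, cfg, explore = FALSE)
  pre_qref <- pre$qref
  pre_metric <- pre$metric

  episode_reward <- numeric(0)
  eval_at <- integer(0); eval_metric <- numeric(0); eval_metric2 <- numeric(0)
  nA <- n_agents(task)
  best_agent_metric <- rep(-Inf, nA)
  best_actor <- vector("list", nA)
  sigma0 <- cfg$ou_sigma_scale * cfg$a_max
  ups_warm <- if (is.null(cfg$warmup_updates_per_step)) cfg$updates_per_step
              else cfg$warmup_updates_per_step
  ep_done <- 0L
  for (round in seq_len(max(1L, cfg$n_restarts))) {
    # each restart round trains an independent initialisation; the best
    # evaluated policy across rounds is kept
    if (round > 1L) agents <- .build_agents(cfg, task)
    for (ep in seq_len(cfg$episodes)) {
      cfg$.ups <- if (ep <= cfg$warmup_frac * cfg$episodes) ups_warm
                  else cfg$updates_per_step
      if (isTRUE(cfg$explore_decay)) {
        # linear annealing of the OU noise towards a small floor
        f <- max(cfg$explore_floor, 1 - (ep - 1) / max(1, cfg$episodes - 1))
        for (ag in agents)
          cpp_agent_set_exploration(ag$ptr, f * sigma0, cfg$eps_uniform)
      }
      mask <- rep(TRUE, nA)
      if (!is.null(cfg$explore_groups) && cfg$explore_groups > 1L) {
        # rotate exploration among agent subsets so that the shared reward
        # terms are not swamped by everyone's noise at once
        g <- cfg$explore_groups
        mask <- (seq_len(nA) - 1L) %% g == (ep - 1L) %% g
      }
      tr <- .rollout(task, agents, cfg, explore = TRUE, learn = TRUE,
                     explore_mask = mask)
      ep_done <- ep_done + 1L
      episode_reward[ep_done] <- tr$mean_reward
      if (ep %% cfg$eval_every == 0L || ep == cfg$episodes) {
        ev <- lapply(seq_len(cfg$eval_episodes), function(i)
          .rollout(task, agents, cfg, explore = FALSE))
        m <- mean(vapply(ev, `[[`, numeric(1), "metric"))
        m2 <- mean(vapply(ev, `[[`, numeric(1), "metric2"))
        am <- rowMeans(matrix(vapply(ev, `[[`, numeric(nA), "agent_metric"),
                             nrow = nA))
        for (i in which(am > best_agent_metric)) {
          best_agent_metric[i] <- am[i]
          best_actor[[i]] <- agent_params(agents[[i]], "actor")
        }
        eval_at <- c(eval_at, ep_done)
        eval_metric <- c(eval_metric, m)
        eval_metric2 <- c(eval_metric2, m2)
        if (!quiet)
          message(sprintf("episode %d: reward %.3f, metric %.3f", ep_done,
                          tr$mean_reward, m))
      }
    }
  }
  # restore the best-evaluating actors and measure them afresh
  for (i in seq_len(nA)) if (!is.null(best_actor[[i]])) {
    agent_set_params(agents[[i]], "actor", best_actor[[i]])
    agent_set_params(agents[[i]], "target_actor", best_actor[[i]])
  }
  fin <- lapply(seq_len(max(1L, cfg$eval_episodes)), function(i)
    .rollout(task, agents, cfg, explore = FALSE))
  post <- fin[[1]]
  post_qref <- unlist(lapply(fin, `[[`, "qref"))
  final_metric <- mean(vapply(fin, `[[`, numeric(1), "metric"))

  summary <- structure(list(
    task = cfg$task, seed = cfg$seed, config = unclass(cfg),
    episode_reward = episode_reward, eval_at = eval_at,
    eval_metric = eval_metric, eval_metric2 = eval_metric2,
    final_metric = final_metric, final_eval = post$metric,
    pre_metric = pre_metric, best_eval_metric = best_agent_metric,
    baseline_metric = baseline_metric,
    pre_qref = pre_qref, post_qref = post_qref,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "run_summary")

  if (!is.null(cfg$out_dir)) .write_run_outputs(summary, task, cfg)
  summary
}

.write_run_outputs <- function(summary, task, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  keep <- setdiff(names(cfg), c("out_dir", grep("^\\.", names(cfg), value = TRUE)))
  keep <- keep[!vapply(unclass(cfg)[keep], is.null, logical(1))]
  jsonlite::write_json(unclass(cfg)[keep],
                       file.path(cfg$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(episode = seq_along(summary$episode_reward),
                              mean_reward = summary$episode_reward),
                   file.path(cfg$out_dir, "train_log.csv"), row.names = FALSE)
  utils::write.csv(data.frame(episode = summary$eval_at,
                              metric = summary$eval_metric,
                              metric2 = summary$eval_metric2),
                   file.path(cfg$out_dir, "eval_log.csv"), row.names = FALSE)
  if (inherits(task, "spike_train_task") || inherits(task, "latent_task"))
    write_raster_csv(task$raster, file.path(cfg$out_dir, "final_raster.csv"))
  if (inherits(task, "sync_task") && length(summary$post_qref))
    utils::write.csv(data.frame(q_ref = summary$post_qref),
                     file.path(cfg$out_dir, "post_qref.csv"),
                     row.names = FALSE)
  jsonlite::write_json(
    list(task = summary$task, seed = summary$seed,
         final_metric = summary$final_metric,
         baseline_metric = summary$baseline_metric,
         elapsed_sec = summary$elapsed_sec),
    file.path(cfg$out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Uncontrolled baseline rollouts
#'
#' Rolls the configured task out with zero actions and reports the
#' per-episode task metric (time-averaged order parameter for the
#' synchronization task, raster accuracy for the spike-train task).
#'
#' @param cfg An [experiment_config()].
#' @return A list with per-episode `metric` values and their mean.
#' @export
baseline_uncontrolled <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  set.seed(cfg$seed)
  task <- .build_task(cfg)
  agents <- list()
  metrics <- vapply(seq_len(max(1L, cfg$baseline_episodes)), function(i)
    .rollout(task, agents, cfg, zero_actions = TRUE)$metric, numeric(1))
  list(metric = metrics, mean_metric = mean(metrics), task = cfg$task,
       seed = cfg$seed)
}

#' Write small deterministic fixtures for the test suite
#'
#' `kind = "slif"`: a directed SLIF network and a noise-driven raster;
#' `kind = "kuramoto"`: an uncontrolled phase trajectory;
#' `kind = "latent"`: a two-block network (no cross edges) with a
#' common-drive calibration raster and the true community labels.
#'
#' @param kind Fixture family.
#' @param size Number of cells / oscillators.
#' @param seed Integer seed (fixtures are byte-identical for equal seeds).
#' @param dir Output directory.
#' @return Character vector of written file paths.
#' @export
make_fixture <- function(kind = c("slif", "kuramoto", "latent"), size = NULL,
                         seed = 1L, dir = tempdir()) {
  kind <- match.arg(kind)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(as.integer(seed))
  files <- character(0)
  if (kind == "slif") {
    n <- if (is.null(size)) 3L else as.integer(size)
    net <- slif_network(n, "directed")
    st <- slif_state(net)
    raster <- matrix(0L, n, 50L)
    for (t in 1:50) {
      st <- slif_step(net, st, rep(20, n))
      raster[, t] <- st$spiked
    }
    f1 <- file.path(dir, "slif_adjacency.csv")
    utils::write.csv(as.data.frame(net$adjacency), f1, row.names = FALSE)
    f2 <- file.path(dir, "slif_raster.csv")
    write_raster_csv(raster, f2)
    files <- c(f1, f2)
  } else if (kind == "kuramoto") {
    n <- if (is.null(size)) 4L else as.integer(size)
    net <- km_network(n, K = 0.1)
    st <- km_state(net)
    tr <- matrix(0, n, 100L)
    for (t in 1:100) {
      st <- km_step(net, st)
      tr[, t] <- st$phi
    }
    f1 <- file.path(dir, "km_phases.csv")
    write_phase_csv(tr, f1)
    files <- f1
  } else {
    n <- if (is.null(size)) 8L else as.integer(size)
    net <- slif_network(n, "block", n_communities = 2L, p_cross = 0)
    raster <- calibration_raster(net, steps = 400L, mode = "block_poisson")
    f1 <- file.path(dir, "latent_raster.csv")
    utils::write.csv(as.data.frame(raster), f1, row.names = FALSE)
    f2 <- file.path(dir, "latent_communities.csv")
    utils::write.csv(data.frame(cell_id = seq_len(n),
                                community = net$communities),
                     f2, row.names = FALSE)
    files <- c(f1, f2)
  }
  files
}
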