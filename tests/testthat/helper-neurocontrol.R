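# Shared helpers: tiny agents, finite-difference gradients, scripted batches.

tiny_agent <- function(state_dim = 2, action_dim = 1, hidden = c(3, 3),
                       a_max = 2, ...) {
  ddpg_agent(state_dim, action_dim, hidden = hidden, a_max = a_max,
             lr = 1e-3, buffer_capacity = 100, eps_uniform = 0, ...)
}

# fill an agent's buffer with random transitions and return a sampled batch
random_batch <- function(agent, n_push = 12, n = 8, seed = 42) {
  set.seed(seed)
  for (i in seq_len(n_push))
    remember(agent, rnorm(agent$state_dim),
             runif(agent$action_dim, -agent$a_max, agent$a_max),
             rnorm(1), rnorm(agent$state_dim), i %% 4 == 0)
  buffer_sample(agent, n)
}

# central finite-difference gradient of f(params)
fd_gradient <- function(agent, which, f, h = 1e-6) {
  p <- agent_params(agent, which)
  g <- vapply(seq_along(p), function(j) {
    pp <- p
    pp[j] <- p[j] + h
    agent_set_params(agent, which, pp)
    up <- f()
    pp[j] <- p[j] - h
    agent_set_params(agent, which, pp)
    dn <- f()
    (up - dn) / (2 * h)
  }, numeric(1))
  agent_set_params(agent, which, p)
  g
}

# set every parameter of a network from a list of explicit weight matrices
# layout: W1 (in x h1), b1, W2 (h1 x h2), b2, W3 (h2 x out), b3
flat_params <- function(W1, b1, W2, b2, W3, b3) {
  c(as.numeric(W1), as.numeric(b1), as.numeric(W2), as.numeric(b2),
    as.numeric(W3), as.numeric(b3))
}

# critic with Q(s, a) = -|a - centre| built from two ReLU units; the critic
# consumes actions scaled by 1 / a_max internally, handled here
v_shape_critic <- function(agent, centre = 3) {
  sdim <- agent$state_dim
  h1 <- agent$hidden[1]; h2 <- agent$hidden[2]
  W1 <- matrix(0, sdim + 1, h1)
  W1[sdim + 1, 1] <- agent$a_max     # undo the internal action scaling
  W1[sdim + 1, 2] <- -agent$a_max
  b1 <- numeric(h1); b1[1] <- -centre; b1[2] <- centre
  W2 <- matrix(0, h1, h2); W2[1, 1] <- 1; W2[2, 2] <- 1
  W3 <- matrix(0, h2, 1); W3[1, 1] <- -1; W3[2, 1] <- -1
  agent_set_params(agent, "critic",
                   flat_params(W1, b1, W2, numeric(h2), W3, 0))
  agent_set_params(agent, "target_critic",
                   flat_params(W1, b1, W2, numeric(h2), W3, 0))
  agent
}

# deterministic SLIF network with chosen adjacency and noise-free params
quiet_slif <- function(A, eta = 0, ...) {
  n <- nrow(A)
  net <- slif_network(n, "directed", params = slif_params(eta = eta, ...))
  net$adjacency <- A
  net
}

bandit_ddpg <- function(centre, seed, n_updates = 2000) {
  # the full loop: explore (annealed), store, update, select best by reward
  set.seed(seed)
  a <- ddpg_agent(1, 1, hidden = c(16, 16), a_max = 5, lr = 0.01, tau = 0.1,
                  buffer_capacity = 4000, ou_sigma = 1, eps_uniform = 0.2)
  best <- -Inf; bestp <- NULL
  for (i in seq_len(n_updates)) {
    f <- max(0.02, 1 - i / 1600)
    set_exploration(a, f, f * 0.2)
    act <- select_action(a, 0, explore = TRUE)
    remember(a, 0, act, -(act - centre)^2, 0, TRUE)
    agent_train_step(a)
    if (i %% 10 == 0) {
      r <- -(select_action(a, 0) - centre)^2
      if (r > best) { best <- r; bestp <- agent_params(a, "actor") }
    }
  }
  agent_set_params(a, "actor", bestp)
  select_action(a, 0)
}

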