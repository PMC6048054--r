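# DDPG engine: policies, Bellman targets, gradient updates, target tracking.

test_that("construction invariants: targets equal live networks, shapes", {
  set.seed(1)
  a <- tiny_agent(state_dim = 3, hidden = c(5, 4))
  expect_identical(agent_params(a, "actor"), agent_params(a, "target_actor"))
  expect_identical(agent_params(a, "critic"), agent_params(a, "target_critic"))
  # final layers initialised small so initial actions are near zero
  expect_lt(abs(select_action(a, rnorm(3))), 0.05 * a$a_max)
  expect_error(ddpg_agent(2, hidden = c(10, 10, 10)), "two layer")
  expect_error(ddpg_agent(2, gamma = 1.5), "gamma")
  expect_error(ddpg_agent(2, lr = 0), "lr")
})

test_that("select_action is deterministic and respects the noise path", {
  set.seed(2)
  a <- tiny_agent(state_dim = 4)
  s <- rnorm(4)
  expect_identical(select_action(a, s), select_action(a, s))
  # sigma = 0, x = 0: exploration adds an identically-zero noise path
  az <- ddpg_agent(4, hidden = c(3, 3), a_max = 2, ou_sigma = 0,
                   eps_uniform = 0)
  expect_equal(select_action(az, s, explore = TRUE),
               select_action(az, s, explore = FALSE))
  expect_error(select_action(a, rnorm(3)), "dimension")
})

test_that("td_target implements the Bellman bootstrap with terminal cut", {
  set.seed(3)
  a <- ddpg_agent(1, 1, hidden = c(1, 1), a_max = 1, gamma = 0.99,
                  buffer_capacity = 10)
  # target critic == constant 2: all weights/biases zero except output bias
  agent_set_params(a, "target_critic", flat_params(
    matrix(0, 2, 1), 0, matrix(0, 1, 1), 0, matrix(0, 1, 1), 2))
  batch <- list(S = matrix(0), A = matrix(0), R = 1, S2 = matrix(0), D = 0)
  expect_equal(td_target(a, batch), 1 + 0.99 * 2)           # 2.98
  batch$D <- 1
  batch$R <- -1
  expect_equal(td_target(a, batch), -1)                     # no bootstrap
  a0 <- ddpg_agent(1, 1, hidden = c(1, 1), a_max = 1, gamma = 0,
                   buffer_capacity = 10)
  batch$D <- 0
  batch$R <- 0.3
  expect_equal(td_target(a0, batch), 0.3)                   # myopic limit
})

test_that("critic_update: exact critic has zero loss and frozen parameters", {
  set.seed(4)
  a <- ddpg_agent(1, 1, hidden = c(2, 2), a_max = 1, buffer_capacity = 10)
  # critic == constant 0.7 everywhere
  agent_set_params(a, "critic", flat_params(
    matrix(0, 2, 2), c(0, 0), matrix(0, 2, 2), c(0, 0), matrix(0, 2, 1), 0.7))
  p0 <- agent_params(a, "critic")
  batch <- list(S = matrix(0.5), A = matrix(0.2), R = 0.7,
                S2 = matrix(0), D = 1)   # terminal: y = r = 0.7 = Q
  expect_equal(critic_update(a, batch), 0)
  expect_equal(agent_params(a, "critic"), p0)
  # mean over identical transitions equals the single-transition error
  b1 <- list(S = matrix(0.1), A = matrix(0.1), R = 1, S2 = matrix(0), D = 1)
  bn <- lapply(b1, function(x) if (is.matrix(x)) x[rep(1, 6), , drop = FALSE]
               else rep(x, 6))
  expect_equal(critic_loss(a, bn), critic_loss(a, b1))
  expect_error(critic_update(a, list(S = matrix(0, 0, 1), A = matrix(0, 0, 1),
                                     R = numeric(0), S2 = matrix(0, 0, 1),
                                     D = numeric(0))), "empty")
})

test_that("analytic gradients match central finite differences (<= 50 params)", {
  set.seed(5)
  a <- tiny_agent(state_dim = 2, hidden = c(3, 3))
  b <- random_batch(a)
  g <- critic_grad(a, b)
  fd <- fd_gradient(a, "critic", function() critic_loss(a, b))
  expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-5)
  g <- actor_grad(a, b)
  fd <- fd_gradient(a, "actor", function() actor_objective(a, b))
  expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-5)
})

test_that("actor_update climbs a V-shaped critic to its argmax", {
  set.seed(6)
  a <- ddpg_agent(1, 1, hidden = c(4, 4), a_max = 5, lr = 0.01,
                  buffer_capacity = 200, eps_uniform = 0)
  v_shape_critic(a, centre = 3)
  batch <- list(S = matrix(0, 8, 1), A = matrix(0, 8, 1), R = numeric(8),
                S2 = matrix(0, 8, 1), D = rep(1, 8))
  for (i in 1:800) actor_update(a, batch)
  expect_equal(select_action(a, 0), 3, tolerance = 0.01)
  # constant critic: zero actor gradient, parameters unchanged
  b0 <- ddpg_agent(1, 1, hidden = c(2, 2), a_max = 1, buffer_capacity = 10)
  agent_set_params(b0, "critic", flat_params(
    matrix(0, 2, 2), c(0, 0), matrix(0, 2, 2), c(0, 0), matrix(0, 2, 1), 1))
  p0 <- agent_params(b0, "actor")
  actor_update(b0, batch)
  expect_equal(agent_params(b0, "actor"), p0)
})

test_that("polyak_update: exact arithmetic and conservation", {
  set.seed(7)
  a <- tiny_agent(state_dim = 2)
  # tau = 0.001 (default-style arithmetic): p_t = 0, p_live = 1 -> 0.001
  b <- ddpg_agent(1, 1, hidden = c(1, 1), a_max = 1, tau = 0.001,
                  buffer_capacity = 10)
  np <- length(agent_params(b, "actor"))
  agent_set_params(b, "actor", rep(1, np))
  agent_set_params(b, "target_actor", rep(0, np))
  polyak_update(b)
  expect_equal(agent_params(b, "target_actor"), rep(0.001, np))
  # tau = 1: target jumps to live; tau = 0: unchanged
  b1 <- ddpg_agent(1, 1, hidden = c(1, 1), a_max = 1, tau = 1,
                   buffer_capacity = 10)
  agent_set_params(b1, "target_critic", rep(0.5, length(agent_params(b1, "critic"))))
  polyak_update(b1)
  expect_identical(agent_params(b1, "critic"), agent_params(b1, "target_critic"))
  b0 <- ddpg_agent(1, 1, hidden = c(1, 1), a_max = 1, tau = 0,
                   buffer_capacity = 10)
  t0 <- agent_params(b0, "target_critic")
  agent_set_params(b0, "critic", rnorm(length(t0)))
  polyak_update(b0)
  expect_identical(agent_params(b0, "target_critic"), t0)
  # conservation: p_t - old = tau * (p_live - old), to machine precision
  old <- agent_params(a, "target_critic")
  live <- rnorm(length(old))
  agent_set_params(a, "critic", live)
  polyak_update(a)
  expect_equal(agent_params(a, "target_critic") - old,
               a$tau * (live - old), tolerance = 1e-12)
})

test_that("full DDPG loop solves a continuous bandit (3 targets, 3 seeds)", {
  for (centre in c(-1, 0, 2)) {
    ok <- vapply(1:3, function(seed)
      abs(bandit_ddpg(centre, seed) - centre) <= 0.05, logical(1))
    expect_true(all(ok), label = paste("bandit centre", centre))
  }
})

test_that("agent checkpoints round-trip through CSV + JSON manifest", {
  set.seed(8)
  a <- tiny_agent(state_dim = 3)
  dir <- file.path(tempdir(), "agent_ckpt")
  save_agent(a, dir)
  b <- load_agent(dir)
  for (w in c("actor", "critic", "target_actor", "target_critic"))
    expect_equal(agent_params(b, w), agent_params(a, w))
  s <- rnorm(3)
  expect_equal(select_action(b, s), select_action(a, s))
})
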