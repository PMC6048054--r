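# Control environments: rewards, resets, stepping, agent wiring.

test_that("spike reward truth table matches the stated cases", {
  expect_equal(spike_reward(1, 1), 1)
  expect_equal(spike_reward(0, 1), -1)
  expect_equal(spike_reward(1, 0), -1)
  expect_equal(spike_reward(0, 0), 0)
  expect_equal(spike_reward(c(1, 0, 1, 0), c(1, 1, 0, 0)), c(1, -1, -1, 0))
  expect_error(spike_reward(0.5, 1), "binary")
})

test_that("phase reward partitions the circle into half-open halves", {
  expect_equal(phase_reward(pi / 4, pi / 2), 1)
  expect_equal(phase_reward(pi / 4, 3 * pi / 2), -1)
  expect_equal(phase_reward(pi / 2, pi), -1)   # pi belongs to the second half
  phis <- seq(0, 2 * pi - 1e-6, length.out = 25)
  expect_true(all(phase_reward(phis, phis) == 1))
  expect_true(all(phase_reward(phis, phis + pi) == -1))
})

test_that("sync reward: shaping, normalisation bound, action penalty", {
  expect_equal(sync_reward(1, 1, 0, eps = 0.1, eta = 1), 1.1 / 2.1)
  expect_equal(sync_reward(0, 0, 0), 0)
  # with zero action the reward lies in [0, (1 + eps) / (2 + eps)]
  grid <- expand.grid(q = seq(0, 1, 0.25), qr = seq(0, 1, 0.25))
  r <- sync_reward(grid$q, grid$qr, 0, eps = 0.1, eta = 1)
  expect_true(all(r >= 0 & r <= 1.1 / 2.1 + 1e-12))
  # strictly decreasing in |a| at fixed (q, q_ref); literal form increases
  aa <- seq(0, 0.5, 0.1)
  r <- sync_reward(0.5, 0.5, aa)
  expect_true(all(diff(r) < 0))
  rl <- sync_reward(0.5, 0.5, aa, literal_eta = TRUE)
  expect_true(all(diff(rl) > 0))
  expect_error(sync_reward(1, 1, 0, eps = 2), "eps")
})

test_that("accuracy counts matching raster entries", {
  r <- matrix(rbinom(200, 1, 0.2), 20, 10)
  expect_equal(accuracy(r, r), 1)
  expect_equal(accuracy(r, 1 - r), 0)
  r2 <- r
  r2[3, 7] <- 1 - r2[3, 7]
  expect_equal(accuracy(r, r2), 1 - 1 / 200)
  expect_error(accuracy(r, r[, 1:5]), "shape")
})

test_that("spike-train task: reset contract, stepping, agent isolation", {
  set.seed(41)
  net <- slif_network(4, "directed")
  task <- spike_train_task(net, episode_len = 30)
  st <- task_reset(task)
  expect_equal(dim(st), c(4, 20))
  expect_equal(st[, 1:10], matrix(0, 4, 10))                 # empty history
  expect_equal(st[, 11:20], task$targets[, 1:10])            # lookahead
  expect_true(all(task$state$V == net$params$v_rest))
  # same seed -> identical reset
  set.seed(99); s1 <- task_reset(task)
  set.seed(99); s2 <- task_reset(task)
  expect_identical(s1, s2)
  # stepping: per-cell rewards depend only on that cell's spike and target
  out <- task_step(task, c(500, 0, -100, 250))
  expect_equal(out$rewards,
               as.numeric(spike_reward(out$info$spiked, task$targets[, 1])))
  expect_false(out$done)
  expect_error(task_step(task, 1:3), "one action per cell")
  for (t in 2:30) out <- task_step(task, numeric(4))
  expect_true(out$done)
})

test_that("latent task: calibration, phase plumbing, shared reward", {
  set.seed(42)
  net <- slif_network(4, "block", n_communities = 1)
  task <- latent_task(net, pc_dim = 1, period = 40, episode_len = 50,
                      calibration_steps = 600)
  expect_equal(n_agents(task), 1)
  expect_equal(length(task$actuated), 1)
  st <- task_reset(task)
  expect_equal(dim(st), c(1, 20))
  phases <- numeric(50)
  set.seed(1)
  for (t in 1:50) {
    out <- task_step(task, runif(1, -300, 300))
    phases[t] <- out$info$phase
    expect_equal(length(out$rewards), 1)
    expect_true(out$rewards %in% c(-1, 1))
  }
  # the environment's online phase equals the batch estimator on the
  # recorded projection trajectory, shifted by the smoother-lag compensation
  idx <- (task$lag + 1):50
  expect_equal(phases[idx],
               wrap_phase(estimate_phase(task$traj[, 1], lag = task$lag)[idx] +
                          task$phase_lead),
               tolerance = 1e-12)
  expect_equal(out$done, TRUE)
})

test_that("sync task: state layout, reference isolation, reward wiring", {
  set.seed(43)
  net <- km_network(6, K = 0.1)
  task <- sync_task(net, episode_len = 25, reference = 2)
  expect_equal(n_agents(task), 5)
  expect_equal(state_dim(task), 40 * 6 + 36)
  st <- task_reset(task)
  expect_equal(dim(st), c(5, 276))
  expect_true(all(st[1, ] == st[5, ]))            # shared observation
  # newest history column carries the scaled initial phases
  expect_equal(st[1, seq(40 * 6 - 5, 40 * 6)] * 2 * pi,
               task$state$phi, tolerance = 1e-12)
  expect_equal(st[1, (40 * 6 + 1):276], as.numeric(net$adjacency))
  out <- task_step(task, rep(0.1, 5))
  # reference oscillator receives zero control
  expect_equal(task$state$phi_ctrl[2], 0)
  expect_true(all(task$state$phi_ctrl[-2] == 0.1))
  # rewards recompute from the post-step order parameters
  q <- order_parameter(task$state$phi)$q
  qr <- reference_sync(task$state$phi[-2], task$state$phi[2])
  expect_equal(out$rewards,
               as.numeric(sync_reward(q, qr, pmin(rep(0.1, 5), 0.5))))
  expect_error(task_step(task, 1:2), "one action per controlled")
})

test_that("uncontrolled sync rollouts stay far from synchrony", {
  set.seed(44)
  net <- km_network(10, K = 0.1)
  task <- sync_task(net, episode_len = 300)
  task_reset(task)
  qs <- numeric(300)
  for (t in 1:300) {
    out <- task_step(task, numeric(9))
    qs[t] <- out$info$q
  }
  expect_lt(mean(qs), 0.5)
})
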