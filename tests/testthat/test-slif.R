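# SLIF network simulator: alpha synapses, Euler-Maruyama integration,
# threshold-and-reset spiking, random network generators.

test_that("alpha conductance: zero at onset, closed-form value, peak at tau_s", {
  p <- slif_params()
  expect_equal(alpha_conductance(0, p), 0)
  expect_equal(alpha_conductance(-3, p), 0)        # future spikes contribute 0
  expect_equal(alpha_conductance(1, p), 0.01 * exp(-1))   # 0.0036788
  tt <- seq(0.01, 10, by = 0.01)
  expect_equal(tt[which.max(alpha_conductance(tt, p))], p$tau_s)
})

test_that("synaptic_current composes Eq. 8-9 over the weighted adjacency", {
  A <- matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE)   # cell 1 <- cell 2
  net <- quiet_slif(A)
  st <- slif_state(net)
  st$hist[2, 1] <- 1                                # presynaptic spike 1 step ago
  cur <- synaptic_current(net, st, 1)
  expect_equal(cur, 0.01 * exp(-1) * (70 - (-70)))  # 0.51503, depolarising
  expect_gt(cur, 0)
  # at the reversal potential the driving force vanishes
  st$V[1] <- net$params$e_syn
  expect_equal(synaptic_current(net, st, 1), 0)
  # no presynaptic spikes ever -> zero current
  st2 <- slif_state(net)
  expect_equal(synaptic_current(net, st2), c(0, 0))
})

test_that("slif_step: rest is a fixed point and the threshold current divides", {
  net <- quiet_slif(matrix(0, 1, 1))
  st <- slif_state(net)
  st2 <- slif_step(net, st, 0)
  expect_equal(st2$V, net$params$v_rest)
  expect_equal(threshold_current(net$params), 40 / 3)   # C (Vth - Vr) / tau_v
  # below the boundary: V -> -50.2, never spikes; above: spikes
  run <- function(u) {
    s <- slif_state(net)
    n_spikes <- 0
    for (t in 1:500) {
      s <- slif_step(net, s, u)
      n_spikes <- n_spikes + s$spiked
    }
    list(state = s, n_spikes = n_spikes)
  }
  lo <- run(13.2)
  expect_equal(lo$state$V, -70 + 15 * 13.2 / 10, tolerance = 1e-6)   # -50.2
  expect_equal(lo$n_spikes, 0)
  hi <- run(13.4)
  expect_gt(hi$n_spikes, 0)
  expect_error(slif_step(net, st, NaN), "finite")
})

test_that("spike-reset contract and zero-noise determinism", {
  set.seed(21)
  net <- quiet_slif(matrix(runif(25), 5, 5) * (1 - diag(5)))
  go <- function() {
    st <- slif_state(net)
    raster <- matrix(0L, 5, 60)
    for (t in 1:60) {
      st <- slif_step(net, st, runif(5, 0, 30))
      expect_true(all(st$V[st$spiked == 1] == net$params$v_rest))
      expect_true(all(st$V[st$refr == 0] < net$params$v_thresh))
      raster[, t] <- st$spiked
    }
    raster
  }
  set.seed(33); r1 <- go()
  set.seed(33); r2 <- go()
  expect_identical(r1, r2)
  expect_gt(sum(r1), 0)
})

test_that("membrane noise reaches the discrete-time stationary variance", {
  set.seed(22)
  net <- slif_network(1, "directed")   # eta = sqrt(2) default
  st <- slif_state(net)
  vs <- numeric(5e4)
  for (t in seq_along(vs)) {
    st <- slif_step(net, st, 0)
    vs[t] <- st$V
  }
  p <- net$params
  v_exact <- p$eta^2 * p$dt / (1 - (1 - p$dt / p$tau_v)^2)   # 15.52
  expect_lt(abs(var(vs) - v_exact) / v_exact, 0.1)
  expect_equal(mean(vs), p$v_rest, tolerance = 0.3)
})

test_that("synaptic currents are excitatory for subthreshold potentials", {
  set.seed(23)
  net <- quiet_slif(matrix(runif(16), 4, 4) * (1 - diag(4)))
  st <- slif_state(net)
  st$hist[, ] <- rbinom(length(st$hist), 1, 0.3)
  st$V <- runif(4, -90, net$params$v_thresh)
  expect_true(all(synaptic_current(net, st) >= 0))
})

test_that("dt refinement: alpha-synapse response matches a 10x finer oracle", {
  # downstream potential deflection after a single presynaptic spike,
  # integrated at dt = 1, against an independent Euler oracle at dt = 0.1
  A <- matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE)
  net <- quiet_slif(A)
  st <- slif_state(net)
  st$hist[2, 1] <- 1
  coarse <- numeric(12)
  for (t in 1:12) {
    st <- slif_step(net, st, 0)
    coarse[t] <- st$V[1] - (-70)
  }
  # oracle: V' = V + dt (-(V+70)/tau + g(t) (70 - V) / C), g = alpha kernel
  p <- net$params
  dt <- 0.1
  V <- -70
  fine <- numeric(12)
  for (k in 1:120) {
    tel <- k * dt            # elapsed time since the spike
    g <- alpha_conductance(tel, p)
    V <- V + dt * (-(V - p$v_rest) / p$tau_v + g * (p$e_syn - V) / p$C)
    if (k %% 10 == 0) fine[k / 10] <- V - (-70)
  }
  expect_lt(abs(max(coarse) - max(fine)) / max(fine), 0.05)
})

test_that("network generators honour their topologies", {
  set.seed(24)
  n1 <- slif_network(1)
  expect_equal(n1$adjacency, matrix(0, 1, 1))
  nd <- slif_network(20, "directed")
  off <- nd$adjacency[row(nd$adjacency) != col(nd$adjacency)]
  expect_true(all(off >= 0 & off <= 1))
  expect_equal(mean(off), 0.5, tolerance = 0.03)
  expect_true(all(diag(nd$adjacency) == 0))
  nb <- slif_network(8, "block", n_communities = 2, p_cross = 0)
  expect_true(isSymmetric(nb$adjacency))
  blocks <- outer(nb$communities, nb$communities, "==")
  expect_true(all(nb$adjacency[!blocks] == 0))
  expect_true(all(nb$adjacency[blocks & upper.tri(blocks)] > 0))
  expect_error(slif_network(4, "block", n_communities = 9), "communities")
})

test_that("raster and voltage CSV exports round-trip", {
  r <- matrix(0L, 3, 5); r[1, 2] <- 1L; r[3, 4] <- 1L
  f <- tempfile(fileext = ".csv")
  write_raster_csv(r, f)
  got <- read.csv(f)
  expect_equal(got$cell_id, c(1, 3))
  expect_equal(got$timestep, c(2, 4))
  fv <- tempfile(fileext = ".csv")
  write_voltage_csv(matrix(1:6, 2, 3), fv)
  expect_equal(nrow(read.csv(fv)), 6)
})
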