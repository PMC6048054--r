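# neurocontrol

Model-free, closed-loop control of simulated neural systems with Deep
Deterministic Policy Gradients (DDPG), for computational neuroscientists
who want to study what a learned controller can do to a spiking network or
an oscillator population without ever writing down a model of it.

The package implements, from scratch and in compiled code:

* **DDPG** — deterministic policy `mu(s|theta_mu)` and critic
  `Q(a,s|theta_Q)` (two ReLU hidden layers each), trained by Adam on the
  TD loss `E[(Q(a_t,s_t) - y_t)^2]` with Bellman targets
  `y_t = r_t + gamma * Q'(mu'(s_{t+1}), s_{t+1})` from slowly tracking
  target networks (`p_t <- tau * p + (1-tau) * p_t`), uniform experience
  replay, and Ornstein–Uhlenbeck exploration;
* a **stochastic leaky integrate-and-fire network**
  (`dV/dt = -(V - V_rest)/tau_v + (b u + sum_j A_ij I_syn,j)/C + eta e(t)`
  with alpha-conductance synapses and threshold-and-reset spiking);
* a **Kuramoto network** with additive phase control
  (`dphi_i/dt = omega_i + (K/N) sum_j A_ij sin(phi_j - phi_i) + dphi_ctrl/dt`),
  the global order parameter `q e^{i psi} = mean(e^{i phi_j})` and
  per-oscillator reference synchronization `q'_i = |cos((phi_i - phi_ref)/2)|`;
* **latent phase-space control**: PCA of smoothed spike rasters, online
  projection, quadrature phase estimation, and the half-circle phase
  reward.

Three studies are wired up as reproducible experiments: fully-actuated
spike-train induction (one agent per cell, reward +1/0/-1 for correct
spike / correct silence / mismatch), under-actuated latent-trajectory
induction (one agent per cell community), and induction of global
synchrony below the critical coupling (one agent per non-reference
oscillator, shaped reward `(q + eps q'_i - eta |a_i|)/(2 + eps)`).

## Worked example

Train the desk-scale fully-actuated spike-train controller (5 SLIF cells,
one DDPG agent per cell, 500 episodes):

```r
library(neurocontrol)
cfg <- experiment_config("spike_train", preset = "desk", seed = 1)
run <- run_experiment(cfg)
round(run$final_metric, 3)
#> [1] 0.998
round(run$pre_metric, 3)
#> [1] 0.848
```

`final_metric` is the fraction of (cell, timestep) entries of a fresh
no-exploration evaluation episode in which the induced raster matches the
Poisson-drawn target trains — 0.998 here, against 0.848 for the untrained
policy (which never spikes; targets arrive at rate 0.15). Training takes
~3 minutes on one CPU.

The same interface runs the other studies:

```r
run_experiment(experiment_config("kuramoto_sync", "desk", seed = 1))
run_experiment(experiment_config("latent_1d", "desk", seed = 1))
```

For the synchronization task the summary also carries the uncontrolled
baseline `q` on the same network and the pre/post distributions of
reference synchronization. `preset = "paper"` switches every
hyperparameter to the published full-scale settings (400/300 and
1200/1000 hidden units, 20 cells / 20 oscillators; hours of CPU).

Lower-level building blocks are exported too — `ddpg_agent()`,
`select_action()`, `remember()`, `agent_train_step()`, `slif_network()`,
`slif_step()`, `km_network()`, `km_step()`, `order_parameter()`,
`fit_pca()`, `estimate_phase()`, the task environments
(`spike_train_task()`, `latent_task()`, `sync_task()`) — see the methods
vignette (`vignettes/neurocontrol-methods.Rmd`) for the model equations,
parameter choices and their rationale.

A command-line driver is installed at `inst/cli/neurocontrol`:

```sh
Rscript inst/cli/neurocontrol run --task kuramoto_sync --preset desk \
    --seed 1 --out results/sync
Rscript inst/cli/neurocontrol baseline --task kuramoto_sync --seed 1
Rscript inst/cli/neurocontrol fixture --kind latent --seed 1 --out fixtures/
```

Runs echo their fully resolved configuration to `config.json` beside CSV
logs of per-episode rewards and evaluation metrics; re-running from the
echoed config reproduces the run exactly.

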