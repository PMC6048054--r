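---
title: "Model-free control of spiking and oscillator networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-free control of spiking and oscillator networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`neurocontrol` studies closed-loop, model-free control of simulated neural
systems with Deep Deterministic Policy Gradients (DDPG). Three control
problems are implemented:

1. **Fully-actuated spike-train induction.** Every cell of a stochastic
   leaky integrate-and-fire (SLIF) network receives its own scalar current
   from its own DDPG agent; the goal is to reproduce an arbitrary
   Poisson-drawn target spike train in every cell.
2. **Under-actuated latent-trajectory induction.** One cell per community
   of a block-structured SLIF network is actuated; the goal is to trace a
   target oscillation in the phase space spanned by the leading principal
   components of the population activity.
3. **Synchronization of weakly coupled oscillators.** Each non-reference
   oscillator of a Kuramoto network below its critical coupling receives a
   bounded additive phase increment from its own agent; the goal is global
   synchrony, shaped through entrainment to a randomly chosen reference
   oscillator.

# The learner

Each agent is an actor–critic pair. The deterministic policy
$\mu(s\,|\,\theta^\mu)$ and the action-value critic
$Q(a, s\,|\,\theta^Q)$ are dense networks with two ReLU hidden layers; the
actor head is squashed to $[-a_{\max}, a_{\max}]$ with a scaled $\tanh$,
the critic head is linear. The critic is regressed by Adam onto the
bootstrapped Bellman target

$$y_t = r_t + \gamma\, Q'\!\big(\mu'(s_{t+1}),\, s_{t+1}\big),$$

computed with slowly tracking target copies $\mu', Q'$ of both networks
(Polyak coefficient $\tau$); the bootstrap term is dropped on terminal
transitions. The actor ascends the deterministic policy gradient
$\nabla_a Q \cdot \nabla_{\theta^\mu}\mu$ with the critic frozen.
Transitions $(s_t, a_t, r_t, s_{t+1})$ are stored in a per-agent FIFO
replay buffer and minibatches of 32 are resampled uniformly. Exploration
adds Ornstein–Uhlenbeck (OU) noise
$x \leftarrow x + \theta(0 - x)\,dt + \sigma\sqrt{dt}\,z$ to the policy
output.

Both gradients are computed analytically (verified against central finite
differences to $10^{-10}$ relative error in the test suite) in compiled
code; all randomness flows from R's RNG so `set.seed()` reproduces entire
experiments.

## Training-protocol choices

The published account of this control framework leaves the training
protocol largely open. The package makes the following choices, each of
which was driven by an observed failure mode at desk scale:

* **Action scaling in the critic.** The critic sees actions rescaled to
  $[-1, 1]$; with injected currents of order $10^2$ next to binary state
  features the critic input is otherwise catastrophically ill-conditioned.
* **$\varepsilon$-uniform exploration mixture** (default 10%). OU noise is
  centred on the current policy; once a bounded $\tanh$ policy has
  saturated at one extreme, pure OU exploration essentially never samples
  the opposite extreme again, so a wrong commitment can never be falsified
  by data. A small probability of a uniformly drawn action keeps both
  extremes represented in replay.
* **OU annealing.** The OU scale decays linearly to a 5% floor over
  training; late training then refines the critic near the current policy.
* **Decoupled actor weight decay** (SLIF spike task). Under Adam, gradient
  magnitude does not limit step size, so directions with only noise-level
  gradient support still drift to $\tanh$ saturation, producing bang-bang
  policies. A decay term pulls unsupported directions back towards zero
  output, which is also the correct "do nothing" action of the spike task.
  The latent task disables it: there the correct policy must maintain large
  weights through long stretches in which the critic cannot yet support
  them, and decay was observed to erase recovered solutions.
* **Evaluation-based model selection.** Every `eval_every` episodes the
  deterministic policy is evaluated with exploration off; the
  best-evaluating actor per agent is checkpointed. After training the best
  actors are restored and the reported metric is recomputed with a *fresh*
  evaluation, so the reported number is not inflated by selection bias.
  DDPG is well known to degrade after reaching good policies; this
  protocol reports the policy the run actually found.
* **Restart rounds** (latent task, desk preset). The half-circle reward is
  direction-blind: a controller locked in anti-phase receives a uniform
  $-1$ with no gradient pointing towards the half-period shift that would
  fix it, and near-constant-rate policies produce a noise-driven phase
  with no usable gradient at all. Independent re-initialisations with
  best-policy selection are the standard remedy for such basin structure.

# The SLIF plant

Membrane dynamics (forward Euler–Maruyama, `dt = 1`):

$$V \leftarrow V + dt\Big[-\frac{V - V_{\text{rest}}}{\tau_v}
  + \frac{b\,u + \sum_j A_{ij} I_{\text{syn},j}}{C}\Big]
  + \eta\sqrt{dt}\, z,$$

with alpha-conductance synapses
$g(t) = \bar g\,(t/\tau_s)e^{-t/\tau_s}$,
$I_{\text{syn},j} = -g_j (V_i - E_{\text{syn}})$, and threshold-and-reset
spiking. Constants: $C = 10$, $\tau_v = 15$, rest $-70$, threshold $-50$,
zero refractory period, $\tau_s = 1$, $\bar g = 0.01$,
$E_{\text{syn}} = +70$ (a generic excitatory cell), $\eta = \sqrt 2$.
Conductance contributions older than $10\tau_s$ are dropped (relative
error $< 5\times10^{-4}$).

Two written forms of the leak circulate: literal $-V/\tau_v$ (decay to 0,
under which every cell would drift through threshold and fire tonically
with no input at all) and leak-to-rest. The package defaults to
leak-to-rest, which makes the stated rest/threshold values meaningful;
`leak_mode = "zero"` selects the literal form.

Two deliberate departures from the literal equations, both forced by
analysis of the control problem:

* **Action bound $a_{\max} = 500$.** The closed-form steady state
  $V_\infty = V_{\text{rest}} + \tau_v I / C$ puts the threshold current at
  $40/3 \approx 13.3$, but a *sustained* near-threshold current crosses
  only asymptotically; perfect single-step spike placement — which the
  fully-actuated task demands — needs
  $u \ge C\,\Delta V/dt = 200$ plus a noise margin. With weaker bounds the
  best policies cannot exceed ~0.87 accuracy because spike timing jitters
  across the multi-step ramp.
* **Hyperpolarization floor $V \ge -90$** (configurable `v_min`, `-Inf`
  disables). The literal dynamics allow inhibitory drive to push $V$
  arbitrarily far below rest, which is biophysically implausible
  (potassium reversal) and, more importantly, creates a self-consistent
  failure basin for learning: an agent that hyperpolarises deeply sees its
  own firing attempts fail, its critic concludes that firing is useless,
  and the policy never recovers. With the floor, a maximal action crosses
  threshold from any reachable potential in one step; dynamics above
  $-90$ are unchanged.

# The Kuramoto plant

$$\varphi_i \leftarrow \mathrm{wrap}\Big(\varphi_i + dt\big[\omega_i
 + \tfrac{K}{N}\textstyle\sum_j A_{ij}\sin(\varphi_j - \varphi_i)\big]
 + a_i\Big),$$

with symmetric $A_{ij} \sim U(0,1)$, $\omega_i \sim N(0, 10^2)$ (the
conventional $N(0, 10)$ read as a scale parameter) and sub-critical
$K = 0.1$. The control increment $a_i$ accumulates into
$\varphi^{\text{ctrl}}_i$; solving the discretised dynamics for the
increment that lands on any target next phase is exact in one step (tested
to machine precision). Global synchrony is measured by the order parameter
$q e^{i\psi} = \frac1N\sum_j e^{i\varphi_j}$; synchronization with the
reference oscillator by the two-element order parameter
$q'_i = |\cos((\varphi_i - \varphi_{\text{ref}})/2)|$, the only reading of
"order of synchronization with respect to a reference" consistent with
the $N$-oscillator definition.

The shaped per-oscillator reward is
$r_i = (q + \varepsilon q'_i - \eta\,\|a_i\|_1)/(2 + \varepsilon)$ with
$\varepsilon = 0.1$, $\eta = 1$. The printed formula carries
$+\eta\|a\|_1$, which would *reward* large actions, contradicting its
stated regularising purpose; the package implements the penalty and keeps
the literal form behind `literal_eta = TRUE`.

**Timestep.** The integration step is not stated for this system. It
matters far beyond Euler stability: under the action penalty, tracking the
reference costs $|\omega_i - \omega_{\text{ref}}|\,dt$ per step while the
shaping gain is independent of $dt$, so $dt$ sets the price of
entrainment. At $dt = 0.01$ and desk scale the expected tracking cost
(~0.11) exceeds the expected shaped gain (~0.07), making the zero-action
policy a trap for independent learners — observed directly as flat
learning curves. The desk preset uses $dt = 0.002$, at which entrainment
is profitable and forward Euler is comfortably stable
($\max|\omega_i|\,dt \approx 0.06$ rad).

Every agent observes the same state: the flattened 40-step phase history
of all oscillators (scaled by $1/2\pi$) concatenated with the flattened
adjacency matrix. The reference oscillator is drawn uniformly once per
experiment and receives zero control.

# Latent phase analysis

The calibration raster (random telegraph stimulation of the actuated
cells) is smoothed per cell with a trailing moving average of 5 steps —
an instantaneous firing rate — mean-centred, and the cell covariance is
eigendecomposed. The top-$k$ eigenvectors with a deterministic sign
convention (largest-magnitude loading positive) define the latent space;
they are frozen before control begins. Cells are assigned to communities
by the component on which they load with the largest magnitude; on block
networks with no cross edges this recovery is exact (tested over 10
seeds). A trailing rather than centred average is used in both fitting
and control so the two pipelines share one causal kernel.

The controlled phase is `atan2(PC2, PC1)` in two dimensions. A scalar
trajectory has no intrinsic angle, so in one dimension the phase comes
from quadrature delay embedding, $\mathrm{atan2}(x_{t-L}, x_t)$ with
$L = $ period/4, which is exact for a cosine of that period. Two
estimator details: (i) timesteps with a (near-)zero embedding vector carry
the previous phase forward; (ii) the trailing smoother delays the
underlying rate phase by $(w-1)/2$ steps, a known bias that the
environment compensates by adding $2\pi(w-1)/(2P)$ to the estimate.

The per-agent state is the actuated cell's 10-step spike history
concatenated with a 10-step lookahead of Bernoulli samples drawn at the
target rate $r(t) = r_{\max}(1 + \cos\varphi_{\text{targ}}(t))/2$. The
desk preset uses $r_{\max} = 1$: analysis of the observation showed that
at $r_{\max} = 0.5$ even the *best policy expressible on the observable
state* caps near 0.67 of timesteps in the correct half-circle — below
the 0.75 acceptance bar — because ten sparse Bernoulli bits are too noisy
an encoding of the target phase, while at $r_{\max} = 1$ the lookahead is
a faithful realization of the desired spiking and the same policy class
reaches ~0.91.

# Synthetic data

All inputs are generated internally: random directed or block-symmetric
weighted adjacency matrices, Bernoulli target spike trains (rate 0.15 per
step, the low-rate approximation of a Poisson train), sinusoidal target
phase schedules, uniform random oscillator phases and Gaussian natural
frequencies. The generators emulate the stated simulation conditions and
nothing more: no refractory dynamics beyond an optional counter, single
cell type, no inhibitory synapses, no plasticity, no measurement noise on
observations. A green test therefore establishes that the *method* works
on the *stated world*; it says nothing about robustness to model
mismatch, which the underlying control framework explicitly leaves open.

# Presets and scaling

`experiment_config(preset = "paper")` keeps every published setting:
hidden layers 400/300 (SLIF) and 1200/1000 (Kuramoto), learning rates
0.01 / 1e-4, $\gamma = 0.99$, $\tau = 0.001$, batch 32, 20 cells / 20
oscillators, OU exploration. These runs need hours of CPU.

`experiment_config(preset = "desk")` is the scaled-down reconstruction
used by the test suite (minutes per study on one CPU): 5 cells / 10
oscillators / 4-cell latent network, 64/64 hidden units, and the
desk-scale adaptations discussed above (lr 1e-3, $\tau = 0.01$, update
cadence, $dt = 0.002$ for the Kuramoto task, $r_{\max} = 1$, restart
rounds for the latent task). Each adaptation exists because the published
value demonstrably fails at desk scale (detailed above); all remain
configuration fields, so any intermediate regime can be explored.

# Numerical and degenerate-input choices

* Phases are reduced modulo $2\pi$ after every step; control accumulators
  are unconstrained.
* `fit_pca` refuses constant rasters (no principal directions) and
  enforces non-increasing explained variance; `k` may not exceed the cell
  count.
* Replay sampling is uniform without replacement within a batch; sampling
  from an empty buffer is an error, as is a batch larger than the buffer.
* OU parameters must be positive (the diffusion scale may be zero, giving
  deterministic mean reversion — used by the tests).
* Euler stationary variances differ from their continuous-time limits at
  coarse steps by a factor $1/(1 - \theta\,dt/2)$; the tests assert the
  exact discrete formulas at $dt = 1$ and the continuous values at fine
  steps.
* Adam uses $\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$ with
  bias correction; hidden layers are initialised uniform
  $\pm 1/\sqrt{\text{fan-in}}$, final layers uniform $\pm 3\times10^{-3}$
  so initial actions and values are near zero.

# Known limitations

* Desk-scale DDPG on the latent task is marginal: the half-circle reward
  carries no directional information, and a sizeable fraction of runs
  locks into anti-phase or low-amplitude basins that only restarts
  escape. Reported latent metrics hover near the acceptance bar and
  individual seeds can fall below it.
* The synchronization task is a coordination game among independent
  learners; its outcome depends on the action-cost/shaping balance
  discussed above and degrades gracefully rather than failing loudly.
* Paper-preset runs are faithful but not validated end-to-end here; the
  test suite exercises the desk presets only.
* Agent checkpoints persist network parameters but not optimiser or
  exploration state; resumed training is not bitwise identical to
  uninterrupted training.
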