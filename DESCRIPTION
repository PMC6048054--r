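Package: neurocontrol
Title: Model-Free Deep Reinforcement Learning Control of Spiking and
    Oscillator Networks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Closed-loop, model-free control of simulated neural systems with
    Deep Deterministic Policy Gradients (DDPG). Provides a from-scratch
    actor-critic implementation (target networks, experience replay,
    Ornstein-Uhlenbeck exploration, Adam), a stochastic leaky integrate-and-fire
    (SLIF) network simulator with alpha-function conductance synapses, a
    Kuramoto oscillator network with additive phase control, principal-component
    latent-phase estimation for under-actuated control, and reproducible
    experiment drivers for spike-train induction, latent-trajectory induction,
    and synchronization of weakly coupled oscillators below the critical
    coupling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: C++17
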