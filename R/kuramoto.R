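## Kuramoto network of weakly coupled phase oscillators with additive phase
## control:
##   phi_i <- wrap( phi_i + dt * [ omega_i + (K/N) sum_j A_ij rho(phi_j - phi_i) ]
##                  + a_i )
## where a_i is the per-step control-phase increment accumulated in phi_ctrl.

#' Wrap phases into [0, 2*pi)
#' @param x Phases (radians).
#' @export
wrap_phase <- function(x) x %% (2 * pi)

#' Generate a random Kuramoto network
#'
#' Symmetric edge weights iid U(0, 1) with zero diagonal; natural frequencies
#' iid N(0, omega_sd^2).  `omega_sd = 10` reads the conventional N(0, 10) as
#' a scale (standard deviation) parameter; pass `omega_sd = sqrt(10)` for the
#' variance reading.
#'
#' @param n_osc Number of oscillators (>= 2).
#' @param K Coupling strength.
#' @param omega_sd Standard deviation of the natural frequencies.
#' @param dt Integration timestep for the forward Euler discretisation.
#' @param rho Coupling nonlinearity (default `sin`).
#' @return An object of class `km_network` with fields `n_osc`, `K`,
#'   `adjacency`, `omega`, `dt`, `rho`.
#' @export
km_network <- function(n_osc = 20L, K = 0.1, omega_sd = 10, dt = 0.01,
                       rho = sin) {
  n <- as.integer(n_osc)
  if (n < 2) stop("n_osc must be at least 2")
  if (dt <= 0) stop("dt must be positive")
  A <- matrix(0, n, n)
  up <- upper.tri(A)
  A[up] <- stats::runif(sum(up))
  A <- A + t(A)
  omega <- stats::rnorm(n, 0, omega_sd)
  structure(list(n_osc = n, K = K, adjacency = A, omega = omega, dt = dt,
                 rho = rho),
            class = "km_network")
}

#' Initial state of a Kuramoto network
#'
#' Phases drawn uniformly at random from [0, 2*pi); control-phase
#' accumulators start at zero.
#'
#' @param network A [km_network()].
#' @return An object of class `km_state` with fields `phi`, `phi_ctrl`, `t`.
#' @export
km_state <- function(network) {
  structure(list(phi = stats::runif(network$n_osc, 0, 2 * pi),
                 phi_ctrl = rep(0, network$n_osc),
                 t = 0L),
            class = "km_state")
}

.km_drift <- function(network, phi) {
  # [i, j] = rho(phi_j - phi_i)
  D <- network$rho(outer(phi, phi, function(pi, pj) pj - pi))
  network$omega + (network$K / network$n_osc) * rowSums(network$adjacency * D)
}

#' Advance a Kuramoto network one timestep
#'
#' Forward Euler step of the coupled phase dynamics plus the additive control
#' increment `a` (the per-step change of the control phase); `a` must be zero
#' for uncontrolled oscillators.  Phases are wrapped to [0, 2*pi); the
#' control accumulators are cumulative and unconstrained.
#'
#' @param network A [km_network()].
#' @param state A [km_state()].
#' @param a Control increment vector (length `n_osc`), radians per step.
#' @return The updated `km_state`.
#' @export
km_step <- function(network, state, a = 0) {
  a <- rep_len(as.numeric(a), network$n_osc)
  if (any(!is.finite(a))) stop("non-finite control increment")
  drift <- .km_drift(network, state$phi)
  state$phi <- wrap_phase(state$phi + network$dt * drift + a)
  state$phi_ctrl <- state$phi_ctrl + a
  state$t <- state$t + 1L
  state
}

#' Control increment reproducing a target next phase
#'
#' Inverts the discretised controlled dynamics for the additive increment:
#' `a = phi_target - (phi + dt * drift)`.  Feeding the result to [km_step()]
#' lands every oscillator exactly on `wrap_phase(phi_target)` in one step.
#'
#' @param network A [km_network()].
#' @param state A [km_state()].
#' @param phi_target Desired next-phase vector.
#' @return The control increment vector.
#' @export
km_control_increment <- function(network, state, phi_target) {
  drift <- .km_drift(network, state$phi)
  as.numeric(phi_target) - (state$phi + network$dt * drift)
}

#' Global Kuramoto order parameter
#'
#' Modulus `q` and argument `psi` of the mean unit phasor
#' `q e^{i psi} = mean(e^{i phi_j})`.  `q = 1` for perfect synchrony and
#' `q = 0` for phases evenly spread on the circle.
#'
#' @param phi Non-empty phase vector.
#' @return List with elements `q` in [0, 1] and `psi` in [0, 2*pi).
#' @export
order_parameter <- function(phi) {
  if (length(phi) == 0) stop("order_parameter requires a non-empty phase vector")
  z <- mean(exp(1i * phi))
  list(q = Mod(z), psi = wrap_phase(Arg(z)))
}

#' Synchronization with a reference oscillator
#'
#' The two-element order parameter restricted to an oscillator and the
#' reference: `|cos((phi_i - phi_ref) / 2)|`, equal to 1 when in phase and 0
#' in anti-phase.
#'
#' @param phi_i Phase(s) of the oscillator(s).
#' @param phi_ref Phase of the reference oscillator.
#' @return Value(s) in [0, 1].
#' @export
reference_sync <- function(phi_i, phi_ref) {
  abs(cos((phi_i - phi_ref) / 2))
}

#' Export phase trajectories as CSV
#'
#' @param phi_trace Oscillators-by-time matrix of phases.
#' @param file Output path.
#' @export
write_phase_csv <- function(phi_trace, file) {
  df <- data.frame(
    timestep = rep(seq_len(ncol(phi_trace)), each = nrow(phi_trace)),
    oscillator_id = rep(seq_len(nrow(phi_trace)), ncol(phi_trace)),
    phase = as.numeric(phi_trace))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
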