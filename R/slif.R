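## Stochastic leaky integrate-and-fire (SLIF) network simulator.
##
## Membrane dynamics (forward Euler-Maruyama, step dt):
##   V_i <- V_i + dt * [ leak(V_i) + (b u_i + sum_j A_ij I_syn,j) / C ]
##               + eta * sqrt(dt) * z_i
## with threshold-and-reset spiking and alpha-function conductance synapses
##   g_syn(t) = g_bar * (t - t_s)/tau_s * exp(-(t - t_s)/tau_s),
##   I_syn,j  = -g_syn,j * (V_i - E_syn).
## The leak decays towards the resting potential by default ("rest"); the
## literal leak towards zero is selectable via leak_mode = "zero".

#' SLIF model parameters
#'
#' Defaults are the standard constants for this model family: membrane time
#' constant 15 ms, capacitance 10, rest -70 mV, threshold -50 mV, zero
#' refractory period, synaptic time constant 1, conductance scale 0.01,
#' synaptic reversal potential +70 (a generic excitatory cell), membrane
#' noise standard deviation sqrt(2), and unit timestep.
#'
#' @param tau_v Membrane time constant (> 0).
#' @param C Membrane capacitance (> 0).
#' @param v_rest Resting membrane potential.
#' @param v_thresh Spike threshold (must exceed `v_rest`).
#' @param refractory Refractory period in timesteps (0 allows consecutive
#'   spikes).
#' @param tau_s Synaptic time constant (> 0).
#' @param g_bar Synaptic conductance scale.
#' @param e_syn Synaptic reversal potential.
#' @param eta Standard deviation of the membrane white noise.
#' @param dt Integration timestep (> 0).
#' @param b Input gain applied to the scalar injected current.
#' @param v_min Hyperpolarization floor (reversal-potential bound; set to
#'   `-Inf` to disable).  Without it, strong sustained inhibitory drive can
#'   push the membrane arbitrarily far below rest, which is biophysically
#'   implausible and makes the cell unresponsive for many timesteps.
#' @param leak_mode `"rest"`: leak decays towards `v_rest` (default);
#'   `"zero"`: literal leak `-V / tau_v`.
#' @return An object of class `slif_params`.
#' @export
slif_params <- function(tau_v = 15, C = 10, v_rest = -70, v_thresh = -50,
                        refractory = 0L, tau_s = 1, g_bar = 0.01,
                        e_syn = 70, eta = sqrt(2), dt = 1, b = 1,
                        v_min = -90, leak_mode = c("rest", "zero")) {
  leak_mode <- match.arg(leak_mode)
  if (tau_v <= 0 || C <= 0 || tau_s <= 0 || dt <= 0)
    stop("time constants, capacitance and dt must be positive")
  if (v_rest >= v_thresh) stop("v_rest must be below v_thresh")
  if (eta < 0) stop("eta must be non-negative")
  if (v_min > v_rest) stop("v_min must not exceed v_rest")
  structure(list(tau_v = tau_v, C = C, v_rest = v_rest, v_thresh = v_thresh,
                 refractory = as.integer(refractory), tau_s = tau_s,
                 g_bar = g_bar, e_syn = e_syn, eta = eta, dt = dt, b = b,
                 v_min = v_min, leak_mode = leak_mode),
            class = "slif_params")
}

#' Minimum constant current that drives a cell to threshold
#'
#' From the closed-form steady state `V_inf = v_rest + tau_v * I / C`
#' (leak-to-rest mode), the cell fires for sustained currents above
#' `I = C * (v_thresh - v_rest) / tau_v`; with the default constants this is
#' 40/3 = 13.33.
#'
#' @param params A [slif_params()] object.
#' @return The threshold current.
#' @export
threshold_current <- function(params = slif_params()) {
  if (params$leak_mode == "zero")
    return(params$C * params$v_thresh / params$tau_v)
  params$C * (params$v_thresh - params$v_rest) / params$tau_v
}

#' Generate a random SLIF network
#'
#' `topology = "directed"` draws every off-diagonal weight iid from U(0, 1)
#' (the fully-actuated setting).  `topology = "block"` builds a symmetric
#' matrix with community structure: within-block weights iid U(0, 1),
#' between-block weights zero with probability `1 - p_cross` and otherwise
#' U(0, w_cross) (the under-actuated setting; `p_cross = 0` gives an exactly
#' block-diagonal matrix).
#'
#' @param n_cells Number of cells (>= 1).
#' @param topology `"directed"` or `"block"`.
#' @param n_communities Number of blocks for `topology = "block"`.
#' @param p_cross Probability of a between-block edge.
#' @param w_cross Upper bound of between-block weights.
#' @param params A [slif_params()] object.
#' @return An object of class `slif_network` with fields `n_cells`,
#'   `adjacency` (zero diagonal), `params`, `topology`, `communities`.
#' @export
slif_network <- function(n_cells, topology = c("directed", "block"),
                         n_communities = 1L, p_cross = 0.05, w_cross = 0.1,
                         params = slif_params()) {
  topology <- match.arg(topology)
  n <- as.integer(n_cells)
  if (n < 1) stop("n_cells must be at least 1")
  communities <- rep(1L, n)
  if (topology == "directed") {
    A <- matrix(stats::runif(n * n), n, n)
    diag(A) <- 0
  } else {
    k <- as.integer(n_communities)
    if (k < 1 || k > n) stop("n_communities must divide cells into non-empty blocks")
    communities <- sort(rep_len(seq_len(k), n))
    A <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (communities[i] == communities[j]) {
          w <- stats::runif(1)
        } else {
          w <- if (stats::runif(1) < p_cross) stats::runif(1, 0, w_cross) else 0
        }
        A[i, j] <- w
        A[j, i] <- w
      }
    }
  }
  structure(list(n_cells = n, adjacency = A, params = params,
                 topology = topology, communities = communities),
            class = "slif_network")
}

#' Initial state of a SLIF network
#'
#' All cells start at the resting membrane potential with an empty synaptic
#' event queue.  The queue keeps the last `ceiling(10 * tau_s / dt)` steps of
#' spike indicators; older spikes contribute less than 5e-4 of the peak
#' conductance and are dropped.
#'
#' @param network A [slif_network()].
#' @return An object of class `slif_state` with fields `V`, `spiked`,
#'   `hist` (event queue, most recent column first), `refr`, `t`.
#' @export
slif_state <- function(network) {
  p <- network$params
  mem <- as.integer(ceiling(10 * p$tau_s / p$dt))
  structure(list(V = rep(p$v_rest, network$n_cells),
                 spiked = integer(network$n_cells),
                 hist = matrix(0, network$n_cells, mem),
                 refr = integer(network$n_cells),
                 t = 0L),
            class = "slif_state")
}

#' Alpha-function synaptic conductance
#'
#' `g(t) = g_bar * (t / tau_s) * exp(-t / tau_s)` for elapsed time `t` since
#' the presynaptic spike; zero for non-positive elapsed time.  The maximum
#' `g_bar / e` is attained at `t = tau_s`.  Contributions from multiple past
#' spikes sum.
#'
#' @param t_elapsed Elapsed time(s) since the presynaptic spike.
#' @param params A [slif_params()] object.
#' @return Conductance value(s).
#' @export
alpha_conductance <- function(t_elapsed, params = slif_params()) {
  ifelse(t_elapsed > 0,
         params$g_bar * (t_elapsed / params$tau_s) * exp(-t_elapsed / params$tau_s),
         0)
}

# conductance of each presynaptic cell given the event queue
.presyn_conductance <- function(network, state) {
  p <- network$params
  mem <- ncol(state$hist)
  kernel <- alpha_conductance(p$dt * seq_len(mem), p)
  as.numeric(state$hist %*% kernel)
}

#' Synaptic current into each cell
#'
#' Implements the weighted sum of per-synapse currents
#' `sum_j A[i, j] * (-(g_j(t)) * (V_i - E_syn))`, where `g_j` sums the alpha
#' conductances of cell `j`'s recent spikes.
#'
#' @param network A [slif_network()].
#' @param state A [slif_state()].
#' @param i Optional cell index; if `NULL`, currents for all cells.
#' @return Current(s) into the requested cell(s).
#' @export
synaptic_current <- function(network, state, i = NULL) {
  g <- .presyn_conductance(network, state)
  drive <- as.numeric(network$adjacency %*% g)
  cur <- (network$params$e_syn - state$V) * drive
  if (is.null(i)) cur else cur[i]
}

#' Advance a SLIF network one timestep
#'
#' Forward Euler-Maruyama update of the membrane potentials followed by
#' threshold detection: cells whose potential reaches `v_thresh` emit a
#' spike, are recorded in the event queue and are reset to `v_rest`.  With a
#' zero refractory period a cell may spike on consecutive steps.
#'
#' @param network A [slif_network()].
#' @param state A [slif_state()].
#' @param u Injected current, one scalar per cell (the control input).
#' @return The updated `slif_state`.
#' @export
slif_step <- function(network, state, u = 0) {
  p <- network$params
  n <- network$n_cells
  u <- rep_len(as.numeric(u), n)
  if (any(!is.finite(u))) stop("non-finite input current")
  g <- .presyn_conductance(network, state)
  i_syn <- (p$e_syn - state$V) * as.numeric(network$adjacency %*% g)
  leak <- if (p$leak_mode == "rest") -(state$V - p$v_rest) / p$tau_v
          else -state$V / p$tau_v
  noise <- if (p$eta > 0) p$eta * sqrt(p$dt) * stats::rnorm(n) else 0
  V <- state$V + p$dt * (leak + (p$b * u + i_syn) / p$C) + noise
  V <- pmax(V, p$v_min)
  active <- state$refr == 0L
  V[!active] <- p$v_rest
  spiked <- as.integer(active & V >= p$v_thresh)
  V[spiked == 1L] <- p$v_rest
  refr <- pmax(state$refr - 1L, 0L)
  if (p$refractory > 0L) refr[spiked == 1L] <- p$refractory
  mem <- ncol(state$hist)
  state$hist <- cbind(spiked, state$hist[, -mem, drop = FALSE], deparse.level = 0)
  state$V <- V
  state$spiked <- spiked
  state$refr <- refr
  state$t <- state$t + 1L
  state
}

#' Export a spike raster as CSV
#'
#' Writes sparse `(cell_id, timestep)` rows for every action potential.
#'
#' @param raster Binary cells-by-time matrix.
#' @param file Output path.
#' @export
write_raster_csv <- function(raster, file) {
  idx <- which(raster != 0, arr.ind = TRUE)
  df <- data.frame(cell_id = idx[, 1], timestep = idx[, 2])
  df <- df[order(df$timestep, df$cell_id), , drop = FALSE]
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Export membrane-potential traces as CSV
#'
#' @param V_trace Cells-by-time matrix of membrane potentials.
#' @param file Output path.
#' @export
write_voltage_csv <- function(V_trace, file) {
  df <- data.frame(
    timestep = rep(seq_len(ncol(V_trace)), each = nrow(V_trace)),
    cell_id = rep(seq_len(nrow(V_trace)), ncol(V_trace)),
    V = as.numeric(V_trace))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
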