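## Ornstein-Uhlenbeck exploration noise (standalone, R-level).
## The agent carries its own internal copy of the same process; this object
## exposes the discretised update directly for analysis and testing.

#' Ornstein-Uhlenbeck noise process
#'
#' Temporally correlated exploration noise with zero mean.  The Euler
#' discretisation is `x <- x + theta * (0 - x) * dt + sigma * sqrt(dt) * z`
#' with standard normal `z`; the stationary variance is
#' `sigma^2 / (2 * theta)`.
#'
#' @param dim Dimension of the noise vector.
#' @param theta Mean-reversion rate (> 0).
#' @param sigma Diffusion scale (>= 0).
#' @param dt Step size (> 0).
#' @param x0 Initial value (default zero).
#' @return An object of class `ou_noise` with field `x`, the current value.
#' @export
ou_noise <- function(dim = 1L, theta = 0.15, sigma = 0.2, dt = 1, x0 = 0) {
  if (theta <= 0 || dt <= 0) stop("theta and dt must be positive")
  if (sigma < 0) stop("sigma must be non-negative")
  structure(list(x = rep_len(as.numeric(x0), dim), theta = theta,
                 sigma = sigma, dt = dt),
            class = "ou_noise")
}

#' Advance an Ornstein-Uhlenbeck process one step
#'
#' @param noise An [ou_noise()] object.
#' @return The updated `ou_noise` object; the new value is in `$x`.
#' @export
ou_step <- function(noise) {
  stopifnot(inherits(noise, "ou_noise"))
  z <- stats::rnorm(length(noise$x))
  noise$x <- noise$x + noise$theta * (0 - noise$x) * noise$dt +
    noise$sigma * sqrt(noise$dt) * z
  noise
}

#' FIFO replay buffer with uniform sampling
#'
#' A bounded store of `(state, action, reward, next_state, terminal)`
#' transitions.  When full, the oldest transition is evicted first; sampling
#' is uniform without replacement within a batch.
#'
#' @param capacity Maximum number of stored transitions.
#' @param state_dim,action_dim Dimensions of states and actions.
#' @return An object of class `replay_buffer`.
#' @export
replay_buffer <- function(capacity, state_dim, action_dim = 1L) {
  if (capacity < 1) stop("capacity must be a positive integer")
  structure(list(ptr = cpp_rb_new(as.integer(capacity),
                                  as.integer(state_dim),
                                  as.integer(action_dim)),
                 capacity = as.integer(capacity),
                 state_dim = as.integer(state_dim),
                 action_dim = as.integer(action_dim)),
            class = "replay_buffer")
}

#' @rdname replay_buffer
#' @param buffer A [replay_buffer()].
#' @param state,action,reward,next_state,terminal Transition components.
#' @export
rb_push <- function(buffer, state, action, reward, next_state,
                    terminal = FALSE) {
  cpp_rb_push(buffer$ptr, as.numeric(state), as.numeric(action),
              as.numeric(reward), as.numeric(next_state),
              as.numeric(isTRUE(terminal) || (is.numeric(terminal) && terminal != 0)))
  invisible(buffer)
}

#' @rdname replay_buffer
#' @export
rb_size <- function(buffer) cpp_rb_size(buffer$ptr)

#' @rdname replay_buffer
#' @param n Sample size (at most the current buffer size).
#' @export
rb_sample <- function(buffer, n) cpp_rb_sample(buffer$ptr, as.integer(n))

#' @rdname replay_buffer
#' @export
rb_contents <- function(buffer) cpp_rb_contents(buffer$ptr)
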