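## Latent phase-space analysis of spike rasters.
##
## Population spiking is smoothed into instantaneous firing rates, projected
## onto the leading principal components of a calibration raster, and the
## projection is turned into a phase angle: directly (atan2 of the PC1-PC2
## pair) in two dimensions, or by quadrature delay embedding in one.

# trailing moving average along time, truncated at the start of the series
.smooth_raster <- function(raster, window) {
  raster <- as.matrix(raster)
  n <- nrow(raster); T <- ncol(raster)
  w <- as.integer(window)
  if (w < 1) stop("smoothing_window must be a positive integer")
  if (w == 1) return(raster)
  cs <- cbind(0, t(apply(raster, 1, cumsum)))
  out <- matrix(0, n, T)
  for (t in seq_len(T)) {
    lo <- max(0L, t - w)
    out[, t] <- (cs[, t + 1] - cs[, lo + 1]) / (t - lo)
  }
  out
}

#' Fit principal components to a spike raster
#'
#' The raster is smoothed per cell with a trailing moving average of
#' `smoothing_window` steps (turning binary spikes into an instantaneous
#' firing rate), mean-centred, and the cell-by-cell covariance is
#' eigendecomposed.  The top `k` eigenvectors are returned with a
#' deterministic sign convention: the largest-magnitude loading of each
#' component is positive.
#'
#' @param raster Binary cells-by-time matrix from a calibration run.
#' @param k Number of components (1 or 2 for the control tasks).
#' @param smoothing_window Width of the moving average (steps).
#' @return An object of class `pc_model` with orthonormal `loadings`
#'   (cells x k), the smoothed `mean` vector, non-increasing
#'   `explained_variance`, and `smoothing_window`.
#' @export
fit_pca <- function(raster, k = 1L, smoothing_window = 5L) {
  raster <- as.matrix(raster)
  n <- nrow(raster); T <- ncol(raster)
  k <- as.integer(k)
  if (k < 1 || k > n) stop("k must lie between 1 and the number of cells")
  if (T < 2) stop("raster must span at least two timesteps")
  X <- .smooth_raster(raster, smoothing_window)
  mu <- rowMeans(X)
  Xc <- X - mu
  S <- Xc %*% t(Xc) / (T - 1)
  eig <- eigen(S, symmetric = TRUE)
  if (eig$values[1] <= 1e-12)
    stop("degenerate raster: covariance has no principal directions")
  L <- eig$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  structure(list(loadings = L, mean = mu,
                 explained_variance = pmax(eig$values[seq_len(k)], 0),
                 smoothing_window = as.integer(smoothing_window),
                 n_cells = n),
            class = "pc_model")
}

#' Project recent population activity onto the principal components
#'
#' The last `smoothing_window` columns of `spikes_window` are averaged into
#' an instantaneous rate vector, centred with the stored mean, and multiplied
#' by the loadings.
#'
#' @param model A [fit_pca()] model.
#' @param spikes_window Cells-by-time matrix of the most recent raster
#'   columns (at least `smoothing_window` of them).
#' @return Numeric vector of length `k`.
#' @export
project <- function(model, spikes_window) {
  W <- as.matrix(spikes_window)
  w <- model$smoothing_window
  if (nrow(W) != model$n_cells) stop("window has wrong number of cells")
  if (ncol(W) < w) stop("window must span at least smoothing_window steps")
  x <- rowMeans(W[, (ncol(W) - w + 1):ncol(W), drop = FALSE])
  as.numeric(crossprod(model$loadings, x - model$mean))
}

#' Estimate the phase angle of a latent trajectory
#'
#' For `k = 2`, the phase is `atan2(PC2, PC1)` wrapped to [0, 2*pi).  For
#' `k = 1`, a scalar has no intrinsic angle, so the trajectory is delay
#' embedded against its quadrature lag: `phase_t = atan2(x[t - lag], x[t])`,
#' which recovers the true phase exactly for a cosine with period
#' `4 * lag`.  Timesteps where the embedding vector has (near-)zero magnitude
#' carry the previous phase forward (initially 0).
#'
#' @param trajectory Numeric vector (k = 1) or T-by-2 matrix (k = 2) of
#'   projections.
#' @param lag Delay for the 1-D embedding, by default a quarter of the
#'   target period.
#' @param tol Magnitude below which the phase is treated as undefined.
#' @return Numeric vector of phases in [0, 2*pi), one per timestep.
#' @export
estimate_phase <- function(trajectory, lag = 10L, tol = 1e-12) {
  if (is.matrix(trajectory) && ncol(trajectory) >= 2) {
    x <- trajectory[, 1]; y <- trajectory[, 2]
    defined <- sqrt(x^2 + y^2) > tol
    ph <- wrap_phase(atan2(y, x))
  } else {
    x <- as.numeric(trajectory)
    T <- length(x)
    lag <- as.integer(lag)
    if (lag < 1) stop("lag must be a positive integer")
    ph <- numeric(T)
    defined <- logical(T)
    idx <- seq_len(T) > lag
    xl <- c(rep(NA_real_, lag), x[seq_len(max(T - lag, 0))])
    defined <- idx & sqrt(x^2 + ifelse(is.na(xl), 0, xl)^2) > tol
    ph <- wrap_phase(atan2(ifelse(is.na(xl), 0, xl), x))
  }
  out <- numeric(length(ph))
  prev <- 0
  for (t in seq_along(ph)) {
    if (defined[t]) prev <- ph[t]
    out[t] <- prev
  }
  out
}

#' Target phase schedule
#'
#' A uniformly advancing phase `wrap(2 * pi * t / period)` for
#' `t = 0, ..., T - 1`.  For two-dimensional targets the unit-circle curve
#' `(cos, sin)` traced in the PC1-PC2 plane is also returned.
#'
#' @param pc_dim 1 or 2.
#' @param period Oscillation period in timesteps (>= 4).
#' @param T Schedule length (>= period).
#' @return List with `phase` (length T) and, for `pc_dim = 2`, `curve`
#'   (T x 2).
#' @export
target_schedule <- function(pc_dim = 1L, period = 40L, T = 100L) {
  if (period < 4) stop("period must be at least 4 timesteps")
  if (T < period) stop("schedule must span at least one period")
  phase <- wrap_phase(2 * pi * (seq_len(T) - 1) / period)
  out <- list(phase = phase, period = as.integer(period),
              pc_dim = as.integer(pc_dim))
  if (pc_dim == 2L) out$curve <- cbind(cos(phase), sin(phase))
  out
}

#' Assign cells to communities from fitted loadings
#'
#' Each cell is assigned to the component on which it loads with the largest
#' magnitude.  For block networks with no cross-community edges this
#' recovers the blocks exactly.
#'
#' @param model A [fit_pca()] model with `k >= 1` components.
#' @return Integer vector of community labels (one per cell).
#' @export
recover_communities <- function(model) {
  apply(abs(model$loadings), 1, which.max)
}

#' Save a fitted PC model as CSV plus JSON manifest
#'
#' @param model A [fit_pca()] model.
#' @param dir Output directory (created if missing).
#' @export
save_pc_model <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  df <- data.frame(cell_id = seq_len(model$n_cells))
  for (j in seq_len(ncol(model$loadings)))
    df[[paste0("loading_pc", j)]] <- model$loadings[, j]
  df$mean <- model$mean
  utils::write.csv(df, file.path(dir, "pc_loadings.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n_cells = model$n_cells, k = ncol(model$loadings),
         explained_variance = model$explained_variance,
         smoothing_window = model$smoothing_window),
    file.path(dir, "pc_model.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
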