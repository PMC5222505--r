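#' Gaussian white-noise stimulus
#'
#' Independent N(0, sigma^2) draws per time bin and spatial dimension —
#' the stimulus regime under which the response-weighted covariance is
#' proportional to the second-order Wiener kernel. Deterministic given
#' the seed; the caller's RNG state is left untouched.
#'
#' @param T Number of time samples.
#' @param D Number of spatial dimensions.
#' @param sigma Stimulus standard deviation.
#' @param dt Sampling interval.
#' @param seed Integer seed.
#' @return A \code{\link{stimulus_ensemble}}.
#' @export
gaussian_white_stimulus <- function(T, D = 1L, sigma = 1, dt = 1, seed = 1L) {
  T <- check_count(T, "T", min = 2L)
  D <- check_count(D, "D", min = 1L)
  sigma <- check_positive_scalar(sigma, "sigma")
  vals <- with_seed(seed, matrix(stats::rnorm(T * D, sd = sigma), T, D))
  stimulus_ensemble(vals, dt = dt, sigma = sigma)
}

#' Random symmetric second-order Volterra kernel
#'
#' Fixture generator: a seeded random (D*L) x (D*L) matrix, symmetrized
#' as (M + M^T)/2 and scaled to unit Frobenius norm. Such full-rank
#' kernels are deliberately harder than the low-rank kernels typical of
#' real cells and make recovery tests stringent.
#'
#' @param D Spatial dimensions.
#' @param L Number of lags (tau + 1).
#' @param seed Integer seed.
#' @return An object of class `volterra_model` with fields `G2`, `tau`, `D`.
#' @export
random_volterra_kernel <- function(D, L, seed = 1L) {
  D <- check_count(D, "D", min = 1L)
  L <- check_count(L, "L", min = 1L)
  n <- D * L
  M <- with_seed(seed, matrix(stats::rnorm(n * n), n, n))
  G <- (M + t(M)) / 2
  G <- G / sqrt(sum(G^2))
  structure(list(G2 = G, tau = L - 1L, D = D), class = "volterra_model")
}

#' Response of a pure second-order Volterra model cell
#'
#' The model cell of the kernel-recovery experiment: its response is a
#' linear weighting of all pairwise products of recent stimulus values,
#' \deqn{r_t = \sum_{(d_1,i),(d_2,j)} G^{(2)}_{(d_1,i),(d_2,j)}
#'   s_{t-i,d_1} s_{t-j,d_2} = x_t^T G^{(2)} x_t,}
#' where \eqn{x_t} is the lag-window vector at bin t. Bins t <= tau have
#' no complete window and are zero-filled (they are excluded from all
#' estimator sums anyway). Because the system is purely second order,
#' its Wiener kernel equals G2 when the response is demeaned.
#'
#' @param stimulus A \code{\link{stimulus_ensemble}}.
#' @param model A `volterra_model` (from
#'   \code{\link{random_volterra_kernel}} or built by hand).
#' @return A continuous \code{\link{response_set}} (one column).
#' @export
volterra_response <- function(stimulus, model) {
  if (!inherits(model, "volterra_model"))
    stop_validation("model must be a volterra_model")
  lags <- lag_window(model$tau)
  if (ncol(stimulus$values) != model$D)
    stop_dimension("stimulus D does not match the kernel")
  X <- lagged_design(stimulus, lags)
  if (ncol(X) != nrow(model$G2)) stop_dimension("kernel size does not match D*L")
  r <- rowSums((X %*% model$G2) * X)
  full <- numeric(nrow(stimulus$values))
  full[(model$tau + 1L):nrow(stimulus$values)] <- r
  response_set(full, mode = "continuous")
}

#' Multi-filter rectified LNP model cell
#'
#' A spiking model neuron: each linear filter is applied to the stimulus
#' lag window, half-wave rectified, and the rectified outputs are summed;
#' `gain` converts the summed drive into an expected spike count per bin,
#' and spikes are drawn from a Poisson process. With two filters this is
#' the classic ON/OFF-style cell whose STA mixes the filters and whose
#' STC eigenvectors recover their span.
#'
#' @param filters Matrix with one length-(D*L) filter per column (or a
#'   single vector).
#' @param gain Non-negative scalar, expected spikes per unit drive.
#' @param tau Maximum lag (default: filter length - 1, i.e. D = 1).
#' @param D Spatial dimensions (default 1).
#' @return An object of class `lnp_model`.
#' @export
lnp_model <- function(filters, gain = 1, tau = NULL, D = 1L) {
  if (is.vector(filters)) filters <- matrix(filters, ncol = 1L)
  if (ncol(filters) < 1L) stop_validation("need at least one filter")
  check_finite(filters, "filters")
  if (!is.numeric(gain) || length(gain) != 1L || !is.finite(gain) || gain < 0)
    stop_validation("gain must be a single non-negative number")
  D <- check_count(D, "D", min = 1L)
  if (is.null(tau)) {
    if (nrow(filters) %% D != 0L) stop_dimension("filter length not divisible by D")
    tau <- nrow(filters) %/% D - 1L
  }
  tau <- check_count(tau, "tau", min = 0L)
  if (nrow(filters) != D * (tau + 1L))
    stop_dimension("filter length must equal D*(tau+1)")
  structure(list(filters = filters, gain = gain, tau = tau, D = D),
            class = "lnp_model")
}

# summed half-wave-rectified drive per complete-window bin
lnp_drive <- function(stimulus, model) {
  X <- lagged_design(stimulus, lag_window(model$tau))
  U <- X %*% model$filters
  rowSums(pmax(U, 0))
}

#' Simulate spikes from a rectified LNP model
#'
#' For each bin t >= tau+1 the firing rate is
#' `gain * sum_k max(0, f_k . x_t)` and the spike count is Poisson with
#' that mean (counts may exceed 1 per bin). Bins without a complete lag
#' window produce no spikes. Deterministic given the seed.
#'
#' @param stimulus A \code{\link{stimulus_ensemble}}.
#' @param model An \code{\link{lnp_model}}.
#' @param seed Integer seed.
#' @return A spike-counts \code{\link{response_set}} (one column).
#' @export
lnp_spikes <- function(stimulus, model, seed = 1L) {
  if (!inherits(model, "lnp_model")) stop_validation("model must be an lnp_model")
  if (ncol(stimulus$values) != model$D)
    stop_dimension("stimulus D does not match the model")
  rate <- model$gain * lnp_drive(stimulus, model)
  counts <- with_seed(seed, stats::rpois(length(rate), rate))
  full <- numeric(nrow(stimulus$values))
  full[(model$tau + 1L):nrow(stimulus$values)] <- counts
  response_set(full, mode = "spike-counts")
}

#' Calibrate LNP gain for a target mean firing rate
#'
#' Under Gaussian white input of standard deviation sigma, the expected
#' half-wave-rectified output of filter f is the half-normal mean
#' \eqn{\sigma \lVert f \rVert / \sqrt{2\pi}}, so the gain that yields a
#' target expected spike count per bin is
#' \deqn{g = \frac{\text{target}}{\sum_k \sigma \lVert f_k \rVert / \sqrt{2\pi}}.}
#'
#' @param model An \code{\link{lnp_model}} (its current gain is ignored).
#' @param sigma Stimulus standard deviation.
#' @param target_rate Desired mean spikes per bin (> 0).
#' @return The calibrated gain (scalar).
#' @export
calibrate_gain <- function(model, sigma = 1, target_rate) {
  if (!inherits(model, "lnp_model")) stop_validation("model must be an lnp_model")
  sigma <- check_positive_scalar(sigma, "sigma")
  target_rate <- check_positive_scalar(target_rate, "target_rate")
  norms <- sqrt(colSums(model$filters^2))
  denom <- sum(sigma * norms) / sqrt(2 * pi)
  if (denom == 0) stop_degenerate("all filters are zero: cannot calibrate gain")
  target_rate / denom
}

#' Two orthonormal biphasic temporal filters
#'
#' Fixture for the two-filter LNP experiments: a pair of smooth biphasic
#' impulse responses built from gamma-difference shapes with distinct
#' time constants (fast and slow), orthogonalized by Gram-Schmidt and
#' normalized to unit length. Deterministic closed form; the exact
#' shapes are a documented package choice, since subspace recovery is
#' agnostic to them.
#'
#' @param L Number of lags (>= 4 recommended).
#' @return An L x 2 matrix, orthonormal columns.
#' @export
biphasic_filters <- function(L = 16L) {
  L <- check_count(L, "L", min = 2L)
  t <- seq_len(L) - 1L
  gamma_diff <- function(t, t1, t2, k) {
    (t / t1)^3 * exp(-t / t1) - k * (t / t2)^3 * exp(-t / t2)
  }
  f1 <- gamma_diff(t, 1.6, 3.2, 0.8)
  f2 <- gamma_diff(t, 2.8, 5.2, 0.9)
  f1 <- f1 / sqrt(sum(f1^2))
  f2 <- f2 - sum(f2 * f1) * f1
  f2 <- f2 / sqrt(sum(f2^2))
  cbind(f1, f2)
}

#' Relative kernel estimation error
#'
#' Frobenius-norm relative error between an estimated kernel and the
#' ground-truth Volterra kernel,
#' \eqn{\lVert \hat K - G \rVert_F / \lVert G \rVert_F}.
#'
#' @param estimate A `block_cov` or plain matrix.
#' @param truth A `volterra_model` or plain matrix.
#' @return A single non-negative number.
#' @export
kernel_estimation_error <- function(estimate, truth) {
  E <- as_cov_matrix(estimate)
  G <- if (inherits(truth, "volterra_model")) truth$G2 else as.matrix(truth)
  if (!identical(dim(E), dim(G))) stop_dimension("estimate and truth shapes differ")
  denom <- sqrt(sum(G^2))
  if (denom == 0) stop_degenerate("zero-norm truth kernel")
  sqrt(sum((E - G)^2)) / denom
}
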