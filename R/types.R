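#' Stimulus ensemble
#'
#' Container for a white-noise (or other) stimulus presented to a cell:
#' a T x D matrix of stimulus samples (rows = time bins, columns = spatial
#' dimensions, e.g. pixels), together with the sampling interval `dt` and
#' the nominal stimulus standard deviation `sigma`. `sigma` and `dt` enter
#' the Wiener-kernel rescaling; the covariance estimators use the raw
#' samples unchanged (no internal demeaning or rescaling of the stimulus).
#'
#' @param values Numeric matrix (T x D) or vector (treated as T x 1).
#' @param dt Sampling interval (time units per bin), positive.
#' @param sigma Nominal stimulus standard deviation, positive.
#' @return An object of class `stimulus_ensemble` with fields `values`,
#'   `dt`, `sigma`.
#' @examples
#' s <- stimulus_ensemble(matrix(rnorm(100), 50, 2), dt = 0.01, sigma = 1)
#' dim(s$values)
#' @export
stimulus_ensemble <- function(values, dt = 1, sigma = 1) {
  if (is.vector(values)) values <- matrix(as.numeric(values), ncol = 1L)
  if (!is.matrix(values) || !is.numeric(values))
    stop_validation("stimulus values must be a numeric matrix or vector")
  storage.mode(values) <- "double"
  check_finite(values, "stimulus")
  if (nrow(values) < 2L) stop_validation("stimulus needs at least 2 time samples")
  if (ncol(values) < 1L) stop_validation("stimulus needs at least 1 spatial dimension")
  dt <- check_positive_scalar(dt, "dt")
  sigma <- check_positive_scalar(sigma, "sigma")
  structure(list(values = values, dt = dt, sigma = sigma),
            class = "stimulus_ensemble")
}

#' Response set
#'
#' One or more response time series aligned with a stimulus: a T x R
#' matrix (rows = time bins, columns = recorded units/responses). Mode
#' `"continuous"` admits any finite values (membrane voltage, calcium
#' fluorescence, ...); mode `"spike-counts"` requires non-negative
#' integer counts per bin and is the mode the spike-triggered operations
#' (\code{\link{spike_triggered_average}}, \code{\link{stc_matrices}})
#' expect.
#'
#' @param values Numeric matrix (T x R) or vector (treated as T x 1).
#' @param mode `"continuous"` or `"spike-counts"`.
#' @return An object of class `response_set` with fields `values`, `mode`.
#' @export
response_set <- function(values, mode = c("continuous", "spike-counts")) {
  mode <- match.arg(mode)
  if (is.vector(values)) values <- matrix(as.numeric(values), ncol = 1L)
  if (!is.matrix(values) || !is.numeric(values))
    stop_validation("response values must be a numeric matrix or vector")
  storage.mode(values) <- "double"
  check_finite(values, "response")
  if (mode == "spike-counts" &&
      (any(values < 0) || any(values != round(values))))
    stop_validation("spike-counts mode requires non-negative integer values")
  structure(list(values = values, mode = mode), class = "response_set")
}

#' Lag window
#'
#' Temporal extent of the kernel: lags 0..tau inclusive, i.e. L = tau + 1
#' causal taps (the stimulus at, and up to tau bins before, each response
#' bin). The estimator sums run over t = tau+1..T only, so every summed
#' bin has a complete lag window (no zero padding).
#'
#' @param tau Maximum lag in samples, non-negative integer.
#' @return An object of class `lag_window` with fields `tau`, `L`.
#' @export
lag_window <- function(tau) {
  tau <- check_count(tau, "tau", min = 0L)
  structure(list(tau = tau, L = tau + 1L), class = "lag_window")
}

as_lag_window <- function(lags) {
  if (inherits(lags, "lag_window")) lags else lag_window(lags)
}

# internal constructor; matrices are stored dim-major, lag-minor:
# row/col index p = (d-1)*L + i + 1 addresses dimension d (1-based), lag i.
new_block_cov <- function(matrix, role, tau, D, normalization, demeaned = FALSE,
                          dt = NA_real_, sigma = NA_real_) {
  structure(list(matrix = matrix,
                 layout = "dim_major_lag_minor",
                 role = role, tau = as.integer(tau), D = as.integer(D),
                 normalization = normalization, demeaned = isTRUE(demeaned),
                 dt = dt, sigma = sigma),
            class = "block_cov")
}

#' @export
print.block_cov <- function(x, ...) {
  cat(sprintf("<block_cov role=%s  %dx%d (D=%d, L=%d, layout=%s)%s>\n",
              x$role, nrow(x$matrix), ncol(x$matrix), x$D, x$tau + 1L,
              x$layout, if (x$demeaned) ", response demeaned" else ""))
  invisible(x)
}

#' @export
print.stimulus_ensemble <- function(x, ...) {
  cat(sprintf("<stimulus_ensemble T=%d D=%d dt=%g sigma=%g>\n",
              nrow(x$values), ncol(x$values), x$dt, x$sigma))
  invisible(x)
}

#' @export
print.response_set <- function(x, ...) {
  cat(sprintf("<response_set T=%d R=%d mode=%s>\n",
              nrow(x$values), ncol(x$values), x$mode))
  invisible(x)
}

#' @export
print.sta <- function(x, ...) {
  cat(sprintf("<spike-triggered average length=%d n_r=%g>\n", length(x$a), x$n_r))
  invisible(x)
}

#' @export
print.stc_result <- function(x, ...) {
  cat(sprintf("<stc_result %dx%d: C0, C1, C2, sta (n_r=%g)>\n",
              nrow(x$C0), ncol(x$C0), x$sta$n_r))
  invisible(x)
}

#' @export
print.eigen_report <- function(x, ...) {
  cat(sprintf("<eigen_report %d eigenvalues, %d significant (alpha=%g, %s band)>\n",
              length(x$values), sum(x$significant), x$alpha, x$method))
  invisible(x)
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble variant=%s n_shifts=%d seed=%d>\n",
              x$variant, length(x$shifts), x$seed))
  invisible(x)
}

# shared input checks for the covariance estimators
check_pair <- function(stimulus, responses, lags) {
  if (!inherits(stimulus, "stimulus_ensemble"))
    stop_validation("stimulus must be a stimulus_ensemble")
  if (!inherits(responses, "response_set"))
    stop_validation("responses must be a response_set")
  lags <- as_lag_window(lags)
  T <- nrow(stimulus$values)
  if (nrow(responses$values) != T)
    stop_dimension(sprintf("stimulus (T=%d) and response (T=%d) lengths differ",
                           T, nrow(responses$values)))
  if (lags$tau >= T)
    stop_validation(sprintf("tau (%d) must be smaller than T (%d)", lags$tau, T))
  lags
}
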