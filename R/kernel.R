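#' Lagged design matrix of a stimulus
#'
#' Expands a T x D stimulus into its (T-tau) x (D*L) matrix of complete
#' lag windows: row t' (corresponding to time bin t = tau + t') holds
#' `s[t - i, d]` in column `(d-1)*L + i + 1`, i.e. dim-major, lag-minor
#' ordering with lags i = 0..tau. All covariance estimators and model
#' simulators in the package share this layout.
#'
#' @param stimulus A \code{\link{stimulus_ensemble}}.
#' @param lags A \code{\link{lag_window}} or bare tau.
#' @return Numeric matrix with T-tau rows and D*(tau+1) columns.
#' @export
lagged_design <- function(stimulus, lags) {
  if (!inherits(stimulus, "stimulus_ensemble"))
    stop_validation("stimulus must be a stimulus_ensemble")
  lags <- as_lag_window(lags)
  s <- stimulus$values
  T <- nrow(s); D <- ncol(s)
  tau <- lags$tau; L <- lags$L
  if (tau >= T) stop_validation(sprintf("tau (%d) must be smaller than T (%d)", tau, T))
  X <- matrix(0, T - tau, D * L)
  for (d in seq_len(D)) {
    for (i in 0:tau) {
      X[, (d - 1L) * L + i + 1L] <- s[(tau + 1L - i):(T - i), d]
    }
  }
  X
}

# one response column -> one covariance matrix, vectorized (BLAS) path;
# w is the response restricted to bins tau+1..T.
rwc_fast_one <- function(X, w, nt) {
  M <- crossprod(X, w * X) / nt
  (M + t(M)) / 2  # enforce exact symmetry against BLAS round-off
}

rwc_reference_one <- function(s, w_full, tau, nt) {
  M <- .rwc_reference_cpp(s, w_full, as.integer(tau))
  (M + t(M)) / 2  # same symmetrization as the fast path
}

#' Response-weighted stimulus covariance
#'
#' Estimates, for each response column r, the matrix
#' \deqn{C_{ij} = \frac{1}{T-\tau} \sum_{t=\tau+1}^{T} r_t\, s_{t-i}\, s_{t-j}}
#' with lags i, j = 0..tau, organized block-wise per pair of stimulus
#' dimensions (dim-major, lag-minor). The sum runs over the T-tau bins
#' that have a complete lag window; the denominator is the number of
#' summed terms, T-tau. With `demean_response = TRUE` the response is
#' replaced by r - mean(r) (mean over the summed bins), the condition
#' under which C is proportional to the second-order Wiener kernel (see
#' \code{\link{wiener_kernel}}).
#'
#' Two backends are provided: `"accelerated"` builds the lagged design
#' matrix once and uses BLAS cross-products; `"reference"` is a literal
#' per-entry triple loop (compiled). Both accumulate in double precision
#' and agree to better than 1e-10 relative; see
#' \code{\link{backend_equivalence}}.
#'
#' @param stimulus A \code{\link{stimulus_ensemble}}.
#' @param responses A \code{\link{response_set}} (R columns).
#' @param lags A \code{\link{lag_window}} or bare tau.
#' @param demean_response Subtract the response mean before weighting?
#' @param backend `"accelerated"` (default) or `"reference"`.
#' @param drop If `TRUE` (default) and there is a single response column,
#'   return the `block_cov` itself rather than a length-1 list.
#' @return A `block_cov` (role `"C"`), or a list of one per response column.
#' @examples
#' s <- stimulus_ensemble(c(1, 2, 3, 4))
#' r <- response_set(c(0, 0, 1, 2))
#' C <- response_weighted_covariance(s, r, lag_window(1))
#' C$matrix  # [[41/3, 10], [10, 22/3]]
#' @export
response_weighted_covariance <- function(stimulus, responses, lags,
                                         demean_response = FALSE,
                                         backend = c("accelerated", "reference"),
                                         drop = TRUE) {
  backend <- match.arg(backend)
  lags <- check_pair(stimulus, responses, lags)
  s <- stimulus$values
  T <- nrow(s); D <- ncol(s)
  tau <- lags$tau
  nt <- T - tau
  rows <- (tau + 1L):T
  X <- if (backend == "accelerated") lagged_design(stimulus, lags) else NULL

  out <- lapply(seq_len(ncol(responses$values)), function(k) {
    w <- responses$values[rows, k]
    if (demean_response) w <- w - mean(w)
    M <- if (backend == "accelerated") {
      rwc_fast_one(X, w, nt)
    } else {
      w_full <- responses$values[, k]
      if (demean_response) {
        w_full <- w_full - mean(responses$values[rows, k])
      }
      rwc_reference_one(s, w_full, tau, nt)
    }
    new_block_cov(M, role = "C", tau = tau, D = D, normalization = nt,
                  demeaned = demean_response,
                  dt = stimulus$dt, sigma = stimulus$sigma)
  })
  if (drop && length(out) == 1L) out[[1L]] else out
}

#' Stimulus covariance over lag windows
#'
#' The unweighted lagged stimulus covariance
#' \deqn{S_{ij} = \frac{1}{T-\tau} \sum_{t=\tau+1}^{T} s_{t-i} s_{t-j},}
#' identical to \code{\link{response_weighted_covariance}} with every
#' response set to 1 and no demeaning. For white noise of standard
#' deviation sigma, S approaches sigma^2 I as T grows.
#'
#' @inheritParams response_weighted_covariance
#' @return A `block_cov` with role `"S"`.
#' @export
stimulus_covariance <- function(stimulus, lags,
                                backend = c("accelerated", "reference")) {
  backend <- match.arg(backend)
  if (!inherits(stimulus, "stimulus_ensemble"))
    stop_validation("stimulus must be a stimulus_ensemble")
  ones <- response_set(matrix(1, nrow(stimulus$values), 1L))
  out <- response_weighted_covariance(stimulus, ones, lags,
                                      demean_response = FALSE,
                                      backend = backend)
  out$role <- "S"
  out
}

#' Second-order Wiener kernel from a response-weighted covariance
#'
#' Rescales a response-weighted covariance C into the second-order
#' Wiener kernel \deqn{K^{(2)} = \frac{C}{2 \sigma^4 \Delta t^2}} valid
#' for Gaussian white-noise stimulation of standard deviation sigma and
#' sampling interval dt. The proportionality between C and the Wiener
#' kernel requires a zero-mean response, so `cov` must have been computed
#' with `demean_response = TRUE`; a non-demeaned input is refused.
#'
#' @param cov A `block_cov` with role `"C"`, computed with response
#'   demeaning.
#' @param sigma Stimulus standard deviation (default: recorded on `cov`).
#' @param dt Sampling interval (default: recorded on `cov`).
#' @return A `block_cov` with role `"K2"`.
#' @export
wiener_kernel <- function(cov, sigma = cov$sigma, dt = cov$dt) {
  if (!inherits(cov, "block_cov") || cov$role != "C")
    stop_validation("cov must be a block_cov with role 'C'")
  if (!isTRUE(cov$demeaned))
    stop_validation(paste("Wiener rescaling requires a zero-mean response:",
                          "recompute the covariance with demean_response = TRUE"))
  sigma <- check_positive_scalar(sigma, "sigma")
  dt <- check_positive_scalar(dt, "dt")
  out <- cov
  out$matrix <- cov$matrix / (2 * sigma^4 * dt^2)
  out$role <- "K2"
  out$sigma <- sigma
  out$dt <- dt
  out
}

#' Numerical equivalence of the two covariance backends
#'
#' Computes the response-weighted covariance with both the reference
#' (explicit triple loop) and the accelerated (vectorized) backend and
#' returns the largest relative entrywise discrepancy across all response
#' columns (absolute discrepancy scaled by the largest absolute reference
#' entry; 0 when the reference is identically zero). The two backends are
#' contracted to agree to 1e-10 or better.
#'
#' @inheritParams response_weighted_covariance
#' @return A single non-negative number.
#' @export
backend_equivalence <- function(stimulus, responses, lags,
                                demean_response = FALSE) {
  ref <- response_weighted_covariance(stimulus, responses, lags,
                                      demean_response = demean_response,
                                      backend = "reference", drop = FALSE)
  acc <- response_weighted_covariance(stimulus, responses, lags,
                                      demean_response = demean_response,
                                      backend = "accelerated", drop = FALSE)
  worst <- 0
  for (k in seq_along(ref)) {
    scale <- max(abs(ref[[k]]$matrix))
    d <- max(abs(ref[[k]]$matrix - acc[[k]]$matrix))
    worst <- max(worst, if (scale > 0) d / scale else d)
  }
  worst
}
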