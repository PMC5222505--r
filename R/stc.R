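#' Spike-triggered average
#'
#' The spike-count-weighted mean stimulus window,
#' \deqn{a = \frac{1}{n_r} \sum_{t=\tau+1}^{T} r_t s_t,}
#' where \eqn{s_t} is the complete lag-window vector preceding bin t
#' (dim-major, lag-minor layout) and \eqn{n_r = \sum_t r_t} is the total
#' spike count over the summed bins. Only bins with a full window enter
#' both sums, matching the covariance estimators.
#'
#' @param stimulus A \code{\link{stimulus_ensemble}}.
#' @param spikes A \code{\link{response_set}} in `"spike-counts"` mode;
#'   if it has several columns, `column` selects one.
#' @param lags A \code{\link{lag_window}} or bare tau.
#' @param column Response column to use (default 1).
#' @return An object of class `sta` with fields `a` (length D*L vector),
#'   `n_r`, `tau`, `D`.
#' @examples
#' s <- stimulus_ensemble(c(1, 2, 3, 4))
#' r <- response_set(c(0, 0, 1, 2), mode = "spike-counts")
#' spike_triggered_average(s, r, 1)$a  # c(11/3, 8/3)
#' @export
spike_triggered_average <- function(stimulus, spikes, lags, column = 1L) {
  lags <- check_pair(stimulus, spikes, lags)
  if (spikes$mode != "spike-counts")
    stop_validation("spike_triggered_average requires a spike-counts response_set")
  r <- spikes$values[(lags$tau + 1L):nrow(spikes$values), column]
  n_r <- sum(r)
  if (n_r == 0) stop_degenerate("no spikes in the summed window (n_r = 0)")
  X <- lagged_design(stimulus, lags)
  a <- as.numeric(crossprod(X, r)) / n_r
  structure(list(a = a, n_r = n_r, tau = lags$tau, D = ncol(stimulus$values)),
            class = "sta")
}

#' Raw spike-triggered covariance (C0)
#'
#' Combines a response-weighted covariance (computed on raw spike counts,
#' no demeaning) with the stimulus covariance:
#' \deqn{C_0 = \frac{T-\tau}{n_r} C - S,}
#' the covariance of spike-preceding stimulus windows relative to the
#' baseline stimulus covariance. A unit response (one "spike" per bin)
#' gives C0 = 0 exactly, and scaling all counts by a constant leaves C0
#' unchanged.
#'
#' @param C `block_cov` with role `"C"`, computed without demeaning.
#' @param S `block_cov` with role `"S"` from the same stimulus and tau.
#' @param n_r Total spike count over the summed window.
#' @return A `block_cov` with role `"C0"`.
#' @export
stc_raw <- function(C, S, n_r) {
  if (!inherits(C, "block_cov") || C$role != "C")
    stop_validation("C must be a block_cov with role 'C'")
  if (!inherits(S, "block_cov") || S$role != "S")
    stop_validation("S must be a block_cov with role 'S'")
  if (isTRUE(C$demeaned))
    stop_validation("C0 is defined for raw (non-demeaned) spike counts")
  if (!identical(dim(C$matrix), dim(S$matrix)) || C$tau != S$tau)
    stop_dimension("C and S shapes/lags differ")
  if (n_r <= 0) stop_degenerate("n_r must be positive (no spikes)")
  out <- C
  out$matrix <- (C$normalization / n_r) * C$matrix - S$matrix
  out$role <- "C0"
  out
}

as_cov_matrix <- function(M) {
  if (inherits(M, "block_cov")) M$matrix else as.matrix(M)
}

sta_vector <- function(sta) {
  if (inherits(sta, "sta")) sta$a else as.numeric(sta)
}

#' STA-subtracted spike-triggered covariance (C1)
#'
#' The STC variant in which the STA is subtracted from each stimulus
#' window before computing covariance; algebraically
#' \deqn{C_1 = C_0 - a a^T.}
#'
#' @param C0 Raw STC matrix (`block_cov` or plain matrix).
#' @param sta An `sta` object or bare numeric vector.
#' @return A `block_cov` with role `"C1"` (plain matrix in, plain matrix out).
#' @export
stc_sta_subtracted <- function(C0, sta) {
  a <- sta_vector(sta)
  M <- as_cov_matrix(C0)
  if (length(a) != nrow(M)) stop_dimension("STA length does not match C0")
  out_m <- M - tcrossprod(a)
  if (inherits(C0, "block_cov")) {
    out <- C0; out$matrix <- out_m; out$role <- "C1"; out
  } else out_m
}

#' STA-projected spike-triggered covariance (C2)
#'
#' The STC variant in which the component of every stimulus window along
#' the STA is removed before computing covariance. With the normalized
#' STA projector \eqn{A' = a a^T / (a^T a)}, this simplifies to
#' \deqn{C_2 = (I - A')\, C_0\, (I - A')^T,}
#' so C2 annihilates the STA direction (C2 a = 0) and the STA itself is
#' carried separately as an additional filter for subspace analysis.
#'
#' @inheritParams stc_sta_subtracted
#' @return A `block_cov` with role `"C2"` (plain matrix in, plain matrix out).
#' @export
stc_sta_projected <- function(C0, sta) {
  a <- sta_vector(sta)
  M <- as_cov_matrix(C0)
  if (length(a) != nrow(M)) stop_dimension("STA length does not match C0")
  nrm2 <- sum(a^2)
  if (nrm2 == 0) stop_degenerate("zero STA: projector undefined")
  P <- diag(length(a)) - tcrossprod(a) / nrm2
  out_m <- P %*% M %*% t(P)
  out_m <- (out_m + t(out_m)) / 2
  if (inherits(C0, "block_cov")) {
    out <- C0; out$matrix <- out_m; out$role <- "C2"; out
  } else out_m
}

#' All spike-triggered covariance variants in one pass
#'
#' Computes C (raw response-weighted covariance), S, the STA, and the
#' three STC matrices C0, C1 = C0 - aa^T and C2 = (I-A')C0(I-A')^T for a
#' spike-count response.
#'
#' @inheritParams spike_triggered_average
#' @param backend Covariance backend, see
#'   \code{\link{response_weighted_covariance}}.
#' @return An object of class `stc_result` with fields `C0`, `C1`, `C2`
#'   (plain matrices), `sta`, `A` (= aa^T), `A_prime` (= aa^T / a^Ta),
#'   `S`, `tau`, `D`.
#' @export
stc_matrices <- function(stimulus, spikes, lags, column = 1L,
                         backend = c("accelerated", "reference")) {
  backend <- match.arg(backend)
  lags <- check_pair(stimulus, spikes, lags)
  one <- response_set(spikes$values[, column, drop = FALSE], mode = spikes$mode)
  C <- response_weighted_covariance(stimulus, one, lags, backend = backend)
  S <- stimulus_covariance(stimulus, lags, backend = backend)
  sta <- spike_triggered_average(stimulus, spikes, lags, column = column)
  C0 <- stc_raw(C, S, sta$n_r)
  a <- sta$a
  structure(list(C0 = C0$matrix,
                 C1 = stc_sta_subtracted(C0$matrix, a),
                 C2 = stc_sta_projected(C0$matrix, a),
                 sta = sta,
                 A = tcrossprod(a),
                 A_prime = tcrossprod(a) / sum(a^2),
                 S = S$matrix,
                 tau = lags$tau, D = ncol(stimulus$values)),
            class = "stc_result")
}

#' Eigendecomposition of a symmetric STC/kernel matrix
#'
#' Real symmetric eigendecomposition with a deterministic presentation:
#' eigenvalues sorted descending, orthonormal eigenvectors, and each
#' vector's sign fixed so that its largest-magnitude component (lowest
#' index on ties) is positive.
#'
#' @param M Symmetric numeric matrix (or `block_cov`).
#' @param tol Relative asymmetry tolerance (default 1e-8).
#' @return List with `values` (descending) and `vectors` (columns).
#' @export
eigendecompose <- function(M, tol = 1e-8) {
  M <- as_cov_matrix(M)
  if (nrow(M) != ncol(M)) stop_dimension("matrix must be square")
  scale <- max(abs(M), 1e-300)
  if (max(abs(M - t(M))) > tol * scale)
    stop_validation("matrix is not symmetric within tolerance")
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  V <- e$vectors
  for (k in seq_len(ncol(V))) {
    lead <- which.max(abs(V[, k]))  # lowest index wins ties
    if (V[lead, k] < 0) V[, k] <- -V[, k]
  }
  list(values = e$values, vectors = V)
}

# recompute the requested STC variant for one (possibly shifted) spike
# train, reusing the precomputed design matrix and stimulus covariance
stc_variant_spectrum <- function(X, Smat, r_win, nt, variant) {
  n_r <- sum(r_win)
  if (n_r == 0) return(rep(0, ncol(X)))
  C <- rwc_fast_one(X, r_win, nt)
  C0 <- (nt / n_r) * C - Smat
  M <- switch(variant,
    C0 = C0,
    C1 = {
      a <- as.numeric(crossprod(X, r_win)) / n_r
      C0 - tcrossprod(a)
    },
    C2 = {
      a <- as.numeric(crossprod(X, r_win)) / n_r
      nrm2 <- sum(a^2)
      if (nrm2 == 0) C0 else {
        P <- diag(length(a)) - tcrossprod(a) / nrm2
        P %*% C0 %*% t(P)
      }
    })
  eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
}

#' Time-shift null ensemble of STC eigenspectra
#'
#' Builds the null distribution used to assess eigenvalue significance:
#' the response is circularly time-shifted relative to the stimulus by
#' `n_shifts` distinct offsets (drawn uniformly, seeded, from
#' `min_shift..T-min_shift`), decorrelating stimulus and response while
#' preserving each signal's own autocorrelation, and the chosen STC
#' variant is recomputed for every shift. Shifts must exceed the filter
#' window (`min_shift > tau`), otherwise residual stimulus-response
#' correlation would leak into the null.
#'
#' @inheritParams spike_triggered_average
#' @param n_shifts Ensemble size (>= 2); 1000 is a reasonable default,
#'   heavier analyses use 10000.
#' @param min_shift Smallest allowed |shift| (must exceed tau).
#' @param seed Integer seed for the shift draw.
#' @param variant Which matrix to recompute: `"C0"`, `"C1"` or `"C2"`.
#' @return An object of class `null_ensemble` with fields `shifts`,
#'   `spectra` (n_shifts x D*L matrix, rows sorted descending), `seed`,
#'   `variant`, `tau`.
#' @export
shift_null_ensemble <- function(stimulus, spikes, lags, n_shifts = 1000L,
                                min_shift = NULL, seed = 1L,
                                variant = c("C0", "C1", "C2"), column = 1L) {
  variant <- match.arg(variant)
  lags <- check_pair(stimulus, spikes, lags)
  n_shifts <- check_count(n_shifts, "n_shifts", min = 2L)
  T <- nrow(stimulus$values)
  if (is.null(min_shift)) min_shift <- lags$tau + 1L
  min_shift <- check_count(min_shift, "min_shift", min = 1L)
  if (min_shift <= lags$tau)
    stop_validation("min_shift must exceed tau (shift must clear the filter window)")
  pool <- min_shift:(T - min_shift)
  if (length(pool) < n_shifts)
    stop_validation("response too short for the requested number of distinct shifts")
  shifts <- with_seed(seed, sample(pool, n_shifts, replace = FALSE))

  X <- lagged_design(stimulus, lags)
  nt <- T - lags$tau
  Smat <- rwc_fast_one(X, rep(1, nt), nt)
  r_full <- spikes$values[, column]
  rows <- (lags$tau + 1L):T
  spectra <- matrix(0, n_shifts, ncol(X))
  for (m in seq_len(n_shifts)) {
    idx <- ((seq_len(T) - 1L + shifts[m]) %% T) + 1L
    spectra[m, ] <- stc_variant_spectrum(X, Smat, r_full[idx][rows], nt, variant)
  }
  structure(list(shifts = as.integer(shifts), spectra = spectra,
                 seed = as.integer(seed), variant = variant, tau = lags$tau),
            class = "null_ensemble")
}

#' Flag significant eigenvalues against a shift-null ensemble
#'
#' Compares an observed eigenspectrum (sorted descending) with the
#' spectra of a \code{\link{shift_null_ensemble}}. Two band constructions
#' are available:
#'
#' * `"global"` (default): an eigenvalue is significant when it exceeds
#'   the upper `1-alpha/2` empirical quantile of the *largest* null
#'   eigenvalues, or falls below the `alpha/2` quantile of the *smallest*
#'   null eigenvalues. This extreme-value band is the standard STC
#'   practice and is robust to rank displacement: when genuine filters
#'   occupy the top ranks, the remaining noise eigenvalues shift down in
#'   rank and would otherwise be compared against too-narrow bands.
#' * `"rank"`: each rank-k observed eigenvalue is compared with the
#'   `[alpha/2, 1-alpha/2]` empirical quantiles of the rank-k null
#'   eigenvalues.
#'
#' @param values Observed eigenvalues, sorted descending (or the list
#'   returned by \code{\link{eigendecompose}}).
#' @param null A `null_ensemble`.
#' @param alpha Two-sided significance level (default 0.05).
#' @param method `"global"` or `"rank"` band construction.
#' @return Logical mask, one flag per eigenvalue, with the band stored in
#'   attributes `null_low` / `null_high`.
#' @export
significant_eigenvalues <- function(values, null, alpha = 0.05,
                                    method = c("global", "rank")) {
  method <- match.arg(method)
  if (is.list(values)) values <- values$values
  if (!inherits(null, "null_ensemble") || nrow(null$spectra) < 1L)
    stop_validation("null must be a non-empty null_ensemble")
  if (length(values) != ncol(null$spectra))
    stop_dimension("observed spectrum and null spectra lengths differ")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop_validation("alpha must be in (0, 1]")
  m <- length(values)
  if (method == "rank") {
    lo <- apply(null$spectra, 2L, stats::quantile, probs = alpha / 2, names = FALSE)
    hi <- apply(null$spectra, 2L, stats::quantile, probs = 1 - alpha / 2, names = FALSE)
  } else {
    hi <- rep(stats::quantile(null$spectra[, 1L], 1 - alpha / 2, names = FALSE), m)
    lo <- rep(stats::quantile(null$spectra[, m], alpha / 2, names = FALSE), m)
  }
  sig <- values > hi | values < lo
  attr(sig, "null_low") <- lo
  attr(sig, "null_high") <- hi
  sig
}

#' Eigenspectrum report with shift-null significance
#'
#' Convenience wrapper: eigendecomposes an STC matrix and flags its
#' significant eigenvalues against a time-shift null ensemble.
#'
#' @param M Symmetric STC matrix (or `block_cov`).
#' @param null A \code{\link{shift_null_ensemble}} for the same variant.
#' @param alpha Two-sided significance level.
#' @param method Band construction, see
#'   \code{\link{significant_eigenvalues}}.
#' @return An object of class `eigen_report` with fields `values`,
#'   `vectors`, `null_low`, `null_high`, `significant`, `alpha`, `method`.
#' @export
eigen_report <- function(M, null, alpha = 0.05, method = c("global", "rank")) {
  method <- match.arg(method)
  e <- eigendecompose(M)
  sig <- significant_eigenvalues(e$values, null, alpha = alpha, method = method)
  structure(list(values = e$values, vectors = e$vectors,
                 null_low = attr(sig, "null_low"),
                 null_high = attr(sig, "null_high"),
                 significant = as.logical(sig),
                 alpha = alpha, method = method),
            class = "eigen_report")
}

#' Subspace recovery quality of extracted filters
#'
#' Measures how well each true input filter is spanned by a set of
#' recovered vectors (typically the significant STC eigenvectors; for C2
#' analyses append the STA as an extra vector). Each filter is projected
#' onto the span of the vectors by least squares and the cosine
#' similarity between filter and projection is returned; 1 means the
#' filter lies in the recovered subspace, 0 means it is orthogonal to it.
#'
#' @param vectors Numeric matrix, one recovered vector per column.
#' @param filters Numeric matrix, one true filter per column (or vector).
#' @return Numeric vector of cosine similarities, one per filter.
#' @export
filter_subspace_check <- function(vectors, filters) {
  if (is.vector(vectors)) vectors <- matrix(vectors, ncol = 1L)
  if (is.vector(filters)) filters <- matrix(filters, ncol = 1L)
  if (ncol(vectors) == 0L) stop_validation("empty recovered-vector set")
  if (nrow(vectors) != nrow(filters))
    stop_dimension("vectors and filters must share length D*L")
  qrV <- qr(vectors)
  Q <- qr.Q(qrV)[, seq_len(qrV$rank), drop = FALSE]
  vapply(seq_len(ncol(filters)), function(k) {
    f <- filters[, k]
    p <- Q %*% crossprod(Q, f)
    np <- sqrt(sum(p^2)); nf <- sqrt(sum(f^2))
    if (np == 0 || nf == 0) 0 else as.numeric(crossprod(f, p)) / (nf * np)
  }, numeric(1L))
}
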