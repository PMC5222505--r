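# Shared fixtures. The 4-sample pair is small enough to hand-evaluate
# every estimator; its expected values below are exact fractions obtained
# by brute-force evaluation of the defining sums (see brute_rwc).

worked_pair <- function() {
  list(stimulus = stimulus_ensemble(c(1, 2, 3, 4)),
       spikes = response_set(c(0, 0, 1, 2), mode = "spike-counts"),
       tau = 1L)
}

worked_expected <- list(
  C = matrix(c(41, 30, 30, 22) / 3, 2, 2),
  S = matrix(c(29, 20, 20, 14) / 3, 2, 2),
  a = c(11, 8) / 3,
  n_r = 3,
  C0 = matrix(c(36, 30, 30, 24) / 9, 2, 2),
  C1 = matrix(c(-85, -58, -58, -40) / 9, 2, 2)
)

# Independent pure-R brute-force oracle for the response-weighted
# covariance: a literal triple loop over the defining sum, written
# without the lagged-design representation used by the package.
brute_rwc <- function(s, r, tau, demean = FALSE) {
  s <- as.matrix(s)
  T <- nrow(s); D <- ncol(s); L <- tau + 1L
  if (demean) r <- r - mean(r[(tau + 1):T])
  n <- D * L
  M <- matrix(0, n, n)
  for (d1 in 1:D) for (i in 0:tau) for (d2 in 1:D) for (j in 0:tau) {
    acc <- 0
    for (t in (tau + 1):T) acc <- acc + r[t] * s[t - i, d1] * s[t - j, d2]
    M[(d1 - 1) * L + i + 1, (d2 - 1) * L + j + 1] <- acc / (T - tau)
  }
  M
}

# stimulus window vector at bin t (dim-major, lag-minor), for oracles
window_vec <- function(s, t, tau) {
  s <- as.matrix(s)
  as.vector(vapply(seq_len(ncol(s)), function(d) s[t:(t - tau), d],
                   numeric(tau + 1)))
}

random_pair <- function(seed, T = NULL, D = NULL, tau = NULL, spiking = TRUE) {
  set.seed(seed)
  if (is.null(T)) T <- sample(64:512, 1)
  if (is.null(D)) D <- sample(1:3, 1)
  if (is.null(tau)) tau <- sample(0:7, 1)
  st <- stimulus_ensemble(matrix(rnorm(T * D), T, D))
  r <- if (spiking) rpois(T, 0.3) else rnorm(T)
  rs <- response_set(r, mode = if (spiking) "spike-counts" else "continuous")
  list(stimulus = st, responses = rs, tau = tau, T = T, D = D)
}

expect_rel_equal <- function(object, expected, tol = 1e-10) {
  scale <- max(abs(expected), 1e-300)
  expect_lt(max(abs(object - expected)) / scale, tol)
}
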