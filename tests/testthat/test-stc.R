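test_that("spike-triggered average matches hand-derived and single-spike cases", {
  p <- worked_pair()
  a <- spike_triggered_average(p$stimulus, p$spikes, p$tau)
  expect_equal(a$a, worked_expected$a, tolerance = 1e-14)
  expect_equal(a$n_r, worked_expected$n_r)

  # a single spike picks out exactly its stimulus window
  set.seed(4)
  s <- rnorm(30)
  r <- rep(0, 30); r[17] <- 1
  a1 <- spike_triggered_average(stimulus_ensemble(s),
                                response_set(r, mode = "spike-counts"), 4)
  expect_equal(a1$a, s[17:13], tolerance = 1e-14)

  expect_error(spike_triggered_average(stimulus_ensemble(s),
                                       response_set(rep(0, 30), mode = "spike-counts"),
                                       4),
               class = "stcov_degenerate_error")
  expect_error(spike_triggered_average(stimulus_ensemble(s),
                                       response_set(r, mode = "continuous"), 4),
               class = "stcov_validation_error")
})

test_that("raw STC combines C and S as (T-tau)/n_r * C - S", {
  p <- worked_pair()
  res <- stc_matrices(p$stimulus, p$spikes, p$tau)
  expect_equal(res$C0, worked_expected$C0, tolerance = 1e-13)

  # unit response: spike-weighted and plain covariance coincide, C0 = 0
  st <- stimulus_ensemble(rnorm(200))
  ones <- response_set(rep(1, 200), mode = "spike-counts")
  res1 <- stc_matrices(st, ones, 5)
  expect_equal(res1$C0, matrix(0, 6, 6), tolerance = 1e-13)

  # doubling every spike count leaves C0 unchanged
  set.seed(8)
  r <- rpois(200, 0.4); r[which.max(r == 0)] <- 1
  sp <- response_set(r, mode = "spike-counts")
  sp2 <- response_set(2 * r, mode = "spike-counts")
  expect_rel_equal(stc_matrices(st, sp, 5)$C0, stc_matrices(st, sp2, 5)$C0,
                   tol = 1e-12)

  C <- response_weighted_covariance(st, sp, 5)
  S <- stimulus_covariance(st, 5)
  expect_error(stc_raw(C, S, 0), class = "stcov_degenerate_error")
  Cd <- response_weighted_covariance(st, sp, 5, demean_response = TRUE)
  expect_error(stc_raw(Cd, S, 10), class = "stcov_validation_error")
})

test_that("C1 = C0 - aa^T matches its definitional (window-subtraction) form", {
  p <- worked_pair()
  res <- stc_matrices(p$stimulus, p$spikes, p$tau)
  expect_equal(res$C1, worked_expected$C1, tolerance = 1e-13)
  expect_equal(stc_sta_subtracted(res$C0, rep(0, 2)), res$C0)

  # independent oracle: (1/n_r) sum r_t (s_t - a)(s_t - a)^T - S
  for (seed in 1:5) {
    rp <- random_pair(seed + 40)
    r <- rp$responses$values[, 1]
    if (sum(r[(rp$tau + 1):rp$T]) == 0) next
    res <- stc_matrices(rp$stimulus, rp$responses, rp$tau)
    a <- res$sta$a
    n <- length(a)
    M <- matrix(0, n, n); S <- matrix(0, n, n)
    for (t in (rp$tau + 1):rp$T) {
      x <- window_vec(rp$stimulus$values, t, rp$tau)
      M <- M + r[t] * tcrossprod(x - a)
      S <- S + tcrossprod(x)
    }
    C1_def <- M / res$sta$n_r - S / (rp$T - rp$tau)
    expect_rel_equal(res$C1, C1_def, tol = 1e-10)
  }
})

test_that("C2 product form matches the two-term projection-subtraction form and annihilates the STA", {
  for (seed in 1:5) {
    rp <- random_pair(seed + 60)
    r <- rp$responses$values[, 1]
    if (sum(r[(rp$tau + 1):rp$T]) == 0) next
    res <- stc_matrices(rp$stimulus, rp$responses, rp$tau)
    a <- res$sta$a
    n <- length(a)

    # oracle: subtract b_t = a (a.s_t)/(a.a) from every window, then form
    # both covariance terms directly
    M <- matrix(0, n, n); S <- matrix(0, n, n)
    for (t in (rp$tau + 1):rp$T) {
      x <- window_vec(rp$stimulus$values, t, rp$tau)
      y <- x - a * sum(a * x) / sum(a * a)
      M <- M + r[t] * tcrossprod(y)
      S <- S + tcrossprod(y)
    }
    C2_def <- M / res$sta$n_r - S / (rp$T - rp$tau)
    expect_rel_equal(res$C2, C2_def, tol = 1e-10)

    # C2 a = 0 and the projector is symmetric + idempotent
    expect_lt(max(abs(res$C2 %*% a)),
              1e-10 * max(abs(res$C2)) * sqrt(sum(a^2)))
    P <- diag(n) - res$A_prime
    expect_rel_equal(P %*% P, P, tol = 1e-10)
    expect_identical(res$A_prime, t(res$A_prime))
  }

  # STA along the first basis vector zeroes the first row/column
  C0 <- matrix(c(4, 1, 1, 3), 2, 2)
  C2 <- stc_sta_projected(C0, c(2, 0))
  expect_equal(C2[1, ], c(0, 0)); expect_equal(C2[, 1], c(0, 0))
  expect_error(stc_sta_projected(C0, c(0, 0)), class = "stcov_degenerate_error")
})

test_that("eigendecomposition sorts descending, fixes signs, and validates symmetry", {
  e <- eigendecompose(diag(c(3, 1, 2)))
  expect_equal(e$values, c(3, 2, 1))
  e2 <- eigendecompose(matrix(c(2, 1, 1, 2), 2, 2))
  expect_equal(e2$values, c(3, 1))
  expect_equal(abs(e2$vectors), matrix(1 / sqrt(2), 2, 2), tolerance = 1e-12)
  # sign convention: largest-magnitude component positive
  set.seed(5)
  M <- crossprod(matrix(rnorm(49), 7, 7))
  V <- eigendecompose(M)$vectors
  for (k in 1:7) expect_gt(V[which.max(abs(V[, k])), k], 0)
  expect_rel_equal(crossprod(V), diag(7), tol = 1e-10)
  expect_error(eigendecompose(matrix(c(1, 2, 0, 1), 2, 2)),
               class = "stcov_validation_error")
})

test_that("shift-null ensembles are seeded, decorrelating, and validated", {
  rp <- random_pair(71, T = 400, D = 1, tau = 4)
  n1 <- shift_null_ensemble(rp$stimulus, rp$responses, rp$tau, n_shifts = 20,
                            seed = 9, variant = "C1")
  n2 <- shift_null_ensemble(rp$stimulus, rp$responses, rp$tau, n_shifts = 20,
                            seed = 9, variant = "C1")
  expect_identical(n1$shifts, n2$shifts)
  expect_identical(n1$spectra, n2$spectra)
  expect_false(any(duplicated(n1$shifts)))
  expect_true(all(n1$shifts > rp$tau))
  # rows sorted descending
  expect_true(all(apply(n1$spectra, 1, function(z) all(diff(z) <= 0))))

  # zero response: every shifted kernel is the zero matrix
  z <- response_set(rep(0, 400), mode = "spike-counts")
  nz <- shift_null_ensemble(rp$stimulus, z, rp$tau, n_shifts = 5, seed = 2)
  expect_identical(unique(as.vector(nz$spectra)), 0)

  expect_error(shift_null_ensemble(rp$stimulus, rp$responses, rp$tau,
                                   n_shifts = 20, min_shift = rp$tau, seed = 1),
               class = "stcov_validation_error")
  expect_error(shift_null_ensemble(rp$stimulus, rp$responses, rp$tau,
                                   n_shifts = 1, seed = 1),
               class = "stcov_validation_error")
})

test_that("significance flags respect the null band in degenerate cases", {
  rp <- random_pair(81, T = 400, D = 1, tau = 3)
  null <- shift_null_ensemble(rp$stimulus, rp$responses, rp$tau,
                              n_shifts = 101, seed = 3, variant = "C1")
  med <- apply(null$spectra, 2, stats::median)
  for (m in c("global", "rank")) {
    expect_false(any(significant_eigenvalues(med, null, alpha = 0.05, method = m)))
    expect_true(all(significant_eigenvalues(med + 1e3, null, alpha = 1, method = m)))
  }
  expect_error(significant_eigenvalues(med[-1], null, 0.05),
               class = "stcov_dimension_error")
  expect_error(significant_eigenvalues(med, null, 0), class = "stcov_validation_error")
})

test_that("subspace check returns 1 for included filters and 0 for orthogonal ones", {
  set.seed(12)
  V <- qr.Q(qr(matrix(rnorm(64), 8, 8)))
  vecs <- V[, 1:3]
  expect_equal(filter_subspace_check(vecs, V[, 2]), 1, tolerance = 1e-12)
  expect_equal(filter_subspace_check(vecs, V[, 5]), 0, tolerance = 1e-12)
  mixed <- 0.6 * V[, 1] + 0.8 * V[, 8]
  expect_equal(filter_subspace_check(vecs, mixed), 0.6, tolerance = 1e-12)
  expect_error(filter_subspace_check(matrix(numeric(0), 8, 0), V[, 1]),
               class = "stcov_validation_error")
  expect_error(filter_subspace_check(vecs, rnorm(5)),
               class = "stcov_dimension_error")
})
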