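---
title: "Second-order Wiener kernels and spike-triggered covariance with stcov"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Second-order Wiener kernels and spike-triggered covariance with stcov}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stcov)
```

## The estimation problem

Sensory neurons are often characterized by how their response depends on
*pairwise products* of recent stimulus values — the quadratic term of a
Wiener/Volterra expansion. Given a stimulus time series `s` (T bins, D
spatial dimensions) and an aligned response `r`, the central object this
package estimates is the response-weighted stimulus covariance

$$C_{ij} = \frac{1}{T-\tau}\sum_{t=\tau+1}^{T} r_t\, s_{t-i}\, s_{t-j},
\qquad i,j = 0,\dots,\tau,$$

a (D·L)×(D·L) symmetric matrix (L = τ+1 lags) organized block-wise per
pair of stimulus dimensions. For Gaussian white-noise stimulation with
standard deviation σ and sampling interval Δt, and a zero-mean response,

$$K^{(2)} = \frac{C}{2\sigma^4 \Delta t^2}$$

is the second-order Wiener kernel: the least-squares-optimal quadratic
description of the system. When the system is *purely* second order (no
higher-order dependence on the stimulus), the Wiener kernel equals the
generating Volterra kernel, which is what the package's kernel-recovery
validation exploits.

The same machinery drives spike-triggered covariance (STC) analysis.
With `r` holding non-negative integer spike counts (not demeaned), and
with the plain stimulus covariance $S$ (the same sum with $r_t \equiv 1$)
and the spike-triggered average $a = \frac{1}{n_r}\sum_t r_t s_t$
($n_r = \sum_t r_t$, window vector $s_t$), the three standard STC
variants are algebraic transformations of $C$:

* raw: $C_0 = \frac{T-\tau}{n_r} C - S$;
* STA-subtracted: $C_1 = C_0 - a a^T$, equivalent to subtracting the STA
  from every stimulus window before computing covariance;
* STA-projected: $C_2 = (I - A') C_0 (I - A')^T$ with
  $A' = a a^T / (a^T a)$, equivalent to removing the component of every
  window along the STA first. $C_2 a = 0$ by construction, so the STA is
  carried alongside $C_2$ as an extra filter.

The significant eigenvectors of these matrices span the space of linear
filters that feed the cell's nonlinearity; individual eigenvectors are
generally *mixtures* of the true filters, but their span is the
recoverable object, and `filter_subspace_check()` quantifies recovery as
the cosine between each true filter and its projection onto that span.

## Estimator conventions

Several conventions are fixed package-wide and recorded in every output:

* **Lags are causal, 0..τ inclusive** (L = τ+1 taps). Sums run over
  t = τ+1..T only — the bins with a complete lag window — with no zero
  padding, and the denominator is the number of summed terms, T−τ. The
  STA and $n_r$ use the same window, which is what makes the
  unit-response identity $C_0 = 0$ exact rather than approximate.
* **Layout is dim-major, lag-minor**: row p = (d−1)·L + i + 1 addresses
  spatial dimension d, lag i. The layout string travels with every
  matrix (`layout = "dim_major_lag_minor"`), since block conventions
  differ between toolboxes.
* **The stimulus is never demeaned or rescaled internally.** σ is a
  declared property of the stimulus (the simulators know it; users of
  recorded data supply their estimate). The estimators operate on raw
  samples.
* **Response demeaning is an explicit flag**, default off.
  `wiener_kernel()` refuses a covariance computed without demeaning,
  because proportionality between $C$ and $K^{(2)}$ requires a zero-mean
  response; STC mode conversely requires raw counts, and `stc_raw()`
  refuses a demeaned $C$. Making both contracts explicit prevents the
  silent misuse each convention invites.
* **Double-precision accumulation** throughout (up to $2^{18}$ and more
  terms per entry).

## Two backends, one contract

`response_weighted_covariance()` has two implementations. The
*reference* backend is a literal triple loop (compiled): one
independent accumulation per matrix entry, directly transcribing the
defining sum. The *accelerated* backend builds the (T−τ)×(D·L) lagged
design matrix X once and computes `crossprod(X, r * X) / (T-τ)` via
BLAS — the same arithmetic reorganized for throughput, and the form that
makes large-T analyses and 1000+-member null ensembles practical on a
desktop. Both are exposed so the fast path can always be checked against
the transparent one: `backend_equivalence()` returns the largest
relative entrywise discrepancy, contracted to ≤ 1e-10, and the test
suite sweeps randomized instances (T ≤ 4096, D ≤ 4, τ ≤ 31) to hold
that contract. Results from either backend are symmetrized as
(M + Mᵀ)/2 to remove BLAS-level round-off asymmetry.

## Eigenvalue significance via time-shift nulls

Noise in a kernel estimate is correlated across entries, so eigenvalue
significance cannot be judged entry-wise. The package builds a null
ensemble by circularly time-shifting the response relative to the
stimulus by `n_shifts` distinct seeded offsets, each larger than τ (and
at most T − min_shift), recomputing the chosen STC variant per shift.
Circular shifting preserves each signal's own autocorrelation while
destroying the stimulus-response relationship, so the ensemble has the
right noise structure for a "no relationship" null. The default
ensemble size is 1000; heavier analyses use 10000, and the package's
own end-to-end validation uses 200 to keep desk-scale runtimes.

Two band constructions are offered by `significant_eigenvalues()`:

* `method = "global"` (default): flag an eigenvalue if it exceeds the
  1−α/2 empirical quantile of the *largest* null eigenvalues or falls
  below the α/2 quantile of the *smallest*. This extreme-value band is
  the standard practice in the STC literature.
* `method = "rank"`: compare the rank-k observed eigenvalue with
  quantiles of the rank-k null eigenvalues.

The global band is the default for a structural reason. When genuine
filters occupy the top ranks of the observed spectrum, every noise
eigenvalue is displaced downward in rank; rank-matched bands then
compare the largest *noise* eigenvalue (observed rank 3, say) against
the null's rank-3 band, which is systematically too narrow, and so
flag spurious eigenvalues at middle ranks. The global band is immune
to this displacement, and the validation suite verifies that it flags
exactly the true filter count on the two-filter cell. The rank band remains
available because it is the sharper calibration check under a pure
null, where no displacement occurs.

A deterministic eigenvector presentation (descending eigenvalues, signs
fixed so each vector's largest-magnitude component — lowest index on
ties — is positive) makes runs comparable across seeds and machines.

## The synthetic model cells

Two simulators generate ground-truth data; they are first-class,
tested code, not test fixtures.

**Pure second-order Volterra cell** (`random_volterra_kernel()` +
`volterra_response()`): $r_t = x_t^T G^{(2)} x_t$ with a seeded random
symmetric unit-Frobenius-norm kernel. Such full-rank kernels are
deliberately harder than the low-rank kernels of real cells. Because
the response has no other stimulus dependence, the demeaned-response
Wiener estimate converges to $G^{(2)}$, and the relative Frobenius
error shrinks like $1/\sqrt{T}$; the validation suite checks
err(T = 2¹⁸) < 0.6 · err(T = 2¹⁶) averaged over 5 seeds, and that the
error at T = 2¹⁸ (D = 1, τ = 15) is below 0.15.

**Two-filter rectified LNP cell** (`lnp_model()` + `lnp_spikes()`): two
orthonormal filters applied to the stimulus window, half-wave
rectified, summed, scaled by a gain, and fed to a Poisson spike
generator (counts may exceed 1 per bin). The filter pair
(`biphasic_filters()`) is a deterministic closed form — two
gamma-difference biphasic impulse responses with fast and slow time
constants, Gram-Schmidt orthogonalized — because subspace recovery is
agnostic to filter shape but tests need a known ground truth.
`calibrate_gain()` inverts the half-normal closed form
$E[\max(0, f \cdot s)] = \sigma \lVert f \rVert / \sqrt{2\pi}$ to hit a
target mean rate; the validation experiments use 0.0045 spikes per bin,
a realistic sparse-firing regime, which at T = 2¹⁸ yields roughly 1200
spikes. For this cell the STA is a mixture of the two filters (for
equal-gain half-rectified filters it points near their sum) and is
therefore not a faithful estimate of either one; C0 and C1 carry two
significant eigenvalues, while C2 — having had the STA direction
projected out — carries one, with the STA itself appended as the second
recovered filter.

What these simulations do *not* emulate: temporally correlated or
non-Gaussian stimuli, refractory or bursty (non-Poisson) spiking,
adaptation, and observation noise on continuous responses. Passing the
validation suite therefore demonstrates estimator correctness under the
white-noise model assumptions, not robustness to their violation; with
correlated stimuli the covariance estimators remain computable but the
Wiener rescaling and the filter-span interpretation no longer hold
without stimulus whitening, which is out of scope.

## Numerical and edge-case policy

* Validation errors (shape mismatch, τ ≥ T, non-finite input,
  min_shift ≤ τ) and degenerate inputs (no spikes, zero STA for the C2
  projector, zero-norm truth kernel) are distinct condition classes;
  the CLI maps them to exit codes 2 and 3.
* A zero response produces a zero covariance, not an error, except
  where a normalization by $n_r$ makes the quantity undefined.
* Matrices are symmetrized after BLAS products; asymmetry beyond 1e-8
  relative in `eigendecompose()` input is rejected rather than silently
  symmetrized away.
* Empirical quantiles use R's default (type 7) interpolation; with the
  default 1000-shift ensemble the band estimates at α = 0.05 are stable
  to well under the eigenvalue noise scale.
* All stochastic operations take explicit integer seeds and restore the
  caller's RNG state; identical (parameters, seed) reproduce results
  bit-for-bit.

## Validation problem sizes

The shipped test suite exercises: randomized backend-equivalence sweeps
(100 instances, T ≤ 4096, D ≤ 4, τ ≤ 31); a 4-sample worked example
whose estimators are hand-derivable as exact fractions; definitional
vs simplified forms of C1 and C2 on random spike trains; kernel
recovery at T = 2¹⁶ and 2¹⁸ over 5 seeds; the two-filter LNP experiment
at T = 2¹⁸ with 200-shift null ensembles over 5 seeds; and a 200-replicate
false-positive calibration of the shift-null test at T = 4096, L = 8.
These sizes were chosen so the whole suite runs in minutes on one core
while leaving each check's statistical power intact;
`scripts/acceptance.R` re-runs the same experiments end to end and
writes the measured quantities as JSON.

## Known limitations

* Second order only: no higher-order kernels, and no information-
  theoretic (iSTAC-style) filter selection or nonlinearity estimation
  after subspace recovery.
* White-noise theory: the Wiener rescaling assumes an uncorrelated
  Gaussian stimulus; no whitening correction is applied.
* The delimited-text + JSON-sidecar interchange favors transparency
  over compactness; very long multi-electrode recordings are better
  generated or held in memory than round-tripped through text.
* The shift-null significance rule is a documented package choice (see
  above); published STC studies vary in how they highlight significant
  eigenvalues, and α should be interpreted per-band-construction.
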