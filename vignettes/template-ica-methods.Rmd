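---
title: "Hierarchical Bayesian template ICA for individual resting-state networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical Bayesian template ICA for individual resting-state networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`bayesrsn` estimates subject-level resting-state networks (RSNs) from
vertex-wise BOLD time series on a cortical surface, by shrinking noisy
individual estimates toward an empirical population prior. This vignette
is the package's own account of the model, its assumptions, the tunable
parameters, the synthetic validation data, and the numerical and design
choices made where more than one reasonable option existed.

## The model and its assumptions

For one subject, after SVD dimension reduction of the T × V run to
`Tr` dimensions, the data at vertex `v` are modeled as

$$y(v) = A\,s(v) + e(v), \qquad e(v) \sim N(0, \sigma^2 I_{T_r}),$$
$$s(v) = \mu_0(v) + \delta(v), \qquad \delta(v) \sim N\!\big(0, \mathrm{diag}\,\sigma_0^2(v)\big),$$

with `A` the `Tr × Q` mixing matrix over the `Q` networks and
`(μ0, σ0²)` a population template. The assumptions that matter:

* **Gaussian residuals.** The model presumes non-Gaussian structured noise
  has been removed upstream (the intended inputs are denoised,
  surface-mapped runs); what remains is treated as isotropic Gaussian.
  `Ω` is modeled as a scalar variance times the identity — the
  residual-variance initialization from the discarded SVD energy is
  scalar, and a full covariance would be poorly identified at `Tr` near
  `Q`.
* **Vertex independence given the parameters.** The prior on `δ` is
  diagonal per vertex with no spatial process across vertices; spatial
  coherence in the output comes only from spatial coherence in `μ0`,
  `σ0²` and the data.
* **Shared time courses across vertices.** One mixing matrix serves all
  vertices of a subject; networks differ by their spatial maps, not by
  vertex-specific dynamics.

The E-step is the exact Gaussian conditional (`posterior_given_params()`),
the M-step the closed-form maximum-likelihood update of `(A, σ²)`; both
are exact, so the marginal log-likelihood is non-decreasing — the package
records it every iteration (`loglik_trace`) together with the per-iteration
ascent of the expected complete-data objective at fixed posterior
(`q_ascent`). Note the expected complete-data log-likelihood evaluated at
successive iterations' *own* posteriors is not guaranteed monotone (its
entropy term changes between iterations); the two recorded quantities are
the forms EM theory does guarantee, and the test suite asserts both.

## The empirical prior

`estimate_template()` implements the test–retest decomposition: each
template subject's run is split into two contiguous pseudo-session halves,
dual regression gives a map estimate per half, and the between-subject
variance is the session-averaged across-subject variance minus half the
across-subject variance of the session difference, clamped at zero.
Choices worth stating:

* Across-subject variances use the unbiased (N−1) denominator; subject
  means are not re-centred per session beyond what the variance takes out.
* Stage-1 dual-regression time courses are variance-normalized before
  stage 2, the standard convention that puts map magnitudes on a common
  scale across subjects and sessions.
* Negative variance differences are clamped to zero: a Gaussian prior
  needs a non-negative variance, and the clamp is reported
  (`print.prior_template` shows the clamped fraction).
* Runs are **not** rescaled to unit mean temporal variance by default
  (`standardize = FALSE` in `reduce_dimension()`): the mixing matrix
  absorbs any global scale of the data, so standardization buys nothing
  for the fit, while native units keep the template variances directly
  interpretable against the data. It remains an option for cohorts with
  grossly different acquisition scales.
* Template subjects should be excluded from downstream subject-level
  analysis; the package keeps template and analysis cohorts as separate
  argument lists rather than enforcing a registry.

A caveat established on simulated data: dual-regression point estimates
from *short* pseudo-sessions are mildly attenuated (the stage-1 time
courses are themselves estimated, and their normalization interacts with
the subject deviations), which biases recovered `σ0²` low by roughly 10%
at 200-frame halves, shrinking to a few percent at 400–800-frame halves.
With ten-minute runs (1600 frames, 800 per half) the decomposition is
unbiased for practical purposes; with much shorter runs the prior variance
is conservative (over-shrinkage toward `μ0`).

## Quality control

* **DVARS** is the root-mean-square across vertices of the
  frame-to-frame intensity difference, first frame 0 by convention — the
  standard backward-difference definition matching "root-mean-squared
  BOLD signal intensity change".
* **Outlier fence**: strictly above `Q75 + 1.5·IQR` of the session's
  DVARS values, with linear-interpolation quantiles (the convention is
  not pinned down elsewhere; this is R's default, and flags are invariant
  to adding a constant to the series either way).
* **Block censoring**: the contiguous window of `block_length` frames
  (default 1600, i.e. ten minutes at TR 0.375 s) with the fewest flags,
  earliest start on ties for determinism; exclusion when strictly more
  than `floor(0.10 · block_length)` in-block outliers — the decision
  flips exactly between 160 and 161 outliers at the defaults.
* **tSNR**: per subject `|temporal mean| / temporal SD` per vertex
  (linear, unitless); the global map is `10·log10` of the across-subject
  arithmetic mean. Zero-variance vertices are reported as undefined, never
  silently dropped. The 17 dB threshold is exposed only as an optional
  display mask (`tsnr_mask()`); no analysis applies it implicitly.
* **Surface smoothing** is iterated combinatorial-Laplacian diffusion
  calibrated so `n·τ·2h²` equals the Gaussian kernel variance
  `σ² = fwhm²/(8 ln 2)` (`h` = mean edge length): exact geodesic kernels
  are expensive, diffusion conserves the map sum exactly on a closed mesh
  and cannot cross a masked-out edge, so disconnected mask components are
  smoothed independently. On a planar grid the resulting kernel matches
  the analytic Gaussian to second moments within ~10% (tested); a FWHM
  below one edge length is not representable and returns the input.

## Inference and group analyses

* The engagement test computes, per network and vertex, the Gaussian
  posterior probability that the network value is ≤ γ, and declares
  engagement when it is ≤ α/m with `m` the number of in-mask vertices —
  a one-sided test with default γ = 0, because "engagement" is a signed
  notion; the Bonferroni family is the vertices within one network's map,
  matching the per-network masks the pipeline outputs. Both γ and the
  family size are arguments.
* Winner-takes-all parcellation uses **unthresholded** t-maps (engagement
  masks are used only for strength summaries); ties take the lowest
  network index for determinism.
* Connectivity strength is the area-weighted mean t within the engagement
  mask; empty masks give flagged-undefined values that are dropped
  listwise per network, never zero-filled.
* Age association: ranks of age and strength are residualized on intercept
  + sex + motion, the residuals correlated (partial Spearman), with the
  two-sided t approximation on `N − 2 − K` degrees of freedom. At cohort
  sizes ≥ 30 this is indistinguishable from exact-permutation p-values at
  the 0.05 level; the classical no-covariate case reduces exactly to
  Spearman's rho and is cross-checked against the direct rank formula in
  the tests. The motion covariate is whatever per-subject summary the user
  supplies; the natural default from this package's QC is the number of
  flagged outlier frames in the retained block.

## The synthetic-data generator

`sample_truth()` draws cohorts with exactly the generative structure the
model assumes, so parameter recovery is well defined:

| Parameter | Default | Meaning |
|---|---|---|
| `noise_sd` | 1 | residual SD (√Ω), BOLD units |
| `age_effect` | 0 | log-amplitude slope per week PMA |
| `between_sd_base` | 0.05 | between-subject SD floor, map units |
| `between_sd_scale` | 0.25 | between-subject SD per unit of \|μ0\| |
| `deviation_fwhm_mm` | 0 | optional spatial smoothing of δ |
| `tr_seconds` | 0.375 | sampling interval (1600 frames = 10 min) |

Group maps are geodesic Gaussian bumps (peak 3) at farthest-point-sampled
centres — the simplest topography giving distinct networks with limited
overlap, since no generative recipe exists for real group-ICA maps. The
between-subject SD is `base + scale·|μ0|`: subjects vary most where a
network is engaged, which also concentrates "high-signal" vertices where
recovery is assessed. Ages are uniform on 37.4–44.8 weeks PMA; the age
effect multiplies a subject's network amplitude by
`exp(age_effect·(age − 41))` — a strength effect, not a topography change,
because the downstream age analysis measures strength. Motion corruption
is an additive global intensity jump whose sign alternates with frame
parity, so consecutive corrupt frames still produce large frame-to-frame
changes and are caught by the DVARS rule.

Mixing time courses are temporally smoothed Gaussian processes,
independent across networks, scaled to unit variance *in expectation*.
An earlier variant normalized each column's realized sample variance to
exactly 1; that pins the sum of the two pseudo-session variances and
makes the session amplitude factors strongly anticorrelated
(r ≈ −0.9 in simulation) — an artifact real time courses do not have,
which inflates the within-subject variance term of the template estimator
by ~25%. Population scaling removes the artifact; realized cross-column
correlations (~0.1 at T = 300) leave dual regression well conditioned.

What the generator does **not** emulate: hemodynamic response shapes,
physiological noise spectra, spatially structured (non-isotropic) scanner
noise, registration error, and topography changes with age. Passing tests
therefore validate the estimators under the model's own assumptions plus
the stated deviations (motion bursts, amplitude–age coupling); they do not
certify behavior under real-data violations such as mis-specified group
maps or structured artifacts.

## Numerical choices and degenerate inputs

* Reduced dimension defaults to `Q + 5` (capped at `T − 1`): headroom for
  noise estimation while keeping `A` well posed.
* EM convergence: maximum relative Frobenius change of `A` and relative
  change of `σ²` below `tol` (default 1e-3), `max_iter` 100;
  non-convergence returns `converged = FALSE` with the trace, only
  non-finite parameters abort.
* The mixing matrix is initialized by regressing the reduced data on the
  template mean (a rough dual regression), variance-normalized; `σ²` from
  the discarded SVD energy, floored at 1e-10.
* Zero prior variances are hard constraints: those components are fixed at
  `μ0` and excluded from the precision inversion, avoiding infinite
  precisions; their posterior SD is 0 and t-scores there are reported
  `NA`.
* `post_sd` is the square root of the marginal posterior variance — the
  "standard error" entering the t-maps.
* Ties: earliest window in censoring, lowest network index in
  winner-takes-all and in frequency-map modes.

## Problem sizes used in validation

The test-suite and acceptance experiments run at desk scale, chosen as the
smallest sizes at which the statistical contracts are comfortably
identified: meshes of 196–625 vertices, Q = 2–4 networks, runs of 80–800
frames, cohorts of 20–200 subjects, 10 replicate cohorts of N = 80 for
age-effect power, 500 replicates for family-wise error and 1000 for the
Spearman type-I rate. The estimators contain nothing size-dependent beyond
these statistical considerations; study-scale inputs (tens of thousands of
vertices, 1600 frames) only change runtime.

## Known limitations

* The vertex-independent prior ignores spatial correlation of subject
  deviations; posterior maps inherit no smoothness guarantee.
* Isotropic `Ω` by design; strongly heteroscedastic residuals would call
  for a diagonal extension.
* The engagement test is marginal per vertex (Bonferroni), not a joint
  excursion-set probability; no FDR alternative is provided.
* Dual-regression-based templates from very short pseudo-sessions
  under-estimate `σ0²` (see above), making the prior conservative.
* The partial Spearman p-value is a t approximation, adequate at N ≥ 30;
  very small cohorts would need exact or permutation inference.
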