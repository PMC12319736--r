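# bayesrsn

Subject-level resting-state networks from surface-based BOLD fMRI via
hierarchical Bayesian template ICA.

## The problem

Resting-state networks (RSNs) are sets of cortical regions whose
spontaneous BOLD fluctuations are temporally coherent. In neonates —
typically scanned asleep, with short usable runs and heavy motion — naive
subject-level estimates such as dual regression are too noisy to study
individual differences. `bayesrsn` implements a surface-based hierarchical
Bayesian alternative: subject network maps are modeled as Gaussian
deviations around an empirical population template, so each subject's
estimate borrows strength from the cohort exactly where the individual data
are weak, while preserving individual topography where the data are
informative. The package targets researchers analysing vertex-wise BOLD
time series on cortical surface meshes who want individual network maps,
parcellations and cohort-level developmental analyses from ~10 minutes of
data per subject.

## The model

For subject *i*, the dimension-reduced data at vertex *v* follow

```
y_i(v) = A_i s_i(v) + e_i(v),      e_i(v) ~ N(0, Ω)
s_i(v) = μ0(v) + δ_i(v),           δ_i(v) ~ N(0, Σ0(v)),  Σ0(v) diagonal
```

where `A_i` is the subject mixing matrix over the `Q` networks, `μ0` is the
population mean map and `σ0,q²(v)` (the diagonal of `Σ0`) the vertex-wise
between-subject variance of network `q`. The template `(μ0, σ0²)` is
estimated empirically: each template subject's run is split into two
pseudo-sessions, dual regression gives noisy map estimates `s_ij`, and

```
μ0        = mean over subjects and sessions of s_ij
σ_tot²    = across-subject variance, averaged over the two sessions
σ_noise²  = ½ · across-subject variance of (s_i2 − s_i1)
σ0²       = max(σ_tot² − σ_noise², 0)
```

Given the template, an EM algorithm fits `(A_i, Ω)` for a new subject; the
E-step is the exact vertex-wise Gaussian conditional, so the output is a
posterior mean and SD map per network. Downstream, `t = mean/SD` maps feed a
one-sided Bayesian engagement test (Bonferroni over in-mask vertices),
winner-takes-all parcellations, area-weighted connectivity strengths, and a
partial Spearman rank correlation of strength with age at scan controlling
for sex and motion. Quality control implements DVARS outlier flagging
(above `Q75 + 1.5·IQR`), retention of the contiguous 1600-frame block with
fewest outliers (exclusion when >10% of the block is corrupted), tSNR maps
in dB, and approximate geodesic Gaussian smoothing on the mesh.

A synthetic-data module (`make_mesh()`, `sample_truth()`, `render_bold()`)
generates surface meshes and multi-subject BOLD data with exactly this
generative structure plus motion bursts and a planted age effect, so every
stage can be validated against known ground truth.

## Worked example

```r
library(bayesrsn)

mesh  <- make_mesh(400, kind = "grid")
truth <- sample_truth(mesh, n_subjects = 30, n_ics = 4, n_timepoints = 300,
                      noise_sd = 2, age_effect = 0.1, seed = 1)

run    <- render_bold(truth, 1, corrupt_frames = 1:25)
censor <- select_block(run, block_length = 200)
censor
#> <censor_result> block frames 27-226 (200 frames), 0 outliers in block, included

template <- prior_template(truth$group_maps, truth$between_var)
post <- fit_template_ica(apply_censor(run, censor), template)
post
#> <subject_posterior> 4 networks x 400 vertices
#>   EM: 36 iterations, converged, residual var 9.186, loglik -9777.48

engagement_test(post, gamma = 0, alpha = 0.05)
#> <engagement_result> 4 networks x 400 vertices; gamma=0, alpha=0.05 (Bonferroni over 400 vertices)
#>   engaged vertices per network: 272, 152, 176, 164

runs <- lapply(1:30, function(i) render_bold(truth, i))
res  <- analyze_cohort(runs, template, mesh, truth_covariates(truth),
                       max_iter = 25)
res$age_table
#> # A tibble: 4 × 5
#>   ic      rho        p p_bonferroni     n
#>   <chr> <dbl>    <dbl>        <dbl> <int>
#> 1 IC1   0.882 5.64e-10     2.26e- 9    30
#> 2 IC2   0.895 1.26e-10     5.03e-10    30
#> 3 IC3   0.848 1.23e- 8     4.93e- 8    30
#> 4 IC4   0.817 1.16e- 7     4.66e- 7    30
res$frequency
#> <frequency_map> 400 vertices, 30 subjects; median agreement 96.7%
```

The censoring step drops the motion-corrupted opening frames and keeps the
cleanest contiguous 200-frame block. The EM fit returns per-network
posterior mean/SD maps; the engagement counts are the vertices whose
posterior credibly exceeds 0 after Bonferroni correction. In the cohort run
the planted amplitude–age effect is recovered in every network (positive
rho, p ≪ 0.05), and the frequency map shows the high inter-subject label
agreement expected at this noise level. `tidy()`, `glance()` and
`autoplot()` methods are available for every result type.

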