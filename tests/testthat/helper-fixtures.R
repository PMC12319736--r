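# Shared small fixtures, built in code.

small_grid <- function(n = 100) make_mesh(n, kind = "grid")

# a tiny cohort truth used across modules
tiny_truth <- function(n_subjects = 5, n_ics = 3, v = 100, t = 80,
                       noise_sd = 1, age_effect = 0, seed = 42) {
  sample_truth(small_grid(v), n_subjects, n_ics, t,
               noise_sd = noise_sd, age_effect = age_effect, seed = seed)
}

# hand-built reduced-data object for EM tests: data generated exactly from
# the model in the reduced space (projection = identity)
model_reduced <- function(A, noise_sd, mu0, sigma0_sq, seed = 1) {
  withr::with_seed(seed, {
    q <- ncol(A); v <- ncol(mu0)
    s <- mu0 + sqrt(sigma0_sq) * matrix(rnorm(q * v), q, v)
    y <- A %*% s + matrix(rnorm(nrow(A) * v, 0, noise_sd), nrow(A), v)
    list(
      reduced = structure(list(y = y, projection = diag(nrow(A)),
                               resid_var0 = noise_sd^2,
                               n_timepoints = nrow(A)),
                          class = "reduced_data"),
      s = s
    )
  })
}

# joint-Gaussian conditioning oracle for the vertex posterior:
# stack (s, y), build the joint covariance, condition numerically
joint_gaussian_posterior <- function(y_v, A, noise_var, mu0_v, sigma0_sq_v) {
  q <- ncol(A); tr <- nrow(A)
  D <- diag(sigma0_sq_v, q)
  Syy <- A %*% D %*% t(A) + noise_var * diag(tr)
  Ssy <- D %*% t(A)
  w <- solve(Syy, y_v - A %*% mu0_v)
  list(mean = drop(mu0_v + Ssy %*% w),
       cov = D - Ssy %*% solve(Syy, t(Ssy)))
}

# exhaustive-scan oracle for the censoring block search
naive_best_block <- function(flags, len) {
  starts <- seq_len(length(flags) - len + 1L)
  counts <- vapply(starts, function(s) sum(flags[s:(s + len - 1L)]),
                   integer(1))
  list(start = starts[which.min(counts)], count = min(counts))
}

# classical Spearman via the direct rank-difference formula (no ties)
spearman_direct <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}
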