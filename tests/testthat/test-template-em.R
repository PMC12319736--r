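test_that("SVD reduction is exact on low-rank data and idempotent on the subspace", {
  a <- withr::with_seed(1, matrix(rnorm(40 * 3), 40, 3))
  s <- withr::with_seed(2, matrix(rnorm(3 * 60), 3, 60))
  y <- a %*% s
  red <- reduce_dimension(y, 3)
  expect_equal(red$resid_var0, 0, tolerance = 1e-10)
  # reconstruction from the retained subspace is exact
  yc <- scale(y, center = TRUE, scale = FALSE)
  expect_equal(t(red$projection) %*% red$y, unclass(yc), tolerance = 1e-8,
               ignore_attr = TRUE)
  # projector property: rows orthonormal, applying twice changes nothing
  expect_equal(red$projection %*% t(red$projection), diag(3), tolerance = 1e-10)
  expect_error(reduce_dimension(y, 40), "below")
})

test_that("white-noise residual variance lands in the simulated band", {
  # Frozen band from direct simulation of the discarded SVD energy for
  # T=100, V=200, k=10 white noise: selection of the top directions makes
  # the residual clearly less than var * (1 - k/T).
  vals <- sapply(1:3, function(s) {
    y <- withr::with_seed(s, matrix(rnorm(100 * 200), 100, 200))
    reduce_dimension(y, 10)$resid_var0
  })
  expect_true(all(vals < 0.9))
  expect_true(all(vals > 0.6))
})

test_that("the vertex posterior matches joint-Gaussian conditioning", {
  for (s in 1:30) {
    withr::with_seed(s, {
      tr <- sample(3:8, 1); q <- sample(2:min(4, tr), 1)
      A <- matrix(rnorm(tr * q), tr, q)
      y <- rnorm(tr)
      mu0 <- rnorm(q)
      d0 <- rexp(q)
      nv <- rexp(1) + 0.1
      got <- posterior_given_params(y, A, nv, mu0, d0)
      want <- joint_gaussian_posterior(y, A, nv, mu0, d0)
      expect_lt(max(abs(got$mean - want$mean)), 1e-8)
      expect_lt(max(abs(got$cov - want$cov)), 1e-8)
    })
  }
})

test_that("degenerate prior variances pin components at the prior mean", {
  A <- withr::with_seed(3, matrix(rnorm(12), 6, 2))
  y <- withr::with_seed(4, rnorm(6))
  res0 <- posterior_given_params(y, A, 1, c(2, -1), c(0, 0))
  expect_equal(res0$mean, c(2, -1))
  expect_equal(res0$cov, matrix(0, 2, 2))
  # mixed: fixed component removed from the data before conditioning
  mixed <- posterior_given_params(y, A, 1, c(2, -1), c(0, 0.5))
  oracle <- joint_gaussian_posterior(y - A[, 1] * 2,
                                     A[, 2, drop = FALSE], 1, -1, 0.5)
  expect_equal(mixed$mean[1], 2)
  expect_equal(mixed$mean[2], oracle$mean, tolerance = 1e-10)
})

test_that("an uninformative likelihood returns the prior", {
  A <- withr::with_seed(5, matrix(rnorm(12), 6, 2))
  y <- withr::with_seed(6, rnorm(6, sd = 5))
  res <- posterior_given_params(y, A, 1e12, c(1, 3), c(0.5, 2))
  expect_equal(res$mean, c(1, 3), tolerance = 1e-4)
  expect_equal(res$cov, diag(c(0.5, 2)), tolerance = 1e-4)
  expect_error(posterior_given_params(y, A, 0, c(1, 3), c(0.5, 2)), "positive")
  expect_error(posterior_given_params(y, A, 1, c(1, 3), c(-1, 2)),
               "non-negative")
})

test_that("EM initialized at the generative parameters stays at the fixed point", {
  A <- withr::with_seed(7, matrix(rnorm(8 * 3), 8, 3))
  mu0 <- withr::with_seed(8, matrix(rnorm(3 * 300), 3, 300))
  d0 <- withr::with_seed(9, matrix(rexp(3 * 300, rate = 2), 3, 300))
  sim <- model_reduced(A, noise_sd = 0.7, mu0, d0, seed = 10)
  tmpl <- prior_template(mu0, d0)
  fit <- em_fit(sim$reduced, tmpl, init_mixing = A, tol = 1e-4,
                max_iter = 200)
  expect_true(fit$converged)
  expect_lt(norm(fit$mixing - A, "F") / norm(A, "F"), 0.15)
  expect_lt(abs(fit$noise_var - 0.49) / 0.49, 0.25)
  # the returned posterior equals the vertex-wise oracle at the final params
  for (j in c(1, 57, 300)) {
    o <- posterior_given_params(sim$reduced$y[, j], fit$mixing,
                                fit$noise_var, mu0[, j], d0[, j])
    expect_equal(fit$post_mean[, j], o$mean, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(fit$post_sd[, j], sqrt(diag(o$cov)), tolerance = 1e-8)
  }
})

test_that("a fully informative prior forces the posterior onto the prior mean", {
  A <- withr::with_seed(11, matrix(rnorm(6 * 2), 6, 2))
  mu0 <- withr::with_seed(12, matrix(rnorm(2 * 50), 2, 50))
  sim <- model_reduced(A, 1, mu0, matrix(0, 2, 50), seed = 13)
  fit <- em_fit(sim$reduced, prior_template(mu0, matrix(0, 2, 50)),
                init_mixing = A, tol = 1e-3, max_iter = 50)
  expect_equal(unname(fit$post_mean), mu0)
  expect_true(all(fit$post_sd == 0))
})

test_that("the marginal log-likelihood and EM objective ascend every iteration", {
  for (s in 1:5) {
    A <- withr::with_seed(s, matrix(rnorm(6 * 2), 6, 2))
    mu0 <- withr::with_seed(s + 50, matrix(rnorm(2 * 60), 2, 60))
    d0 <- withr::with_seed(s + 100, matrix(rexp(2 * 60), 2, 60))
    sim <- model_reduced(A, 1, mu0, d0, seed = s + 150)
    init <- withr::with_seed(s + 200, A + matrix(rnorm(12, sd = 0.5), 6, 2))
    fit <- em_fit(sim$reduced, prior_template(mu0, d0), init,
                  tol = 1e-6, max_iter = 40)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
    expect_true(all(fit$q_ascent >= -1e-8))
  }
})

test_that("posterior SD never exceeds the prior SD (Gaussian conditioning shrinks)", {
  truth <- tiny_truth(n_subjects = 2, n_ics = 3, v = 100, t = 80,
                      noise_sd = 2)
  tmpl <- prior_template(truth$group_maps, truth$between_var)
  fit <- fit_template_ica(render_bold(truth, 1), tmpl)
  prior_sd <- sqrt(truth$between_var)
  ok <- truth$between_var > 0
  expect_true(all(fit$post_sd[ok] <= prior_sd[ok] + 1e-10))
})

test_that("noisier data shrinks the posterior toward the prior mean", {
  mesh <- small_grid(100)
  dist_to_prior <- sapply(c(0.5, 8), function(ns) {
    truth <- sample_truth(mesh, 2, 3, 120, noise_sd = ns, seed = 17)
    tmpl <- prior_template(truth$group_maps, truth$between_var)
    fit <- fit_template_ica(render_bold(truth, 1), tmpl)
    mean(abs(fit$post_mean - truth$group_maps))
  })
  expect_lt(dist_to_prior[2], dist_to_prior[1])
})

test_that("expected complete log-likelihood matches a Monte-Carlo oracle", {
  A <- withr::with_seed(20, matrix(rnorm(4 * 2), 4, 2))
  mu0 <- withr::with_seed(21, matrix(rnorm(2 * 3), 2, 3))
  d0 <- matrix(c(0.5, 1, 2, 0.3, 1.5, 0.8), 2, 3)
  sim <- model_reduced(A, 1, mu0, d0, seed = 22)
  tmpl <- prior_template(mu0, d0)
  mom <- posterior_moments(sim$reduced, tmpl, A, 1)
  got <- expected_complete_loglik(sim$reduced, tmpl, mom, A, 1)
  # oracle: average the complete-data log density over posterior samples
  mc <- withr::with_seed(23, {
    n_mc <- 200000
    total <- 0
    for (j in 1:3) {
      ch <- chol(mom$cov[[j]])
      ss <- matrix(rnorm(n_mc * 2), n_mc, 2) %*% ch +
        matrix(mom$mean[, j], n_mc, 2, byrow = TRUE)
      resid <- matrix(sim$reduced$y[, j], n_mc, 4, byrow = TRUE) -
        ss %*% t(A)
      obs <- -0.5 * (4 * log(2 * pi) + rowSums(resid^2))
      pri <- -0.5 * rowSums(log(2 * pi * matrix(d0[, j], n_mc, 2,
                                                byrow = TRUE)) +
                              sweep(ss, 2, mu0[, j])^2 /
                                matrix(d0[, j], n_mc, 2, byrow = TRUE))
      total <- total + mean(obs + pri)
    }
    total
  })
  expect_equal(got, mc, tolerance = 0.01)
})

test_that("the EM objective is higher at the generative than at perturbed parameters", {
  diffs <- sapply(1:10, function(s) {
    A <- withr::with_seed(s + 300, matrix(rnorm(6 * 2), 6, 2))
    mu0 <- withr::with_seed(s + 350, matrix(rnorm(2 * 40), 2, 40))
    d0 <- withr::with_seed(s + 400, matrix(rexp(2 * 40), 2, 40))
    sim <- model_reduced(A, 1, mu0, d0, seed = s + 450)
    tmpl <- prior_template(mu0, d0)
    mom <- posterior_moments(sim$reduced, tmpl, A, 1)
    pert <- withr::with_seed(s + 500, A + matrix(rnorm(12, sd = 0.6), 6, 2))
    expected_complete_loglik(sim$reduced, tmpl, mom, A, 1) -
      expected_complete_loglik(sim$reduced, tmpl, mom, pert, 1.7)
  })
  expect_gt(mean(diffs), 0)
})

test_that("template-data dimension mismatches and bad inits are rejected", {
  A <- matrix(rnorm(12), 6, 2)
  mu0 <- matrix(rnorm(2 * 20), 2, 20)
  sim <- model_reduced(A, 1, mu0, matrix(1, 2, 20), seed = 30)
  tmpl_bad <- prior_template(mu0[, 1:10], matrix(1, 2, 10))
  expect_error(em_fit(sim$reduced, tmpl_bad, A), "vertices")
  rank1 <- cbind(A[, 1], A[, 1])
  tmpl <- prior_template(mu0, matrix(1, 2, 20))
  expect_error(em_fit(sim$reduced, tmpl, rank1), "full column rank")
})
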