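#' SVD dimension reduction of a BOLD run
#'
#' Centers each vertex's time series and projects the T x V data onto its
#' top `n_components` left singular directions (an orthonormal Tr x T
#' projection), preserving the retained variance exactly. The discarded
#' singular-value energy, averaged over all T x V elements, provides the
#' initial estimate of the isotropic Gaussian residual variance used to
#' start the EM algorithm.
#'
#' @param run A `bold_run` (or T x V matrix).
#' @param n_components Reduced dimension Tr, with Q <= Tr < T.
#' @param standardize If `TRUE`, rescale the centered data to unit mean
#'   temporal variance before reduction (off by default; the mixing matrix
#'   absorbs any global scale, so native units are kept and the template's
#'   variance scale stays interpretable).
#' @return A `reduced_data` object: `y` (Tr x V), `projection` (Tr x T,
#'   orthonormal rows), `resid_var0` (scalar), `n_timepoints`.
#' @export
reduce_dimension <- function(run, n_components, standardize = FALSE) {
  y <- if (inherits(run, "bold_run")) run$data else as.matrix(run)
  tt <- nrow(y)
  n_components <- as.integer(n_components)
  if (n_components >= tt)
    stop("`n_components` must be below the number of timepoints", call. = FALSE)
  if (n_components < 1L) stop("`n_components` must be >= 1", call. = FALSE)

  y <- scale(y, center = TRUE, scale = FALSE)
  if (standardize) {
    msd <- sqrt(mean(apply(y, 2L, stats::var)))
    if (msd > 0) y <- y / msd
  }
  sv <- svd(y, nu = n_components, nv = 0)
  proj <- t(sv$u)
  resid_var0 <- (sum(sv$d^2) - sum(sv$d[seq_len(n_components)]^2)) /
    (tt * ncol(y))
  structure(list(y = proj %*% y, projection = proj,
                 resid_var0 = resid_var0, n_timepoints = tt),
            class = "reduced_data")
}

#' Vertex-wise Gaussian posterior of the network values
#'
#' Exact conjugate update for one vertex of the hierarchical model
#' `y = A s + e`, `e ~ N(0, noise_var I)`, `s ~ N(mu0, diag(sigma0_sq))`:
#' `cov = (Sigma0^-1 + A'A / noise_var)^-1` and
#' `mean = cov (Sigma0^-1 mu0 + A'y / noise_var)`.
#' Components with zero prior variance are held fixed at their prior mean
#' (zero posterior variance and covariance); their contribution `A_f mu0_f`
#' is subtracted from `y` before conditioning the free components.
#'
#' @param y_v Length-Tr data vector at the vertex.
#' @param A Tr x Q mixing matrix.
#' @param noise_var Positive residual variance.
#' @param mu0_v Length-Q prior mean at the vertex.
#' @param sigma0_sq_v Length-Q non-negative prior variances at the vertex.
#' @return List with `mean` (length Q) and `cov` (Q x Q).
#' @export
posterior_given_params <- function(y_v, A, noise_var, mu0_v, sigma0_sq_v) {
  q <- ncol(A)
  stopifnot(length(mu0_v) == q, length(sigma0_sq_v) == q,
            length(y_v) == nrow(A))
  if (any(sigma0_sq_v < 0))
    stop("prior variances must be non-negative", call. = FALSE)
  if (noise_var <= 0) stop("`noise_var` must be positive", call. = FALSE)

  free <- sigma0_sq_v > 0
  m <- as.numeric(mu0_v)
  covm <- matrix(0, q, q)
  if (any(free)) {
    yr <- y_v - if (any(!free)) A[, !free, drop = FALSE] %*% mu0_v[!free] else 0
    Af <- A[, free, drop = FALSE]
    P <- crossprod(Af) / noise_var
    diag(P) <- diag(P) + 1 / sigma0_sq_v[free]
    ch <- tryCatch(chol(P), error = function(e)
      stop("combined posterior precision is singular", call. = FALSE))
    rhs <- mu0_v[free] / sigma0_sq_v[free] +
      drop(crossprod(Af, yr)) / noise_var
    covm[free, free] <- chol2inv(ch)
    m[free] <- drop(covm[free, free, drop = FALSE] %*% rhs)
  }
  list(mean = m, cov = covm)
}

# E-step over all vertices. Returns posterior moments plus the sufficient
# statistics needed by the M-step and the exact marginal log-likelihood
# (via the Woodbury identity, reusing the per-vertex Cholesky factors).
e_step <- function(y, A, noise_var, mu0, sigma0_sq) {
  q <- ncol(A); v <- ncol(y); tr <- nrow(y)
  AtA <- crossprod(A)
  AtY <- crossprod(A, y)
  post_mean <- matrix(0, q, v)
  post_var <- matrix(0, q, v)
  S1 <- matrix(0, tr, q)   # sum_v y_v m_v'
  S2 <- matrix(0, q, q)    # sum_v E[s s']
  loglik <- -0.5 * tr * v * log(2 * pi)
  cov_list <- vector("list", v)
  for (j in seq_len(v)) {
    d <- sigma0_sq[, j]
    free <- d > 0
    m <- mu0[, j]
    covm <- matrix(0, q, q)
    yr <- y[, j] - drop(A %*% ifelse(free, 0, m)) # remove fixed components
    Atyr <- AtY[, j] - drop(AtA %*% ifelse(free, 0, m))
    if (any(free)) {
      P <- AtA[free, free, drop = FALSE] / noise_var
      diag(P) <- diag(P) + 1 / d[free]
      ch <- chol(P)
      rhs <- m[free] / d[free] + Atyr[free] / noise_var
      cf <- chol2inv(ch)
      covm[free, free] <- cf
      m[free] <- drop(cf %*% rhs)
      # marginal loglik of yr ~ N(A_f mu0_f, A_f D_f A_f' + noise_var I)
      r <- yr - drop(A[, free, drop = FALSE] %*% mu0[free, j])
      Atr <- drop(crossprod(A[, free, drop = FALSE], r))
      quad <- sum(r^2) / noise_var -
        drop(crossprod(Atr, cf %*% Atr)) / noise_var^2
      logdet <- tr * log(noise_var) + sum(log(d[free])) +
        2 * sum(log(diag(ch)))
      loglik <- loglik - 0.5 * (logdet + quad)
    } else { # fully informative prior: y ~ N(A mu0, noise_var I)
      r <- y[, j] - drop(A %*% m)
      loglik <- loglik - 0.5 * (tr * log(noise_var) + sum(r^2) / noise_var)
    }
    post_mean[, j] <- m
    post_var[, j] <- diag(covm)
    cov_list[[j]] <- covm
    S1 <- S1 + tcrossprod(y[, j], m)
    S2 <- S2 + covm + tcrossprod(m)
  }
  list(mean = post_mean, var = post_var, cov = cov_list,
       S1 = S1, S2 = S2, loglik = loglik)
}

#' Posterior moments of the network maps at fixed parameters
#'
#' Runs the E-step of the EM algorithm once: for every vertex, the exact
#' Gaussian posterior of the Q network values given the reduced data, a
#' mixing matrix and a residual variance. Also returns the marginal
#' log-likelihood of the data at these parameters.
#'
#' @param reduced A `reduced_data` object.
#' @param template A `prior_template`.
#' @param A Tr x Q mixing matrix.
#' @param noise_var Positive residual variance.
#' @return List with `mean` (Q x V), `var` (Q x V marginal posterior
#'   variances), `cov` (list of V posterior Q x Q covariances), `loglik`.
#' @export
posterior_moments <- function(reduced, template, A, noise_var) {
  stopifnot(inherits(reduced, "reduced_data"),
            inherits(template, "prior_template"))
  es <- e_step(reduced$y, A, noise_var, template$mu0, template$sigma0_sq)
  es[c("mean", "var", "cov", "loglik")]
}

#' Expected complete-data log-likelihood (the EM objective)
#'
#' Evaluates `E[log p(y, s | A, noise_var)]` under the supplied posterior
#' moments, summing the Gaussian observation term and the Gaussian prior
#' term over vertices (components with zero prior variance contribute no
#' prior term; they are constants). The M-step maximizes this quantity over
#' `(A, noise_var)` at fixed posterior, so for any posterior the updated
#' parameters can never decrease it.
#'
#' @param reduced A `reduced_data`.
#' @param template A `prior_template`.
#' @param moments Posterior moments as returned by [posterior_moments()].
#' @param A Tr x Q mixing matrix.
#' @param noise_var Positive residual variance.
#' @return A single number.
#' @export
expected_complete_loglik <- function(reduced, template, moments, A, noise_var) {
  y <- reduced$y
  tr <- nrow(y); v <- ncol(y); q <- ncol(A)
  AtA <- crossprod(A)
  mu0 <- template$mu0; d0 <- template$sigma0_sq
  out <- 0
  for (j in seq_len(v)) {
    m <- moments$mean[, j]
    covm <- moments$cov[[j]]
    Ess <- covm + tcrossprod(m)
    e2 <- sum(y[, j]^2) - 2 * sum(y[, j] * (A %*% m)) + sum(AtA * Ess)
    out <- out - 0.5 * (tr * log(2 * pi * noise_var) + e2 / noise_var)
    free <- d0[, j] > 0
    if (any(free)) {
      dev2 <- diag(Ess)[free] - 2 * m[free] * mu0[free, j] + mu0[free, j]^2
      out <- out - 0.5 * sum(log(2 * pi * d0[free, j]) +
                               dev2 / d0[free, j])
    }
  }
  out
}

#' Fit the hierarchical template-ICA model to one subject by EM
#'
#' Alternates an exact E-step (vertex-wise Gaussian posteriors of the
#' network values at the current mixing matrix and residual variance) with
#' closed-form M-step updates
#' `A <- (sum_v y_v E[s_v]') (sum_v E[s_v s_v'])^-1` and
#' `noise_var <- (1/(Tr V)) sum_v E[ ||y_v - A s_v||^2 ]`,
#' until the maximum relative change of `A` (Frobenius) and `noise_var`
#' falls below `tol` or `max_iter` is reached. The marginal log-likelihood
#' is recorded every iteration; exact EM guarantees it never decreases.
#'
#' @param reduced A `reduced_data` for the subject.
#' @param template A `prior_template` (dimensions must match).
#' @param init_mixing Tr x Q initial mixing matrix (full column rank);
#'   typically a rough dual-regression estimate, see [fit_template_ica()].
#' @param tol Relative-change convergence tolerance (default 1e-3).
#' @param max_iter Maximum EM iterations (default 100).
#' @param noise_var0 Optional initial residual variance; defaults to the
#'   reduction's residual-variance estimate (floored at a tiny positive
#'   value so the likelihood is defined).
#' @return A `subject_posterior`: `post_mean` (Q x V), `post_sd` (Q x V),
#'   `mixing` (Tr x Q), `noise_var`, `n_iterations`, `converged`,
#'   `loglik_trace` (marginal log-likelihood per iteration),
#'   `q_ascent` (per-iteration increase of the EM objective at fixed
#'   posterior, all >= 0 up to round-off), `ic_labels`.
#' @export
em_fit <- function(reduced, template, init_mixing, tol = 1e-3,
                   max_iter = 100L, noise_var0 = NULL) {
  stopifnot(inherits(reduced, "reduced_data"),
            inherits(template, "prior_template"))
  y <- reduced$y
  q <- nrow(template$mu0)
  if (ncol(y) != ncol(template$mu0))
    stop("template and data disagree on the number of vertices", call. = FALSE)
  A <- as.matrix(init_mixing)
  if (nrow(A) != nrow(y) || ncol(A) != q)
    stop("`init_mixing` must be Tr x Q", call. = FALSE)
  if (qr(A)$rank < q)
    stop("`init_mixing` must have full column rank", call. = FALSE)
  noise_var <- if (is.null(noise_var0)) max(reduced$resid_var0, 1e-10)
               else noise_var0
  tr <- nrow(y); v <- ncol(y)
  ytot <- sum(y^2)

  loglik_trace <- numeric(0)
  q_ascent <- numeric(0)
  converged <- FALSE
  it <- 0L
  es <- NULL
  while (it < max_iter) {
    it <- it + 1L
    es <- e_step(y, A, noise_var, template$mu0, template$sigma0_sq)
    loglik_trace <- c(loglik_trace, es$loglik)

    A_new <- t(solve(es$S2, t(es$S1)))
    err <- ytot - 2 * sum(A_new * es$S1) + sum(crossprod(A_new) * es$S2)
    noise_var_new <- max(err / (tr * v), 1e-12)

    if (!all(is.finite(A_new)) || !is.finite(noise_var_new))
      stop(sprintf("EM diverged at iteration %d (non-finite parameters)", it),
           call. = FALSE)

    q_old <- ecll_at(y, es, A, noise_var, template, ytot)
    q_new <- ecll_at(y, es, A_new, noise_var_new, template, ytot)
    q_ascent <- c(q_ascent, q_new - q_old)

    rel_a <- norm(A_new - A, "F") / max(norm(A, "F"), .Machine$double.eps)
    rel_s <- abs(noise_var_new - noise_var) /
      max(noise_var, .Machine$double.eps)
    A <- A_new; noise_var <- noise_var_new
    if (max(rel_a, rel_s) < tol) { converged <- TRUE; break }
  }
  # final posterior at the converged parameters
  es <- e_step(y, A, noise_var, template$mu0, template$sigma0_sq)
  loglik_trace <- c(loglik_trace, es$loglik)

  post_sd <- sqrt(pmax(es$var, 0))
  dimnames(es$mean) <- list(template$ic_labels, NULL)
  structure(list(post_mean = es$mean, post_sd = post_sd, mixing = A,
                 noise_var = noise_var, n_iterations = it,
                 converged = converged, loglik_trace = loglik_trace,
                 q_ascent = q_ascent, ic_labels = template$ic_labels),
            class = "subject_posterior")
}

# EM objective at given params using already-computed sufficient statistics
ecll_at <- function(y, es, A, noise_var, template, ytot) {
  tr <- nrow(y); v <- ncol(y)
  err <- ytot - 2 * sum(A * es$S1) + sum(crossprod(A) * es$S2)
  obs <- -0.5 * (tr * v * log(2 * pi * noise_var) + err / noise_var)
  d0 <- template$sigma0_sq
  free <- d0 > 0
  Ediag <- es$var + es$mean^2 # E[s_q^2] per entry
  dev2 <- Ediag - 2 * es$mean * template$mu0 + template$mu0^2
  pri <- -0.5 * sum(log(2 * pi * d0[free]) + dev2[free] / d0[free])
  obs + pri
}

#' @export
print.subject_posterior <- function(x, ...) {
  cat(sprintf("<subject_posterior> %d networks x %d vertices\n",
              nrow(x$post_mean), ncol(x$post_mean)))
  cat(sprintf("  EM: %d iterations, %s, residual var %.4g, loglik %.2f\n",
              x$n_iterations,
              if (x$converged) "converged" else "NOT converged",
              x$noise_var, utils::tail(x$loglik_trace, 1)))
  invisible(x)
}

#' End-to-end subject fit: reduce, initialize, run EM
#'
#' Convenience wrapper implementing the estimation pipeline for one
#' subject: SVD dimension reduction (default reduced dimension Q + 5,
#' capped at T - 1), a rough dual-regression estimate of the mixing matrix
#' from the reduced data (columns variance-normalized), residual variance
#' initialized from the discarded SVD energy, then [em_fit()].
#'
#' @param run A `bold_run`.
#' @param template A `prior_template`.
#' @param n_components Reduced dimension (default `min(Q + 5, T - 1)`).
#' @param tol,max_iter Passed to [em_fit()].
#' @param standardize Passed to [reduce_dimension()].
#' @return A `subject_posterior`.
#' @export
fit_template_ica <- function(run, template, n_components = NULL,
                             tol = 1e-3, max_iter = 100L,
                             standardize = FALSE) {
  stopifnot(inherits(template, "prior_template"))
  y <- if (inherits(run, "bold_run")) run$data else as.matrix(run)
  q <- nrow(template$mu0)
  if (is.null(n_components)) n_components <- min(q + 5L, nrow(y) - 1L)
  if (n_components < q)
    stop("reduced dimension must be at least the number of networks",
         call. = FALSE)
  reduced <- reduce_dimension(y, n_components, standardize = standardize)
  # rough dual regression in the reduced space: y_red ~ A mu0
  dr <- dual_regression(reduced$y, template$mu0)
  A0 <- dr$time_courses # Tr x Q, variance-normalized
  em_fit(reduced, template, A0, tol = tol, max_iter = max_iter)
}
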