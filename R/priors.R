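#' Construct a set of group-level network maps
#'
#' @param maps Q x V numeric matrix of group spatial maps (e.g. group-ICA
#'   Z-score maps); rows must not be identically zero and Q >= 2.
#' @param ic_labels Optional character names for the Q networks.
#' @return A `group_maps` object.
#' @export
group_maps <- function(maps, ic_labels = NULL) {
  maps <- as.matrix(maps)
  if (nrow(maps) < 2L) stop("need at least 2 group maps", call. = FALSE)
  if (any(apply(maps, 1L, function(r) all(r == 0))))
    stop("group maps contain an all-zero row", call. = FALSE)
  if (is.null(ic_labels)) ic_labels <- sprintf("IC%d", seq_len(nrow(maps)))
  structure(list(maps = maps, ic_labels = ic_labels), class = "group_maps")
}

as_group_maps <- function(x) {
  if (inherits(x, "group_maps")) return(x)
  x <- as.matrix(x)
  if (nrow(x) == 1L) # single-map regression is allowed even though a
    # template needs Q >= 2
    return(structure(list(maps = x, ic_labels = "IC1"), class = "group_maps"))
  group_maps(x)
}

#' Dual regression of group maps into a subject's data
#'
#' Two-stage ordinary least squares. Stage 1 regresses the group spatial
#' maps against each frame of the data, giving subject time courses
#' (T x Q); the time courses are then variance-normalized (unit temporal
#' SD) so stage-2 map magnitudes are comparable across subjects. Stage 2
#' regresses the normalized time courses against each vertex's time series,
#' giving subject spatial maps (Q x V).
#'
#' @param run A `bold_run` (T x V), with Q < min(T, V).
#' @param gmaps A `group_maps` object or Q x V matrix.
#' @return List with `time_courses` (T x Q, normalized) and `subject_maps`
#'   (Q x V).
#' @export
dual_regression <- function(run, gmaps) {
  gmaps <- as_group_maps(gmaps)
  y <- if (inherits(run, "bold_run")) run$data else as.matrix(run)
  g <- gmaps$maps
  q <- nrow(g)
  if (q >= min(dim(y)))
    stop("number of maps must be below min(T, V)", call. = FALSE)

  qr_g <- qr(t(g))
  if (qr_g$rank < q) {
    bad <- setdiff(seq_len(q), sort(qr_g$pivot[seq_len(qr_g$rank)]))
    stop(sprintf("group maps are rank deficient; offending map(s): %s",
                 paste(gmaps$ic_labels[bad], collapse = ", ")),
         call. = FALSE)
  }
  # stage 1: y_t ~ G' b  =>  TC = Y G' (G G')^-1
  tc <- t(qr.coef(qr_g, t(y)))
  tc <- tc / rep(apply(tc, 2L, stats::sd), each = nrow(tc))

  qr_tc <- qr(tc)
  if (qr_tc$rank < q) {
    bad <- setdiff(seq_len(q), sort(qr_tc$pivot[seq_len(qr_tc$rank)]))
    stop(sprintf("stage-1 time courses are collinear; offending map(s): %s",
                 paste(gmaps$ic_labels[bad], collapse = ", ")),
         call. = FALSE)
  }
  maps <- qr.coef(qr_tc, y)
  dimnames(maps) <- list(gmaps$ic_labels, NULL)
  list(time_courses = tc, subject_maps = maps)
}

#' Split a run into two contiguous pseudo-sessions
#'
#' The first pseudo-session holds the first `floor(T/2)` frames, the second
#' the remainder; both keep the original TR. Splitting a run in half gives
#' two noisy repeated measurements of the same subject's networks, from
#' which within-subject (noise) variance can be separated from
#' between-subject variance.
#'
#' @param run A `bold_run` with T >= 4.
#' @return List of two `bold_run`s, `first` and `second`.
#' @export
split_pseudo_sessions <- function(run) {
  stopifnot(inherits(run, "bold_run"))
  tt <- nrow(run$data)
  if (tt < 4L) stop("need at least 4 frames to split", call. = FALSE)
  h <- tt %/% 2L
  list(
    first = bold_run(run$data[seq_len(h), , drop = FALSE],
                     run$tr_seconds, paste0(run$subject_id, "_ses1")),
    second = bold_run(run$data[(h + 1L):tt, , drop = FALSE],
                      run$tr_seconds, paste0(run$subject_id, "_ses2"))
  )
}

#' Estimate the empirical population prior (template)
#'
#' For each subject the run is split into two pseudo-sessions and dual
#' regression produces a noisy map estimate `s_ij` per session j. The
#' template is then, per network q and vertex v:
#' * prior mean: `mu0 = (1/2N) sum_i sum_j s_ij`;
#' * total variance: the across-subject variance computed within each
#'   session and averaged over the two sessions;
#' * noise (within-subject) variance: half the across-subject variance of
#'   the session difference `s_i2 - s_i1`;
#' * between-subject variance: `sigma0^2 = max(total - noise, 0)`.
#'
#' Across-subject variances use the unbiased (N-1) denominator. Negative
#' between-subject estimates are clamped to zero so the prior is a valid
#' Gaussian variance.
#'
#' @param runs List of `bold_run`s (>= 2 subjects), each splittable.
#' @param gmaps A `group_maps` object or Q x V matrix.
#' @return A `prior_template`: list with `mu0`, `sigma0_sq`, `sigma_tot_sq`,
#'   `sigma_noise_sq` (all Q x V), `ic_labels`, `n_subjects_used`.
#' @export
estimate_template <- function(runs, gmaps) {
  gmaps <- as_group_maps(gmaps)
  n <- length(runs)
  if (n < 2L)
    stop("template variances are undefined for fewer than 2 subjects",
         call. = FALSE)
  q <- nrow(gmaps$maps); v <- ncol(gmaps$maps)

  s1 <- array(NA_real_, c(n, q, v))
  s2 <- array(NA_real_, c(n, q, v))
  for (i in seq_len(n)) {
    halves <- split_pseudo_sessions(runs[[i]])
    s1[i, , ] <- dual_regression(halves$first, gmaps)$subject_maps
    s2[i, , ] <- dual_regression(halves$second, gmaps)$subject_maps
  }

  mu0 <- (apply(s1, c(2, 3), mean) + apply(s2, c(2, 3), mean)) / 2
  var1 <- apply(s1, c(2, 3), stats::var)
  var2 <- apply(s2, c(2, 3), stats::var)
  sigma_tot_sq <- (var1 + var2) / 2
  sigma_noise_sq <- apply(s2 - s1, c(2, 3), stats::var) / 2
  sigma0_sq <- pmax(sigma_tot_sq - sigma_noise_sq, 0)

  dimnames(mu0) <- list(gmaps$ic_labels, NULL)
  structure(list(mu0 = mu0, sigma0_sq = sigma0_sq,
                 sigma_tot_sq = sigma_tot_sq,
                 sigma_noise_sq = sigma_noise_sq,
                 ic_labels = gmaps$ic_labels, n_subjects_used = n),
            class = "prior_template")
}

#' Construct a prior template directly from known maps and variances
#'
#' Mainly for simulation studies where the generative group maps and
#' between-subject variances are known exactly.
#'
#' @param mu0 Q x V prior mean maps.
#' @param sigma0_sq Q x V non-negative between-subject variances.
#' @param ic_labels Optional network names.
#' @return A `prior_template`.
#' @export
prior_template <- function(mu0, sigma0_sq, ic_labels = NULL) {
  mu0 <- as.matrix(mu0); sigma0_sq <- as.matrix(sigma0_sq)
  stopifnot(all(dim(mu0) == dim(sigma0_sq)))
  if (any(sigma0_sq < 0))
    stop("`sigma0_sq` must be non-negative", call. = FALSE)
  if (is.null(ic_labels)) ic_labels <- sprintf("IC%d", seq_len(nrow(mu0)))
  structure(list(mu0 = mu0, sigma0_sq = sigma0_sq,
                 sigma_tot_sq = NULL, sigma_noise_sq = NULL,
                 ic_labels = ic_labels, n_subjects_used = NA_integer_),
            class = "prior_template")
}

#' @export
print.prior_template <- function(x, ...) {
  cat(sprintf("<prior_template> %d networks x %d vertices (from %s subjects)\n",
              nrow(x$mu0), ncol(x$mu0),
              ifelse(is.na(x$n_subjects_used), "known-truth",
                     x$n_subjects_used)))
  cat(sprintf("  between-subject variance: median %.3g, clamped at 0 in %.1f%% of entries\n",
              stats::median(x$sigma0_sq), 100 * mean(x$sigma0_sq == 0)))
  invisible(x)
}
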