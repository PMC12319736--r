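#' t-statistic maps from a subject posterior
#'
#' The per-vertex, per-network t-score is the posterior mean divided by the
#' posterior standard deviation (the Bayesian analogue of estimate over
#' standard error). Vertices with zero posterior SD (components held fixed
#' at the prior mean) are returned as `NA` and reported with a warning.
#'
#' @param posterior A `subject_posterior`, or any list with `post_mean` and
#'   `post_sd` Q x V matrices.
#' @return Q x V numeric matrix of t-scores.
#' @export
t_maps <- function(posterior) {
  m <- posterior$post_mean; s <- posterior$post_sd
  stopifnot(all(dim(m) == dim(s)))
  out <- m / s
  zero <- s == 0
  if (any(zero)) {
    out[zero] <- NA_real_
    warning(sprintf("%d map entries have zero posterior SD; t undefined there",
                    sum(zero)), call. = FALSE)
  }
  out
}

#' Bayesian engagement test with Bonferroni correction
#'
#' For each network and vertex, computes from the Gaussian posterior the
#' probability that the network value is at or below the engagement
#' threshold `gamma` (a one-sided Bayesian tail probability: small values
#' mean the posterior credibly exceeds `gamma`). A vertex is declared
#' engaged when that probability is at most `alpha / m`, Bonferroni
#' corrected with `m` the number of in-mask vertices (the family is the
#' vertices within each network map).
#'
#' @param posterior A `subject_posterior`.
#' @param gamma Engagement threshold, in the units of the network maps
#'   (default 0: any credible positive engagement).
#' @param alpha Family-wise significance level in (0, 1), default 0.05.
#' @param analysis_mask Optional logical length-V mask; defaults to all
#'   vertices.
#' @return An `engagement_result`: `t_map`, `p_map` (uncorrected tail
#'   probabilities), `mask` (Q x V logical), `alpha`, `gamma`,
#'   `correction = "bonferroni"`, `m` (family size), `analysis_mask`.
#' @export
engagement_test <- function(posterior, gamma = 0, alpha = 0.05,
                            analysis_mask = NULL) {
  m <- posterior$post_mean; s <- posterior$post_sd
  if (!(alpha > 0 && alpha < 1)) stop("`alpha` must be in (0,1)", call. = FALSE)
  v <- ncol(m)
  if (is.null(analysis_mask)) analysis_mask <- rep(TRUE, v)
  n_mask <- sum(analysis_mask)

  p_map <- matrix(NA_real_, nrow(m), v)
  ok <- s > 0
  p_map[ok] <- stats::pnorm((gamma - m[ok]) / s[ok])
  engaged <- !is.na(p_map) & p_map <= alpha / n_mask
  engaged[, !analysis_mask] <- FALSE

  tm <- suppressWarnings(t_maps(posterior))
  structure(list(t_map = tm, p_map = p_map, mask = engaged,
                 alpha = alpha, gamma = gamma, correction = "bonferroni",
                 m = n_mask, analysis_mask = analysis_mask,
                 ic_labels = posterior$ic_labels),
            class = "engagement_result")
}

#' @export
print.engagement_result <- function(x, ...) {
  cat(sprintf(paste0("<engagement_result> %d networks x %d vertices; ",
                     "gamma=%g, alpha=%g (Bonferroni over %d vertices)\n"),
              nrow(x$mask), ncol(x$mask), x$gamma, x$alpha, x$m))
  cat(sprintf("  engaged vertices per network: %s\n",
              paste(rowSums(x$mask), collapse = ", ")))
  invisible(x)
}

# shared winner-takes-all kernel
wta_labels <- function(stat, analysis_mask) {
  q <- nrow(stat); v <- ncol(stat)
  if (q < 2L) stop("winner-takes-all needs at least 2 networks", call. = FALSE)
  if (is.null(analysis_mask)) analysis_mask <- rep(TRUE, v)
  labels <- integer(v)
  inm <- which(analysis_mask)
  # which.max returns the first (lowest) index on ties
  labels[inm] <- apply(stat[, inm, drop = FALSE], 2L, which.max)
  labels
}

#' Winner-takes-all parcellation from t-statistic maps
#'
#' Assigns each in-mask vertex the label of the network with the highest
#' t-score there; exact ties go to the lowest network index, out-of-mask
#' vertices are labeled 0.
#'
#' @param t_map Q x V matrix of t-scores (Q >= 2), e.g. from [t_maps()].
#' @param analysis_mask Logical length-V mask (default all `TRUE`).
#' @param source Label describing provenance (`"group"` or a subject id).
#' @return A `parcellation`: `labels` (length V, 0 = outside mask),
#'   `n_networks`, `source`, `analysis_mask`.
#' @export
wta_parcellation <- function(t_map, analysis_mask = NULL, source = "subject") {
  t_map <- as.matrix(t_map)
  labels <- wta_labels(t_map, analysis_mask)
  structure(list(labels = labels, n_networks = nrow(t_map), source = source,
                 analysis_mask = if (is.null(analysis_mask))
                   rep(TRUE, ncol(t_map)) else analysis_mask),
            class = "parcellation")
}

#' Winner-takes-all parcellation of group-level maps
#'
#' Identical mechanics to [wta_parcellation()] applied to group Z-score (or
#' other statistic) maps, yielding the cohort-level reference parcellation.
#'
#' @param group_z Q x V matrix of group statistic maps.
#' @param analysis_mask Logical length-V mask (default all `TRUE`).
#' @return A `parcellation` with `source = "group"`.
#' @export
group_parcellation <- function(group_z, analysis_mask = NULL) {
  wta_parcellation(group_z, analysis_mask, source = "group")
}

#' @export
print.parcellation <- function(x, ...) {
  tab <- table(factor(x$labels[x$labels > 0], levels = seq_len(x$n_networks)))
  cat(sprintf("<parcellation> (%s) %d vertices, %d networks\n",
              x$source, length(x$labels), x$n_networks))
  cat("  vertices per label:", paste(as.integer(tab), collapse = ", "), "\n")
  invisible(x)
}
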