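#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a subject posterior into a long tibble
#'
#' @param x A `subject_posterior`.
#' @param ... Unused.
#' @return Tibble with columns `ic`, `vertex`, `mean`, `sd`, `t`.
#' @method tidy subject_posterior
#' @export
tidy.subject_posterior <- function(x, ...) {
  q <- nrow(x$post_mean); v <- ncol(x$post_mean)
  tm <- suppressWarnings(t_maps(x))
  tibble::tibble(
    ic = rep(x$ic_labels %||% sprintf("IC%d", seq_len(q)), times = v),
    vertex = rep(seq_len(v), each = q),
    mean = as.vector(x$post_mean),
    sd = as.vector(x$post_sd),
    t = as.vector(tm)
  )
}

#' One-row fit summary of a subject posterior
#'
#' @param x A `subject_posterior`.
#' @param ... Unused.
#' @return Tibble with `n_iterations`, `converged`, `noise_var`, `loglik`.
#' @method glance subject_posterior
#' @export
glance.subject_posterior <- function(x, ...) {
  tibble::tibble(n_iterations = x$n_iterations, converged = x$converged,
                 noise_var = x$noise_var,
                 loglik = utils::tail(x$loglik_trace, 1))
}

#' Tidy a prior template into a long tibble
#'
#' @param x A `prior_template`.
#' @param ... Unused.
#' @return Tibble with `ic`, `vertex`, `mu0`, `sigma0_sq` (and the total
#'   and noise variance decomposition when available).
#' @method tidy prior_template
#' @export
tidy.prior_template <- function(x, ...) {
  q <- nrow(x$mu0); v <- ncol(x$mu0)
  out <- tibble::tibble(
    ic = rep(x$ic_labels, times = v),
    vertex = rep(seq_len(v), each = q),
    mu0 = as.vector(x$mu0),
    sigma0_sq = as.vector(x$sigma0_sq)
  )
  if (!is.null(x$sigma_tot_sq)) {
    out$sigma_tot_sq <- as.vector(x$sigma_tot_sq)
    out$sigma_noise_sq <- as.vector(x$sigma_noise_sq)
  }
  out
}

#' Tidy a censoring result into a per-frame tibble
#'
#' @param x A `censor_result`.
#' @param ... Unused.
#' @return Tibble with `frame`, `dvars`, `outlier`, `in_block`.
#' @method tidy censor_result
#' @export
tidy.censor_result <- function(x, ...) {
  tt <- length(x$outlier_flags)
  inb <- seq_len(tt) >= x$block_start &
    seq_len(tt) < x$block_start + x$block_length
  tibble::tibble(frame = seq_len(tt),
                 dvars = x$dvars %||% rep(NA_real_, tt),
                 outlier = x$outlier_flags, in_block = inb)
}

#' One-row summary of a censoring result
#'
#' @param x A `censor_result`.
#' @param ... Unused.
#' @return Tibble with `block_start`, `block_length`, `outliers_in_block`,
#'   `included`.
#' @method glance censor_result
#' @export
glance.censor_result <- function(x, ...) {
  tibble::tibble(block_start = x$block_start, block_length = x$block_length,
                 outliers_in_block = x$outliers_in_block,
                 included = x$included)
}

#' Tidy a frequency map
#'
#' @param x A `frequency_map`.
#' @param ... Unused.
#' @return Tibble with `vertex`, `dominant_label`, `dominant_pct`.
#' @method tidy frequency_map
#' @export
tidy.frequency_map <- function(x, ...) {
  tibble::tibble(vertex = seq_along(x$dominant_label),
                 dominant_label = x$dominant_label,
                 dominant_pct = x$dominant_pct)
}

#' Tidy a parcellation
#'
#' @param x A `parcellation`.
#' @param ... Unused.
#' @return Tibble with `vertex`, `label`, `source`.
#' @method tidy parcellation
#' @export
tidy.parcellation <- function(x, ...) {
  tibble::tibble(vertex = seq_along(x$labels), label = x$labels,
                 source = x$source)
}
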