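#' DVARS: frame-to-frame root-mean-squared intensity change
#'
#' For frame t >= 2 (1-based), DVARS is the root mean square across vertices
#' of the intensity difference from frame t-1; the first frame is assigned 0
#' by convention. This is the standard backward-difference definition of
#' DVARS used for motion screening.
#'
#' @param run A `bold_run` (or a T x V matrix).
#' @return Numeric vector of length T, non-negative.
#' @export
compute_dvars <- function(run) {
  y <- if (inherits(run, "bold_run")) run$data else as.matrix(run)
  if (nrow(y) < 2L) stop("DVARS needs at least 2 frames", call. = FALSE)
  if (!all(is.finite(y))) stop("non-finite values in BOLD data", call. = FALSE)
  d <- diff(y)
  c(0, sqrt(rowMeans(d^2)))
}

#' Flag motion-corrupted frames from a DVARS series
#'
#' A frame is an outlier when its DVARS value is strictly higher than 1.5
#' times the interquartile range above the 75th percentile of the whole
#' session's DVARS values (the boxplot upper-fence rule). Quantiles use the
#' default linear-interpolation convention.
#'
#' @param dvars Numeric DVARS series, length >= 4.
#' @return Logical vector: `TRUE` at outlier frames.
#' @export
flag_outliers <- function(dvars) {
  if (length(dvars) < 4L)
    stop("need at least 4 frames to estimate the outlier fence", call. = FALSE)
  q <- stats::quantile(dvars, c(0.25, 0.75), names = FALSE)
  dvars > q[2L] + 1.5 * (q[2L] - q[1L])
}

#' Select the contiguous low-motion block and apply the exclusion rule
#'
#' Finds the contiguous window of `block_length` frames containing the
#' fewest flagged frames (ties broken by earliest start) and decides
#' inclusion: a subject is excluded when the retained block contains
#' strictly more than `floor(max_outlier_fraction * block_length)` outliers
#' (with the defaults, more than 160 of 1600 frames, i.e. 10%).
#'
#' @param flags Logical per-frame outlier flags (length T), or a
#'   `bold_run` / DVARS series from which flags are computed.
#' @param block_length Number of frames to retain (default 1600, ten
#'   minutes at TR = 0.375 s). Must not exceed T.
#' @param max_outlier_fraction Maximum tolerated fraction of outliers in
#'   the block (default 0.10).
#' @param dvars Optional DVARS series to carry into the result (filled
#'   automatically when `flags` is a run or a numeric series).
#' @return A `censor_result`: list with `dvars`, `outlier_flags`,
#'   `block_start` (1-based first frame), `block_length`,
#'   `outliers_in_block`, `included`, `max_outlier_fraction`.
#' @export
select_block <- function(flags, block_length = 1600L,
                         max_outlier_fraction = 0.10, dvars = NULL) {
  if (inherits(flags, "bold_run") || (is.numeric(flags) && !is.logical(flags))) {
    dvars <- if (inherits(flags, "bold_run")) compute_dvars(flags) else flags
    flags <- flag_outliers(dvars)
  }
  stopifnot(is.logical(flags))
  tt <- length(flags)
  block_length <- as.integer(block_length)
  if (block_length > tt)
    stop(sprintf("block_length (%d) exceeds run length (%d)",
                 block_length, tt), call. = FALSE)

  counts <- window_counts(flags, block_length)
  best <- which.min(counts) # which.min takes the earliest tie
  n_out <- counts[best]
  included <- n_out <= floor(max_outlier_fraction * block_length)
  structure(list(dvars = dvars, outlier_flags = flags,
                 block_start = best, block_length = block_length,
                 outliers_in_block = as.integer(n_out), included = included,
                 max_outlier_fraction = max_outlier_fraction),
            class = "censor_result")
}

window_counts <- function(flags, len) {
  cs <- c(0L, cumsum(as.integer(flags)))
  cs[(len + 1L):(length(flags) + 1L)] - cs[1:(length(flags) - len + 1L)]
}

#' @export
print.censor_result <- function(x, ...) {
  cat(sprintf(paste0("<censor_result> block frames %d-%d (%d frames), ",
                     "%d outliers in block, %s\n"),
              x$block_start, x$block_start + x$block_length - 1L,
              x$block_length, x$outliers_in_block,
              if (x$included) "included" else "EXCLUDED"))
  invisible(x)
}

#' Extract the retained block of a run
#'
#' @param run A `bold_run`.
#' @param censor A `censor_result` for that run.
#' @return A `bold_run` restricted to the retained frames.
#' @export
apply_censor <- function(run, censor) {
  stopifnot(inherits(run, "bold_run"), inherits(censor, "censor_result"))
  idx <- censor$block_start:(censor$block_start + censor$block_length - 1L)
  bold_run(run$data[idx, , drop = FALSE], run$tr_seconds, run$subject_id)
}

#' Temporal signal-to-noise ratio map
#'
#' Per subject and vertex, SNR is the absolute temporal mean of the BOLD
#' signal divided by its temporal standard deviation (a unitless linear
#' ratio). The global map averages the linear SNR across subjects and
#' converts to decibels:
#' `tSNR(v) [dB] = 10 log10( (1/N) sum_i SNR_i(v) )`.
#' Vertices with zero temporal variance in any run have undefined SNR there
#' (`NA`) and are reported, never silently dropped; the global average at a
#' vertex uses the subjects for which SNR is defined.
#'
#' @param runs A list of `bold_run`s sharing V.
#' @return A `tsnr_map`: list with `per_subject_snr` (N x V), `global_db`
#'   (length V), `undefined` (N x V logical).
#' @export
compute_tsnr <- function(runs) {
  if (inherits(runs, "bold_run")) runs <- list(runs)
  v <- ncol(runs[[1L]]$data)
  if (!all(vapply(runs, function(r) ncol(r$data) == v, logical(1))))
    stop("all runs must share the same number of vertices", call. = FALSE)
  snr <- t(vapply(runs, function(r) {
    mu <- colMeans(r$data)
    sdv <- apply(r$data, 2L, stats::sd)
    out <- abs(mu) / sdv
    out[sdv == 0] <- NA_real_
    out
  }, numeric(v)))
  undef <- is.na(snr)
  if (any(undef))
    warning(sprintf("%d vertex/run combinations have zero temporal variance; SNR undefined there",
                    sum(undef)), call. = FALSE)
  global_db <- 10 * log10(colMeans(snr, na.rm = TRUE))
  structure(list(per_subject_snr = snr, global_db = global_db,
                 undefined = undef),
            class = "tsnr_map")
}

#' @export
print.tsnr_map <- function(x, ...) {
  cat(sprintf("<tsnr_map> %d subjects x %d vertices; global median %.1f dB\n",
              nrow(x$per_subject_snr), ncol(x$per_subject_snr),
              stats::median(x$global_db, na.rm = TRUE)))
  invisible(x)
}

#' Threshold a tSNR map into an analysis mask
#'
#' Convenience for masking out noisy cortex (e.g. below 17 dB) before
#' display or parcellation. Thresholding is presentation-level; no analysis
#' in the package applies it implicitly.
#'
#' @param tsnr A `tsnr_map`.
#' @param threshold_db Threshold in decibels.
#' @return Logical vector, `TRUE` where the global map is at or above the
#'   threshold.
#' @export
tsnr_mask <- function(tsnr, threshold_db = 17) {
  stopifnot(inherits(tsnr, "tsnr_map"))
  !is.na(tsnr$global_db) & tsnr$global_db >= threshold_db
}
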