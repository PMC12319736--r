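#' Construct a BOLD run
#'
#' Light container for one subject's vertex time series on a surface.
#'
#' @param data T x V numeric matrix (timepoints by vertices), finite, T >= 2.
#' @param tr_seconds Sampling interval (TR), seconds.
#' @param subject_id Identifier.
#' @return A `bold_run` object.
#' @export
bold_run <- function(data, tr_seconds = 0.375, subject_id = "subject") {
  data <- as.matrix(data)
  if (nrow(data) < 2L) stop("a BOLD run needs at least 2 timepoints", call. = FALSE)
  if (!all(is.finite(data))) stop("BOLD data contains non-finite values", call. = FALSE)
  if (!is.numeric(tr_seconds) || tr_seconds <= 0)
    stop("`tr_seconds` must be positive", call. = FALSE)
  structure(list(data = data, tr_seconds = tr_seconds,
                 subject_id = subject_id),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("<bold_run> %s: %d frames x %d vertices, TR %.3f s (%.1f min)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr_seconds,
              nrow(x$data) * x$tr_seconds / 60))
  invisible(x)
}

#' Sample ground-truth networks, subject maps and covariates
#'
#' Draws a synthetic cohort with exactly the hierarchical structure the
#' template-ICA model assumes: Q spatially smooth group-level network maps
#' on the mesh, per-subject spatial deviations that are Gaussian per vertex
#' with a known vertex-wise between-subject variance, per-subject mixing
#' time courses, and covariates (age at scan in weeks PMA, sex, a motion
#' propensity). An age effect, if requested, multiplies each subject's
#' network signal amplitude (a strength effect, not a topography change).
#'
#' Group maps are geodesic Gaussian bumps at centres placed by
#' farthest-point sampling, so networks are distinct with limited mutual
#' overlap. The between-subject standard deviation at a vertex is
#' `base + scale * |group map|`, i.e. subjects vary most where a network is
#' engaged. Mixing time courses are temporally smoothed Gaussian processes,
#' independent across components, with unit temporal variance in
#' expectation, before the age amplitude factor
#' `exp(age_effect * (age - 41))` is applied.
#'
#' @param mesh A `surface_mesh`.
#' @param n_subjects Cohort size N.
#' @param n_ics Number of networks Q (>= 2).
#' @param n_timepoints Frames per run T (> `n_ics`).
#' @param noise_sd Residual noise standard deviation (the sqrt of the
#'   isotropic Omega scale), > 0.
#' @param age_effect Log-amplitude slope per week PMA (0 = no age effect).
#' @param seed Integer seed; the truth is a pure function of the arguments
#'   and this seed.
#' @param between_sd_base,between_sd_scale Parameters of the vertex-wise
#'   between-subject SD (see Details).
#' @param deviation_fwhm_mm Optional spatial smoothing (mm FWHM) applied to
#'   subject deviations; 0 (default) gives vertex-independent deviations as
#'   the model assumes.
#' @param tr_seconds Sampling interval, seconds (default 0.375 s, i.e.
#'   1600 frames in 10 minutes).
#' @return A `synthetic_truth` object: list with `mesh`, `group_maps` (QxV),
#'   `between_var` (QxV), `subject_maps` (N-list of QxV), `mixing` (N-list
#'   of TxQ), `noise_var`, `ages`, `sexes`, `motion_levels`, `age_effect`,
#'   `amplitudes`, `tr_seconds`, `seed`.
#' @export
sample_truth <- function(mesh, n_subjects, n_ics, n_timepoints,
                         noise_sd = 1, age_effect = 0, seed = 1L,
                         between_sd_base = 0.05, between_sd_scale = 0.25,
                         deviation_fwhm_mm = 0, tr_seconds = 0.375) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (n_ics < 2) stop("`n_ics` must be >= 2", call. = FALSE)
  if (n_timepoints <= n_ics)
    stop("`n_timepoints` must exceed `n_ics`", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop("`noise_sd` must be positive", call. = FALSE)
  n_subjects <- as.integer(n_subjects); n_ics <- as.integer(n_ics)
  n_timepoints <- as.integer(n_timepoints)

  withr::with_seed(as.integer(seed), {
    group_maps <- make_group_maps(mesh, n_ics)
    between_var <- (between_sd_base + between_sd_scale * abs(group_maps))^2

    ages <- stats::runif(n_subjects, 37.4, 44.8)
    sexes <- stats::rbinom(n_subjects, 1L, 0.5)
    motion_levels <- stats::rgamma(n_subjects, shape = 2, scale = 6)
    amplitudes <- exp(age_effect * (ages - 41))

    subject_maps <- vector("list", n_subjects)
    mixing <- vector("list", n_subjects)
    for (i in seq_len(n_subjects)) {
      dev <- matrix(stats::rnorm(n_ics * mesh$n_vertices),
                    n_ics, mesh$n_vertices)
      if (deviation_fwhm_mm > 0) {
        dev <- t(apply(dev, 1L, smooth_surface, mesh = mesh,
                       fwhm_mm = deviation_fwhm_mm))
        dev <- dev / stats::sd(dev) # restore unit variance after smoothing
      }
      subject_maps[[i]] <- group_maps + sqrt(between_var) * dev
      mixing[[i]] <- amplitudes[i] *
        make_time_courses(n_timepoints, n_ics)
    }
    structure(list(mesh = mesh, group_maps = group_maps,
                   between_var = between_var, subject_maps = subject_maps,
                   mixing = mixing, noise_var = noise_sd^2, ages = ages,
                   sexes = sexes, motion_levels = motion_levels,
                   age_effect = age_effect, amplitudes = amplitudes,
                   tr_seconds = tr_seconds, seed = as.integer(seed)),
              class = "synthetic_truth")
  })
}

# Q geodesic Gaussian bumps at farthest-point-sampled centres, peak 3
make_group_maps <- function(mesh, q, amplitude = 3) {
  v <- mesh$n_vertices
  centers <- integer(q)
  centers[1L] <- sample.int(v, 1L)
  dmin <- mesh_distance(mesh, centers[1L])
  if (q > 1) for (k in 2:q) {
    centers[k] <- which.max(dmin)
    dmin <- pmin(dmin, mesh_distance(mesh, centers[k]))
  }
  sep <- min(stats::dist(mesh$coords[centers, , drop = FALSE]))
  width <- 0.45 * sep
  maps <- matrix(0, q, v)
  for (k in seq_len(q)) {
    d <- mesh_distance(mesh, centers[k])
    maps[k, ] <- amplitude * exp(-d^2 / (2 * width^2))
  }
  attr(maps, "centers") <- centers
  maps
}

# Smoothed-GP columns with unit variance and zero cross-correlation in
# expectation (population scaling). Realized per-column variance is
# deliberately left to fluctuate: forcing the sample variance to exactly 1
# would couple the amplitudes of the two pseudo-session halves
# (sd1^2 + sd2^2 pinned), an artifact real time courses do not have that
# breaks the between-session independence the test-retest variance
# decomposition relies on.
make_time_courses <- function(t, q, smooth_frames = 8L) {
  raw <- matrix(stats::rnorm((t + 2L * smooth_frames) * q), ncol = q)
  kern <- stats::dnorm(seq(-2, 2, length.out = 2L * smooth_frames + 1L))
  kern <- kern / sum(kern)
  sm <- apply(raw, 2L, function(col) {
    stats::filter(col, kern, sides = 2)[(smooth_frames + 1L):(smooth_frames + t)]
  })
  sm / sqrt(sum(kern^2))
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_truth> N=%d subjects, Q=%d networks, ",
                     "V=%d vertices, T=%d frames\n"),
              length(x$subject_maps), nrow(x$group_maps),
              ncol(x$group_maps), nrow(x$mixing[[1L]])))
  cat(sprintf("  noise var %.3g, age effect %.3g/week, seed %d\n",
              x$noise_var, x$age_effect, x$seed))
  invisible(x)
}

#' Render one subject's BOLD run from the ground truth
#'
#' Generates `data = A_i s_i + e`, with `e` i.i.d. Gaussian of the truth's
#' residual variance, and optionally corrupts a set of frames with large
#' additive global intensity jumps that emulate motion. Jumps alternate
#' sign with frame parity so consecutive corrupt frames still produce large
#' frame-to-frame intensity changes, guaranteeing they exceed the DVARS
#' outlier threshold used downstream.
#'
#' The run is a pure function of the truth (its seed), the subject index
#' and `corrupt_frames`.
#'
#' @param truth A `synthetic_truth`.
#' @param subject Subject index in `1..N`.
#' @param corrupt_frames Integer frame indices (1-based) to corrupt.
#' @return A `bold_run` with attribute `corrupt_frames`.
#' @export
render_bold <- function(truth, subject, corrupt_frames = integer(0)) {
  stopifnot(inherits(truth, "synthetic_truth"))
  n <- length(truth$subject_maps)
  if (!(subject %in% seq_len(n)))
    stop("`subject` out of range", call. = FALSE)
  tt <- nrow(truth$mixing[[subject]])
  corrupt_frames <- as.integer(corrupt_frames)
  if (length(corrupt_frames) &&
      (any(corrupt_frames < 1L) || any(corrupt_frames > tt)))
    stop("`corrupt_frames` outside [1, T]", call. = FALSE)

  run_seed <- (truth$seed + 7919L * as.integer(subject)) %% .Machine$integer.max
  y <- withr::with_seed(run_seed, {
    sig <- truth$mixing[[subject]] %*% truth$subject_maps[[subject]]
    sig + matrix(stats::rnorm(length(sig), 0, sqrt(truth$noise_var)),
                 nrow(sig), ncol(sig))
  })
  if (length(corrupt_frames)) {
    jump <- 8 * (stats::sd(y) + sqrt(truth$noise_var))
    y[corrupt_frames, ] <- y[corrupt_frames, ] +
      jump * (-1)^corrupt_frames
  }
  run <- bold_run(y, tr_seconds = truth$tr_seconds,
                  subject_id = sprintf("sub-%03d", subject))
  attr(run, "corrupt_frames") <- corrupt_frames
  run
}

#' Cohort covariates as a tibble
#'
#' @param truth A `synthetic_truth`.
#' @return A tibble with one row per subject: `subject_id`, `age_pma_weeks`,
#'   `sex`, `motion_level`, `amplitude`.
#' @export
truth_covariates <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  n <- length(truth$subject_maps)
  tibble::tibble(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    age_pma_weeks = truth$ages,
    sex = truth$sexes,
    motion_level = truth$motion_levels,
    amplitude = truth$amplitudes
  )
}
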