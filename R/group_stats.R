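#' Area-weighted connectivity strength per network
#'
#' A subject's connectivity strength for network q is the mean t-score over
#' the vertices of that network's engagement mask, weighted by midthickness
#' vertex area:
#' `strength(q) = sum_{v in mask_q} area(v) t(q,v) / sum_{v in mask_q} area(v)`.
#' Networks with an empty mask get `NA` (flagged undefined, never
#' zero-filled) and are reported with a warning.
#'
#' @param t_map Q x V t-score matrix.
#' @param mask Q x V logical engagement mask (e.g. from
#'   [engagement_test()]), or an `engagement_result`.
#' @param vertex_area Length-V positive areas (mm^2).
#' @return Named numeric vector of length Q (NA where undefined).
#' @export
connectivity_strength <- function(t_map, mask, vertex_area) {
  if (inherits(mask, "engagement_result")) mask <- mask$mask
  t_map <- as.matrix(t_map); mask <- as.matrix(mask)
  stopifnot(all(dim(t_map) == dim(mask)), length(vertex_area) == ncol(t_map))
  if (any(vertex_area <= 0)) stop("vertex areas must be positive", call. = FALSE)
  out <- vapply(seq_len(nrow(t_map)), function(q) {
    sel <- mask[q, ] & !is.na(t_map[q, ])
    if (!any(sel)) return(NA_real_)
    sum(vertex_area[sel] * t_map[q, sel]) / sum(vertex_area[sel])
  }, numeric(1))
  names(out) <- rownames(t_map) %||% sprintf("IC%d", seq_along(out))
  if (anyNA(out))
    warning(sprintf("connectivity strength undefined (empty mask) for: %s",
                    paste(names(out)[is.na(out)], collapse = ", ")),
            call. = FALSE)
  out
}

#' Partial Spearman rank correlation
#'
#' Rank-transforms `x` and `y` (average ranks for ties), residualizes both
#' rank vectors on an intercept plus the covariates by ordinary least
#' squares, and correlates the residuals (Pearson). The p-value uses the
#' t approximation `t = rho sqrt(df / (1 - rho^2))` with
#' `df = N - 2 - K` degrees of freedom, two-sided. With no covariates this
#' reduces to the classical Spearman coefficient.
#'
#' @param x,y Numeric vectors of equal length N (N >= K + 4).
#' @param covariates Optional N x K numeric matrix / data frame of
#'   covariates to control for.
#' @return A tibble with columns `rho`, `p`, `n`, `df`.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  ok <- stats::complete.cases(x, y, covariates)
  n_drop <- sum(!ok)
  if (n_drop > 0) {
    message(sprintf("partial_spearman: dropped %d incomplete observation(s)",
                    n_drop))
    x <- x[ok]; y <- y[ok]
    if (!is.null(covariates))
      covariates <- as.matrix(covariates)[ok, , drop = FALSE]
  }
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  n <- length(x)
  if (n < k + 4L) stop("need at least K + 4 observations", call. = FALSE)

  rx <- rank(x); ry <- rank(y)
  if (k > 0) {
    z <- cbind(1, as.matrix(covariates))
    rx <- stats::lm.fit(z, rx)$residuals
    ry <- stats::lm.fit(z, ry)$residuals
  } else {
    rx <- rx - mean(rx); ry <- ry - mean(ry)
  }
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("constant ranks after residualization; rho undefined",
            call. = FALSE)
    return(tibble::tibble(rho = NA_real_, p = NA_real_, n = n,
                          df = n - 2L - k))
  }
  rho <- stats::cor(rx, ry)
  df <- n - 2L - k
  tval <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df)
  tibble::tibble(rho = rho, p = p, n = n, df = df)
}

#' Cohort table of per-network age associations
#'
#' Applies [partial_spearman()] of age at scan against connectivity
#' strength, per network, controlling for sex and motion. Reports
#' uncorrected p-values (as in the main analyses this mirrors) plus
#' Bonferroni-corrected ones across networks. Subjects with undefined
#' strength for a network are dropped listwise for that network; networks
#' with too few complete records are skipped with a warning.
#'
#' @param cohort A data frame / tibble with one row per subject: columns
#'   `age_pma_weeks`, `sex`, `motion`, and `strength_<label>` columns (one
#'   per network), e.g. from [cohort_table()].
#' @param min_records Minimum complete records per network (default 10).
#' @return A tibble with columns `ic`, `rho`, `p`, `p_bonferroni`, `n`.
#' @export
age_association_table <- function(cohort, min_records = 10L) {
  cohort <- tibble::as_tibble(cohort)
  needed <- c("age_pma_weeks", "sex", "motion")
  if (!all(needed %in% names(cohort)))
    stop("cohort table must have columns age_pma_weeks, sex, motion",
         call. = FALSE)
  scols <- grep("^strength_", names(cohort), value = TRUE)
  if (!length(scols)) stop("no strength_* columns found", call. = FALSE)

  rows <- lapply(scols, function(sc) {
    ok <- stats::complete.cases(cohort[c("age_pma_weeks", "sex", "motion", sc)])
    if (sum(ok) < min_records) {
      warning(sprintf("skipping %s: only %d complete records", sc, sum(ok)),
              call. = FALSE)
      return(NULL)
    }
    d <- cohort[ok, ]
    res <- partial_spearman(d$age_pma_weeks, d[[sc]],
                            cbind(sex = d$sex, motion = d$motion))
    tibble::tibble(ic = sub("^strength_", "", sc), rho = res$rho,
                   p = res$p, n = res$n)
  })
  out <- dplyr::bind_rows(rows)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out[c("ic", "rho", "p", "p_bonferroni", "n")]
}

#' Assemble a cohort table from covariates and strengths
#'
#' @param covariates Tibble with `subject_id`, `age_pma_weeks`, `sex`, and
#'   a motion summary column (default name `motion`; `motion_level` is
#'   accepted and renamed).
#' @param strengths N x Q matrix (rows = subjects) of connectivity
#'   strengths, or a list of per-subject named vectors from
#'   [connectivity_strength()].
#' @return A tibble, one row per subject, with `strength_<label>` columns.
#' @export
cohort_table <- function(covariates, strengths) {
  covariates <- tibble::as_tibble(covariates)
  if (!"motion" %in% names(covariates) && "motion_level" %in% names(covariates))
    covariates <- dplyr::rename(covariates, motion = "motion_level")
  if (is.list(strengths) && !is.matrix(strengths))
    strengths <- do.call(rbind, strengths)
  strengths <- as.matrix(strengths)
  if (nrow(strengths) != nrow(covariates))
    stop("strengths and covariates disagree on the number of subjects",
         call. = FALSE)
  labels <- colnames(strengths) %||% sprintf("IC%d", seq_len(ncol(strengths)))
  colnames(strengths) <- paste0("strength_", labels)
  dplyr::bind_cols(covariates, tibble::as_tibble(strengths))
}

#' Frequency map of parcellation agreement across subjects
#'
#' Per vertex, the modal (dominant) parcel label across subjects and the
#' percentage of subjects carrying it. Modal ties break to the lowest label
#' index. Out-of-mask vertices (label 0 everywhere) get `dominant_label 0`
#' and 0 percent.
#'
#' @param parcellations List of `parcellation`s sharing V and mask.
#' @return A `frequency_map`: `dominant_label` (length V),
#'   `dominant_pct` (length V, percent of subjects), `n_subjects`.
#' @export
frequency_map <- function(parcellations) {
  stopifnot(length(parcellations) >= 1L)
  labs <- vapply(parcellations, function(p) p$labels,
                 integer(length(parcellations[[1L]]$labels)))
  labs <- matrix(labs, ncol = length(parcellations)) # V x N
  n <- ncol(labs)
  qmax <- max(labs)
  dominant <- integer(nrow(labs)); pct <- numeric(nrow(labs))
  for (v in seq_len(nrow(labs))) {
    lv <- labs[v, ]
    lv <- lv[lv > 0]
    if (!length(lv)) next
    counts <- tabulate(lv, nbins = qmax)
    dominant[v] <- which.max(counts) # earliest tie
    pct[v] <- 100 * counts[dominant[v]] / n
  }
  structure(list(dominant_label = dominant, dominant_pct = pct,
                 n_subjects = n),
            class = "frequency_map")
}

#' @export
print.frequency_map <- function(x, ...) {
  cat(sprintf("<frequency_map> %d vertices, %d subjects; median agreement %.1f%%\n",
              length(x$dominant_label), x$n_subjects,
              stats::median(x$dominant_pct[x$dominant_label > 0])))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
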