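#' Fit a cohort and assemble subject-level and group-level results
#'
#' Runs the subject-level pipeline for every run — template-ICA EM fit,
#' engagement test, t-maps, winner-takes-all parcellation, area-weighted
#' connectivity strength — and assembles the cohort table used by the age
#' association analysis.
#'
#' @param runs List of `bold_run`s (already censored to the retained block
#'   if desired).
#' @param template A `prior_template`.
#' @param mesh A `surface_mesh` (provides vertex areas and analysis mask).
#' @param covariates Tibble with one row per run: `subject_id`,
#'   `age_pma_weeks`, `sex`, and `motion` (or `motion_level`).
#' @param gamma,alpha Engagement-test parameters, see [engagement_test()].
#' @param n_components,tol,max_iter Passed to [fit_template_ica()].
#' @return A `cohort_result`: `cohort` (tibble with strength columns),
#'   `parcellations` (list), `posteriors` (list), `frequency`
#'   (a `frequency_map`), `age_table` (tibble from
#'   [age_association_table()], `NULL` when fewer than 10 subjects).
#' @export
analyze_cohort <- function(runs, template, mesh, covariates,
                           gamma = 0, alpha = 0.05, n_components = NULL,
                           tol = 1e-3, max_iter = 100L) {
  stopifnot(inherits(template, "prior_template"),
            inherits(mesh, "surface_mesh"))
  n <- length(runs)
  covariates <- tibble::as_tibble(covariates)
  if (nrow(covariates) != n)
    stop("covariates must have one row per run", call. = FALSE)

  posteriors <- vector("list", n)
  parcellations <- vector("list", n)
  strengths <- vector("list", n)
  for (i in seq_len(n)) {
    post <- fit_template_ica(runs[[i]], template,
                             n_components = n_components,
                             tol = tol, max_iter = max_iter)
    eng <- engagement_test(post, gamma = gamma, alpha = alpha,
                           analysis_mask = mesh$analysis_mask)
    posteriors[[i]] <- post
    parcellations[[i]] <- wta_parcellation(
      eng$t_map, mesh$analysis_mask,
      source = runs[[i]]$subject_id %||% sprintf("sub-%03d", i))
    strengths[[i]] <- suppressWarnings(
      connectivity_strength(eng$t_map, eng$mask, mesh$vertex_area))
  }
  cohort <- cohort_table(covariates, strengths)
  age_table <- if (n >= 10L)
    suppressWarnings(age_association_table(cohort)) else NULL
  structure(list(cohort = cohort, parcellations = parcellations,
                 posteriors = posteriors,
                 frequency = frequency_map(parcellations),
                 age_table = age_table),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d subjects\n", nrow(x$cohort)))
  if (!is.null(x$age_table)) {
    cat("  age associations (partial Spearman, controlling sex + motion):\n")
    print(as.data.frame(x$age_table), row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Write a censoring report, cohort table or association table as TSV
#'
#' @param x A `censor_result` list (named by subject), a cohort tibble or
#'   an association tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(x, path) {
  if (is.list(x) && length(x) && inherits(x[[1L]], "censor_result")) {
    x <- dplyr::bind_rows(lapply(seq_along(x), function(i) {
      g <- glance(x[[i]])
      g$subject_id <- names(x)[i] %||% as.character(i)
      g
    }))
  }
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
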