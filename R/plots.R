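#' Plot a DVARS trace with the outlier fence and retained block
#'
#' @param object A `censor_result` (with a DVARS series).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot censor_result
#' @export
autoplot.censor_result <- function(object, ...) {
  d <- tidy(object)
  if (all(is.na(d$dvars)))
    stop("this censor_result carries no DVARS series", call. = FALSE)
  q <- stats::quantile(d$dvars, c(0.25, 0.75), names = FALSE)
  fence <- q[2L] + 1.5 * (q[2L] - q[1L])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frame, y = .data$dvars)) +
    ggplot2::annotate("rect",
                      xmin = object$block_start,
                      xmax = object$block_start + object$block_length - 1L,
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = fence, linetype = 2, colour = "red") +
    ggplot2::geom_point(data = d[d$outlier, ], colour = "red", size = 0.8) +
    ggplot2::labs(x = "frame", y = "DVARS",
                  title = sprintf("Retained block: frames %d-%d (%d outliers, %s)",
                                  object$block_start,
                                  object$block_start + object$block_length - 1L,
                                  object$outliers_in_block,
                                  if (object$included) "included" else "excluded"))
}

#' Plot per-vertex values on the mesh as a point map
#'
#' Spherical meshes are shown in an area-preserving cylindrical projection
#' (longitude vs z); grid meshes in their native plane.
#'
#' @param mesh A `surface_mesh`.
#' @param values Length-V numeric (continuous) or factor-like (discrete)
#'   vector.
#' @param name Legend title.
#' @return A ggplot object.
#' @export
plot_surface_map <- function(mesh, values, name = "value") {
  stopifnot(inherits(mesh, "surface_mesh"),
            length(values) == mesh$n_vertices)
  p <- mesh$coords
  if (identical(mesh$kind, "sphere")) {
    d <- tibble::tibble(x = atan2(p[, 2], p[, 1]), y = p[, 3] /
                          sqrt(rowSums(p^2)), value = values)
  } else {
    d <- tibble::tibble(x = p[, 1], y = p[, 2], value = values)
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  colour = .data$value)) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = name, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a parcellation on its mesh
#'
#' @param object A `parcellation`.
#' @param mesh The `surface_mesh` it lives on.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot parcellation
#' @export
autoplot.parcellation <- function(object, mesh, ...) {
  plot_surface_map(mesh, factor(object$labels), name = "network") +
    ggplot2::ggtitle(sprintf("Winner-takes-all parcellation (%s)",
                             object$source))
}

#' Plot a frequency map on its mesh
#'
#' @param object A `frequency_map`.
#' @param mesh The `surface_mesh` it lives on.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot frequency_map
#' @export
autoplot.frequency_map <- function(object, mesh, ...) {
  plot_surface_map(mesh, object$dominant_pct, name = "% subjects") +
    ggplot2::scale_colour_viridis_c(option = "inferno") +
    ggplot2::ggtitle("Dominant-label agreement across subjects")
}

#' Plot per-network age associations from a cohort result
#'
#' Scatter of connectivity strength against age at scan per network, with
#' the partial Spearman rho and uncorrected p annotated.
#'
#' @param object A `cohort_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cohort_result
#' @export
autoplot.cohort_result <- function(object, ...) {
  scols <- grep("^strength_", names(object$cohort), value = TRUE)
  d <- tidyr_pivot(object$cohort, scols)
  lab <- NULL
  if (!is.null(object$age_table)) {
    lab <- object$age_table
    lab$txt <- sprintf("rho=%.2f, p=%.2g", lab$rho, lab$p)
  }
  gg <- ggplot2::ggplot(d, ggplot2::aes(x = .data$age_pma_weeks,
                                        y = .data$strength)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linetype = 2, linewidth = 0.5, colour = "steelblue") +
    ggplot2::facet_wrap(~ic, scales = "free_y") +
    ggplot2::labs(x = "age at scan (weeks PMA)",
                  y = "connectivity strength (mean t)")
  if (!is.null(lab))
    gg <- gg + ggplot2::geom_text(data = lab, inherit.aes = FALSE,
                                  ggplot2::aes(label = .data$txt),
                                  x = -Inf, y = Inf, hjust = -0.05,
                                  vjust = 1.5, size = 3)
  gg
}

# minimal long-format pivot of strength columns (avoids a tidyr dependency)
tidyr_pivot <- function(cohort, scols) {
  dplyr::bind_rows(lapply(scols, function(sc) {
    tibble::tibble(ic = sub("^strength_", "", sc),
                   age_pma_weeks = cohort$age_pma_weeks,
                   strength = cohort[[sc]])
  }))
}

#' @importFrom rlang .data
NULL
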