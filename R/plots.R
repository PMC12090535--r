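#' Plot per-fold accuracies of a cross-validation report
#'
#' Points per fold and environment with the across-fold mean as a line, the
#' standard way the scenario comparisons are displayed.
#'
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_report <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$fold), y = .data$r,
                                  colour = .data$env)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = attr(object, "mean_r"),
                        linetype = "dashed") +
    ggplot2::labs(x = "fold", y = "Pearson r",
                  title = sprintf("%s - %s: mean r = %.3f (sd %.3f)",
                                  attr(object, "scenario") %||% "model",
                                  attr(object, "trait"),
                                  attr(object, "mean_r"),
                                  attr(object, "std_r"))) +
    ggplot2::ylim(min(0, min(d$r, na.rm = TRUE)), 1) +
    ggplot2::theme_minimal()
}

#' Posterior densities of the variance components
#'
#' @param object A `kernel_gibbs` fit.
#' @param ... Unused.
#' @return A ggplot object (one panel per variance component).
#' @export
autoplot.kernel_gibbs <- function(object, ...) {
  d <- tibble::as_tibble(object$variance_draws) |>
    dplyr::mutate(.draw = dplyr::row_number()) |>
    tidyr::pivot_longer(-".draw", names_to = "component",
                        values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::facet_wrap(~component, scales = "free") +
    ggplot2::labs(x = "variance component", y = "posterior density") +
    ggplot2::theme_minimal()
}

#' Scenario-by-trait accuracy comparison plot
#'
#' Point-and-errorbar display of a [run_catalog()] table: mean cross-validated
#' Pearson correlation per scenario, one colour per trait, error bars one
#' standard deviation across folds.
#'
#' @param catalog Tibble from [run_catalog()].
#' @return A ggplot object.
#' @export
plot_catalog <- function(catalog) {
  d <- dplyr::filter(catalog, !is.na(.data$mean_r))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$scenario,
                                             levels = scenario_ids()),
                                  y = .data$mean_r, colour = .data$trait)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_r - .data$std_r,
                                        ymax = .data$mean_r + .data$std_r),
                           width = 0.2,
                           position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = NULL, y = "mean CV Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of a kernel matrix
#' @param K A `kernel_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_kernel <- function(K, ...) {
  d <- tibble::as_tibble(unclass(K), rownames = "row") |>
    tidyr::pivot_longer(-"row", names_to = "col", values_to = "value")
  ids <- rownames(K)
  d$row <- factor(d$row, levels = ids)
  d$col <- factor(d$col, levels = rev(ids))
  ggplot2::ggplot(d, ggplot2::aes(.data$row, .data$col,
                                  fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("kernel (%s)", attr(K, "kind"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
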