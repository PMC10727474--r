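# ggplot2 views and broom-style accessors for the result objects.

class_palette <- c(NORMAL = "grey15", CANCER = "white", HYPERTUMOUR = "grey60",
                   PARTIAL_HYPERTUMOUR = "seagreen3", OTHER_MUTANT = "orchid",
                   VACANT = "black")

metric_labels <- c(prop_normal = "normal", prop_cancer = "cancer",
                   prop_hypertumour = "hypertumour",
                   prop_partial_ht = "partial hypertumour",
                   prop_other = "other mutant",
                   mutation_proportion = "mutation proportion")

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation run
#'
#' @param x An `acd_sim`.
#' @param ... Unused.
#' @return The per-step metrics tibble.
#' @export
tidy.acd_sim <- function(x, ...) x$metrics

#' One-row summary of a simulation run
#'
#' @param x An `acd_sim`.
#' @param ... Unused.
#' @return Final-step metrics plus `n_steps` and `seed`.
#' @export
glance.acd_sim <- function(x, ...) {
  dplyr::mutate(utils::tail(x$metrics, 1), n_steps = x$n_steps, seed = x$seed)
}

#' Tidy an ensemble
#'
#' @param x An `acd_ensemble`.
#' @param ... Unused.
#' @return The per-replicate per-step metrics tibble.
#' @export
tidy.acd_ensemble <- function(x, ...) x$replicates

#' One-row-per-replicate summary of an ensemble
#'
#' @param x An `acd_ensemble`.
#' @param ... Unused.
#' @return The final-step tibble (`finals`), one row per replicate.
#' @export
glance.acd_ensemble <- function(x, ...) x$finals

sim_long <- function(metrics) {
  metrics |>
    dplyr::select(dplyr::all_of(c("step", names(metric_labels)))) |>
    tidyr::pivot_longer(-"step", names_to = "metric", values_to = "value") |>
    dplyr::mutate(metric = factor(metric_labels[.data$metric],
                                  levels = unname(metric_labels)))
}

#' Plot the class-proportion dynamics of a run
#'
#' @param object An `acd_sim`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.acd_sim <- function(object, ...) {
  ggplot2::ggplot(sim_long(object$metrics),
                  ggplot2::aes(x = .data$step, y = .data$value,
                               colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time step", y = "proportion among live cells",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot ensemble mean dynamics with an sd ribbon
#'
#' @param object An `acd_ensemble`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.acd_ensemble <- function(object, ...) {
  s <- object$summary
  long_mean <- s |>
    dplyr::select("step", dplyr::ends_with("_mean")) |>
    tidyr::pivot_longer(-"step", names_to = "metric", values_to = "mean") |>
    dplyr::mutate(metric = sub("_mean$", "", .data$metric))
  long_sd <- s |>
    dplyr::select("step", dplyr::ends_with("_sd")) |>
    tidyr::pivot_longer(-"step", names_to = "metric", values_to = "sd") |>
    dplyr::mutate(metric = sub("_sd$", "", .data$metric))
  dat <- dplyr::inner_join(long_mean, long_sd, by = c("step", "metric")) |>
    dplyr::filter(.data$metric %in% names(metric_labels)) |>
    dplyr::mutate(metric = factor(metric_labels[.data$metric],
                                  levels = unname(metric_labels)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$step, y = .data$mean,
                                    colour = .data$metric, fill = .data$metric)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time step", y = "proportion among live cells",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of a phi grid
#'
#' Negative phi (drug promotes hypertumour progression) in blue, positive
#' (drug impedes it) in red, with the phi = 0 boundary drawn.
#'
#' @param object An `acd_phi_grid`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.acd_phi_grid <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ratio, y = .data$g,
                                       fill = .data$phi)) +
    ggplot2::geom_raster() +
    ggplot2::geom_contour(ggplot2::aes(z = .data$phi), breaks = 0,
                          colour = "black", linewidth = 0.3) +
    ggplot2::scale_fill_gradient2(low = "steelblue4", mid = "white",
                                  high = "firebrick3", midpoint = 0) +
    ggplot2::labs(x = "hypertumour / cancer CGF ratio",
                  y = "CGF concentration at the cancer cells",
                  fill = expression(phi),
                  subtitle = paste0("drug factor r = ", attr(object, "drug_r"),
                                    ", F: ", attr(object, "family"))) +
    ggplot2::theme_minimal()
}

#' Plot a lattice as a class map
#'
#' @param lattice An `acd_lattice`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_lattice <- function(lattice, ...) {
  cls <- matrix("VACANT", nrow(lattice), ncol(lattice))
  live <- !is.na(lattice)
  cls[live] <- cell_classes()[class_table()[lattice[live] + 1L] + 1L]
  df <- tibble::tibble(row = rep(seq_len(nrow(lattice)), times = ncol(lattice)),
                       col = rep(seq_len(ncol(lattice)), each = nrow(lattice)),
                       class = factor(as.vector(cls), levels = names(class_palette)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = class_palette, drop = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_void()
}
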