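# ggplot2 views of the main result types.

#' Plot a pocket ranking
#' @param object An `rpi_pocket_ranking` from [rank_pockets()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rpi_pocket_ranking <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$second_rank_bsa,
    y = stats::reorder(.data$pocket_id, .data$second_rank_bsa),
    fill = .data$algorithm)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = expression("second-rank BSA (" * ring(A)^2 * ")"),
      y = NULL, title = "Pocket ranking by second-rank BSA") +
    ggplot2::theme_minimal()
}

#' Plot a hydration profile
#' @param object An `rpi_hydration` from [hydration_profile()].
#' @param ... Unused.
#' @return A ggplot of per-frame water count, relative density and mean Sk.
#' @export
autoplot.rpi_hydration <- function(object, ...) {
  d <- object$per_frame |>
    select("frame", "count", "rel_density", "mean_sk") |>
    tidyr::pivot_longer(-"frame", names_to = "metric")
  ggplot2::ggplot(d, ggplot2::aes(.data$frame, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "frame", y = NULL, title = "Pocket hydration profile") +
    ggplot2::theme_minimal()
}

#' Plot a congruence report
#' @param object An `rpi_congruence` from [congruence_report()] or [gate()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rpi_congruence <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$metric, .data$value,
    fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::labs(y = expression("distance (" * ring(A) * ")"), x = NULL,
      title = "Ligand placement congruence") +
    ggplot2::theme_minimal()
}

#' Interaction-energy scatter of classified compounds
#'
#' Plots the mean interaction free energy to the RNA against the one to the
#' protein, marking the basic (-7 kcal/mol) and elevated (-10 kcal/mol)
#' stabilizer thresholds.
#'
#' @param energies Tibble with `ddg_protein`, `ddg_rna` and optionally
#'   `stabilizer_class` (computed when absent).
#' @return A ggplot.
#' @export
plot_energy_landscape <- function(energies) {
  e <- as_tibble(energies)
  if (!"stabilizer_class" %in% names(e)) e <- classify_energy_table(e)
  ggplot2::ggplot(e, ggplot2::aes(.data$ddg_protein, .data$ddg_rna,
    colour = .data$stabilizer_class, shape = .data$stabilizer_class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-7, -10), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = c(-7, -10), linetype = "dashed") +
    ggplot2::labs(
      x = expression(Delta * Delta * G[Protein] ~ "(kcal/mol)"),
      y = expression(Delta * Delta * G[RNA] ~ "(kcal/mol)"),
      colour = "class", shape = "class") +
    ggplot2::theme_minimal()
}
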