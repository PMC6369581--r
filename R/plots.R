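#' Beta-value distribution per phenotype
#'
#' Density of beta values in each phenotype with the state thresholds
#' drawn as vertical lines (the bimodal landscape view).
#'
#' @param beta Beta-value tibble (`probe_id` + sample columns).
#' @param phenotypes Tibble `sample_id`, `phenotype`.
#' @param t_low,t_high Thresholds to draw.
#' @return A ggplot object.
#' @export
plot_beta_distribution <- function(beta, phenotypes, t_low = 0.25,
                                   t_high = 0.75) {
  long <- tidyr::pivot_longer(beta, -"probe_id", names_to = "sample_id",
                              values_to = "beta") |>
    inner_join(phenotypes, by = "sample_id") |>
    mutate(phenotype = factor(.data$phenotype, methnet_phenotypes()))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$beta, colour = .data$phenotype)) +
    ggplot2::geom_density(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = c(t_low, t_high),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "beta value", y = "density", colour = "phenotype") +
    ggplot2::theme_minimal()
}

#' @describeIn conservation_matrix Heatmap of the conservation matrix.
#' @param object A `methnet_conservation` matrix.
#' @param ... Unused.
#' @export
autoplot.methnet_conservation <- function(object, ...) {
  df <- as_tibble(unclass(object), rownames = "a") |>
    tidyr::pivot_longer(-"a", names_to = "b", values_to = "agreement") |>
    mutate(a = factor(.data$a, methnet_phenotypes()),
           b = factor(.data$b, methnet_phenotypes()))
  ggplot2::ggplot(df, ggplot2::aes(.data$a, .data$b, fill = .data$agreement)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$agreement)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "agreement") +
    ggplot2::theme_minimal()
}

#' Top differentially methylated genes as a diverging bar chart
#'
#' @param top Output of [top_differential()].
#' @return A ggplot object.
#' @export
plot_top_differential <- function(top) {
  df <- mutate(top, gene_id = stats::reorder(.data$gene_id, .data$delta_mean))
  ggplot2::ggplot(df, ggplot2::aes(.data$delta_mean, .data$gene_id,
                                   fill = .data$list)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(positive = "firebrick",
                                          negative = "steelblue")) +
    ggplot2::labs(x = "trimmed mean beta difference (tumor - normal)",
                  y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn differential_network In-degree consistency view: per-target
#'   in-degrees in the normal and tumor networks, retained targets
#'   highlighted.
#' @param object A `methnet_diffnet`.
#' @param ... Unused.
#' @export
autoplot.methnet_diffnet <- function(object, ...) {
  ggplot2::ggplot(object$summaries,
                  ggplot2::aes(.data$in_deg_normal, .data$in_deg_tumor,
                               colour = .data$retained)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_jitter(width = 0.15, height = 0.15, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "steelblue")) +
    ggplot2::labs(x = "in-degree (normal)", y = "in-degree (tumor)",
                  colour = "retained",
                  title = paste("Stage", object$stage %||% "")) +
    ggplot2::theme_minimal()
}

#' @describeIn gain_loss_table Stacked bar chart of gain/loss counts per
#'   stage.
#' @param x Output of [gain_loss_table()].
#' @export
plot_gain_loss <- function(x) {
  df <- tidyr::pivot_longer(x, c("gain", "loss"), names_to = "direction",
                            values_to = "n")
  ggplot2::ggplot(df, ggplot2::aes(.data$stage, .data$n,
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(gain = "firebrick",
                                          loss = "seagreen")) +
    ggplot2::labs(x = "tumor stage", y = "differential edges", fill = NULL) +
    ggplot2::theme_minimal()
}
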