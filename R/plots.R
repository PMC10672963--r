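#' Plot pathway perturbation scores
#'
#' Horizontal bar chart of the most perturbed pathways (largest
#' `|log score|`), colored by direction; the dashed line marks the neutral
#' score of 1.
#'
#' @param object A `pathway_scores` tibble from [score_pathways()].
#' @param n Number of pathways to show (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pathway_scores <- function(object, n = 20, ...) {
  df <- object %>%
    dplyr::filter(!is.na(.data$score)) %>%
    dplyr::mutate(label = paste(.data$metabolite_id, .data$direction)) %>%
    utils::head(n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$score,
    y = stats::reorder(.data$label, abs(log(.data$score))),
    fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "pathway perturbation score (log scale)", y = NULL,
                  fill = "direction") +
    ggplot2::theme_minimal()
}

#' Plot the reaction weights of a pathway
#'
#' @param object A `met_pathway`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.met_pathway <- function(object, ...) {
  df <- dplyr::arrange(object$weights, .data$weight)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$weight,
    y = factor(.data$reaction_id, levels = df$reaction_id))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      title = sprintf("%s %s pathway (%s)", object$metabolite_id,
                      object$direction, paste(object$provenance, collapse = "+")),
      x = "flux weight", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot subsystem hit scores
#'
#' @param subsys Tibble from [subsystem_scores()].
#' @return A ggplot object.
#' @export
plot_subsystem_scores <- function(subsys) {
  ggplot2::ggplot(subsys, ggplot2::aes(
    x = .data$score, y = stats::reorder(.data$subsystem, .data$score))) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "mean hit x perturbation score", y = NULL) +
    ggplot2::theme_minimal()
}
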