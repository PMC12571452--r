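#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cross-validation report
#'
#' Per-fold metric values as points with the cross-fold mean marked per
#' metric.
#'
#' @param object A `cgsda_cv` report from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cgsda_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::filter(object, !.data$fold %in% c("mean", "sd")),
    -"fold", names_to = "metric", values_to = "value")
  means <- tidyr::pivot_longer(
    dplyr::filter(object, .data$fold == "mean"),
    -"fold", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.6) +
    ggplot2::geom_point(data = means, colour = "red", shape = 18, size = 3) +
    ggplot2::labs(x = NULL, y = "metric value",
                  title = "Cross-validation metrics by fold") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot the training loss trajectory of a fitted model
#'
#' @param model A `cgsda_model`.
#' @return A ggplot object.
#' @export
plot_training_loss <- function(model) {
  df <- tibble::tibble(epoch = seq_along(model$losses), loss = model$losses)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "binary cross-entropy",
                  title = "Training loss") +
    ggplot2::theme_minimal()
}

#' Heatmap of the predicted snoRNA x disease score block
#'
#' @param model A `cgsda_model`.
#' @param max_snornas Cap on the number of snoRNA rows drawn (highest
#'   row-max scores first) to keep the panel readable.
#' @return A ggplot object.
#' @export
plot_score_heatmap <- function(model, max_snornas = 50) {
  S <- model$sd_scores
  keep <- utils::head(order(-apply(S, 1, max)), max_snornas)
  df <- tidyr::pivot_longer(
    tibble::as_tibble(S[keep, , drop = FALSE], rownames = "snorna_id"),
    -"snorna_id", names_to = "disease_id", values_to = "score")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$disease_id, y = .data$snorna_id,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "disease", y = "snoRNA",
                  title = "Predicted association scores") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
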