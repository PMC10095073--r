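#' Plot per-repeat metrics of an experiment
#'
#' Boxplots of the five evaluation metrics across the experiment's repeated
#' train/test splits.
#'
#' @param object A `driver_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.driver_experiment <- function(object, ...) {
  tidy(object) |>
    tidyr::pivot_longer(c("auc", "pr_auc", "balanced_accuracy", "f1", "mcc"),
                        names_to = "metric", values_to = "value") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Prognosis prediction across repeated splits") +
    ggplot2::theme_minimal()
}

#' Plot the threshold-selection curve of a feature selection
#'
#' Mean cross-validated AUC per candidate p-value threshold, with the
#' chosen threshold highlighted.
#'
#' @param object A `feature_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.feature_selection <- function(object, ...) {
  ggplot2::ggplot(object$fold_auc,
                  ggplot2::aes(x = factor(.data$threshold), y = .data$mean_auc)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_col(data = dplyr::filter(object$fold_auc,
                                           .data$threshold == object$chosen_threshold),
                      fill = "steelblue") +
    ggplot2::labs(x = "p-value threshold", y = "mean fold AUC",
                  title = "Cross-validated threshold choice") +
    ggplot2::theme_minimal()
}

#' Plot prognostic-gene selection frequencies
#'
#' @param freq A `gene_frequency` tibble from [rank_frequency()].
#' @param top Show at most this many genes. Default 40.
#' @return A ggplot object.
#' @export
plot_gene_frequency <- function(freq, top = 40) {
  dat <- head(dplyr::filter(freq, .data$count > 0), top)
  ggplot2::ggplot(dat, ggplot2::aes(x = stats::reorder(.data$gene, .data$count),
                                    y = .data$count, fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "repeats in top k", fill = "selected",
                  title = "Prognostic-gene frequency across repeats") +
    ggplot2::theme_minimal()
}
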