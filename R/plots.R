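# ggplot2 graphics for the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Score density with the percentile cutoff
#'
#' Kernel density of the similarity-score distribution with the retained
#' top slice marked by the cutoff line.
#'
#' @param object A `threshold_result` from [percentile_threshold()].
#' @param bandwidth Kernel bandwidth (default 0.01).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot threshold_result
#' @export
autoplot.threshold_result <- function(object, bandwidth = 0.01, ...) {
  full <- object$all_scores
  dens_src <- if (!is.null(full)) tibble::tibble(score = full) else {
    tibble::tibble(score = object$retained$score)
  }
  ggplot2::ggplot(dens_src, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_density(bw = bandwidth, fill = "grey80", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$cutoff_score,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(
      x = "similarity score", y = "density",
      title = sprintf("Score density (cutoff %.4f at percentile %g)",
                      object$cutoff_score, object$percentile)
    ) +
    ggplot2::theme_minimal()
}

#' ROC curve plot
#'
#' @param object A `roc_result` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Replicate ROC curves of an averaged experiment
#'
#' @param object A `roc_experiment` from [averaged_auc_experiment()].
#' @param ... Unused.
#' @return A ggplot object overlaying every replicate curve.
#' @method autoplot roc_experiment
#' @export
autoplot.roc_experiment <- function(object, ...) {
  curves <- purrr::imap(object$curves, function(cv, i) {
    dplyr::mutate(cv, replicate = factor(i))
  }) |>
    dplyr::bind_rows()
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                       group = .data$replicate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_step(alpha = 0.4) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("%d ROC replicates (mean AUC = %.3f)",
                                  object$n_reps, object$mean_auc)) +
    ggplot2::theme_minimal()
}

#' Degree distribution of a gene network
#'
#' @param net A `gene_network` (or edge tibble).
#' @param ... Unused.
#' @return A ggplot histogram of node degrees (isolated nodes included at 0).
#' @export
plot_degree_distribution <- function(net, ...) {
  deg <- degree_table(net)
  ggplot2::ggplot(deg, ggplot2::aes(x = .data$degree)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = "degree", y = "genes") +
    ggplot2::theme_minimal()
}
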