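# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a network comparison report
#'
#' Pivots the one-row report into a long (statistic, value) table, the shape
#' used for printed intersection-statistics tables.
#'
#' @param x A `net_compare` row (from [compare_networks()] or
#'   [comparison_from_counts()]).
#' @param ... Unused.
#' @return A tibble with columns `reference`, `query`, `statistic`, `value`.
#' @method tidy net_compare
#' @export
tidy.net_compare <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(
      cols = -c("reference", "query"),
      names_to = "statistic", values_to = "value"
    )
}

#' Glance at a threshold result
#' @param x A `threshold_result` from [percentile_threshold()].
#' @param ... Unused.
#' @return A one-row tibble: `percentile`, `cutoff_score`, `n_input`,
#'   `n_retained`, `retained_fraction`.
#' @method glance threshold_result
#' @export
glance.threshold_result <- function(x, ...) {
  tibble::tibble(
    percentile = x$percentile, cutoff_score = x$cutoff_score,
    n_input = x$n_input, n_retained = nrow(x$retained),
    retained_fraction = nrow(x$retained) / x$n_input
  )
}

#' Tidy a threshold result
#' @param x A `threshold_result`.
#' @param ... Unused.
#' @return The retained edge tibble.
#' @method tidy threshold_result
#' @export
tidy.threshold_result <- function(x, ...) {
  tibble::as_tibble(x$retained)
}

#' Tidy a replicated ROC experiment
#' @param x A `roc_experiment` from [averaged_auc_experiment()].
#' @param ... Unused.
#' @return A tibble with one row per replicate: `replicate`, `auc`.
#' @method tidy roc_experiment
#' @export
tidy.roc_experiment <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$aucs), auc = x$aucs)
}

#' Glance at a replicated ROC experiment
#' @param x A `roc_experiment`.
#' @param ... Unused.
#' @return A one-row tibble: `mean_auc`, `sd_auc`, `n_reps`.
#' @method glance roc_experiment
#' @export
glance.roc_experiment <- function(x, ...) {
  tibble::tibble(mean_auc = x$mean_auc, sd_auc = stats::sd(x$aucs),
                 n_reps = x$n_reps)
}

#' Tidy a ROC curve
#' @param x A `roc_result` from [roc_auc()].
#' @param ... Unused.
#' @return The curve tibble (`threshold`, `fpr`, `tpr`).
#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) {
  tibble::as_tibble(x$curve)
}

#' Glance at a ROC result
#' @param x A `roc_result`.
#' @param ... Unused.
#' @return A one-row tibble: `auc`, `n_tp`, `n_fp`.
#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_tp = x$n_tp, n_fp = x$n_fp)
}
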