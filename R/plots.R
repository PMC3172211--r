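#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' ROC curve and threshold sweep of a cross-validated run
#'
#' @param object A `mir_eval`.
#' @param type `"roc"` (default) or `"sweep"` (Sen/Spe/Acc and scaled MCC
#'   against threshold).
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot mir_eval
#' @export
autoplot.mir_eval <- function(object, type = c("roc", "sweep"), ...) {
  type <- match.arg(type)
  if (type == "roc") {
    ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                           colour = "grey60") +
      ggplot2::geom_path(colour = "#2166ac") +
      ggplot2::labs(
        x = "False positive rate (1 - specificity)",
        y = "True positive rate (sensitivity)",
        title = sprintf("%s, window %d: AUC %.3f",
                        toupper(object$config$encoding),
                        object$config$window, object$auc)) +
      ggplot2::coord_equal() +
      ggplot2::theme_minimal()
  } else {
    long <- object$by_threshold |>
      dplyr::mutate(mcc = 100 * .data$mcc) |>
      tidyr::pivot_longer(c("sen", "spe", "acc", "mcc"),
                          names_to = "metric", values_to = "value")
    ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$value,
                                       colour = .data$metric)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "Decision threshold", y = "Percent (MCC x 100)",
                    colour = NULL) +
      ggplot2::theme_minimal()
  }
}

#' Composition comparison bar chart
#'
#' Side-by-side percentages for the interacting and non-interacting groups of
#' a composition table (per residue, property class or whole pattern).
#'
#' @param object A `mir_composition`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot mir_composition
#' @export
autoplot.mir_composition <- function(object, ...) {
  key <- names(object)[1]
  long <- tidyr::pivot_longer(
    as.data.frame(object)[, c(key, "interacting_pct", "non_interacting_pct")],
    -dplyr::all_of(key), names_to = "group", values_to = "pct")
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[key]], y = .data$pct,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(
      values = c(interacting_pct = "#b2182b", non_interacting_pct = "#2166ac"),
      labels = c("interacting", "non-interacting")) +
    ggplot2::labs(x = NULL, y = "Composition (%)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Per-position frequency-difference heatmap (two-sample logo data)
#'
#' @param diff_table Output of [positional_frequency_difference()].
#' @return A ggplot.
#' @export
plot_positional_differences <- function(diff_table) {
  ggplot2::ggplot(diff_table,
                  ggplot2::aes(x = .data$pos, y = .data$residue,
                               fill = .data$difference)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", high = "#b2182b",
                                  mid = "white") +
    ggplot2::geom_vline(
      xintercept = unique(diff_table$pos[diff_table$center]),
      linetype = "dashed") +
    ggplot2::labs(x = "Window position", y = NULL,
                  fill = "freq(+) - freq(-)") +
    ggplot2::theme_minimal()
}
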