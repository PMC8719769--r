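# ggplot2 presentation of result types: ROC / PR curves, loss histories, and
# synthetic samples.

#' Plot an evaluation curve
#'
#' @param object A `davsnet_curve` from [roc_curve()] or [pr_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.davsnet_curve <- function(object, ...) {
  type <- attr(object, "curve_type")
  auc <- attr(object, "auc")
  if (identical(type, "roc")) {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                           colour = "grey60") +
      ggplot2::geom_path() +
      ggplot2::labs(x = "False positive rate (1 - specificity)",
                    y = "True positive rate (sensitivity)",
                    title = sprintf("ROC curve (AUC = %.4f)", auc))
  } else {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$recall, y = .data$precision)) +
      ggplot2::geom_path() +
      ggplot2::coord_cartesian(ylim = c(0, 1)) +
      ggplot2::labs(x = "Recall (sensitivity)", y = "Precision",
                    title = sprintf("Precision-recall curve (AUCPR = %.4f)", auc))
  }
}

#' Plot a training loss history
#'
#' @param object A `davsnet_fit`.
#' @param ... Unused.
#' @return A ggplot of loss against iteration.
#' @export
autoplot.davsnet_fit <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$iteration, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Iteration", y = "Weighted cross-entropy",
                  title = "Training loss")
}

#' Plot a synthetic fundus sample
#'
#' Shows the green channel with the vessel mask and field-of-view boundary
#' overlaid, faceted as image / ground truth.
#'
#' @param object A `fundus_sample`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fundus_sample <- function(object, ...) {
  H <- nrow(object$vessel_mask); W <- ncol(object$vessel_mask)
  df <- tidyr::expand_grid(row = seq_len(H), col = seq_len(W))
  df <- dplyr::bind_rows(
    mutate(df, value = as.vector(t(object$image[, , 2])), panel = "image (green channel)"),
    mutate(df, value = as.vector(t(object$vessel_mask)), panel = "vessel ground truth")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::facet_wrap(~panel) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
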