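# Minimal base-graphics views of the two headline result types.

#' Stacked-bar view of signature arm compositions
#'
#' One bar per chromosome arm, stacked by signature basis weight, showing
#' which arms define each signature.
#'
#' @param model a `signature_model`.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the bar midpoints.
#' @export
plot_signature_composition <- function(model, ...) {
  graphics::barplot(t(model$W), beside = FALSE, las = 2,
                    col = grDevices::hcl.colors(model$k, "Dark 3"),
                    legend.text = colnames(model$W),
                    xlab = "chromosome arm", ylab = "basis weight", ...)
}

#' Plot a ROC curve
#'
#' @param scores numeric classifier scores.
#' @param labels logical true labels.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the AUC.
#' @export
plot_roc <- function(scores, labels, ...) {
  rc <- roc_curve(scores, labels)
  auc <- roc_auc(scores, labels)
  graphics::plot(rc$fpr, rc$tpr, type = "l",
                 xlab = "false positive rate", ylab = "true positive rate",
                 main = sprintf("ROC AUC = %.3f", auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(auc)
}
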