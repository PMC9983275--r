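# ggplot2 autoplot methods for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Kaplan-Meier curves of a risk stratification
#'
#' @param object a `risk_stratification` with survival data.
#' @param ... unused.
#' @return a ggplot: step survival curves per risk group, log-rank p in the
#'   subtitle.
#' @export
autoplot.risk_stratification <- function(object, ...) {
  if (is.null(object$km)) stop("no survival data attached to this stratification")
  km <- dplyr::bind_rows(
    tidyr::expand_grid(group = unique(object$km$group),
                       time = 0, survival = 1, n_risk = NA, n_event = NA),
    object$km)
  ggplot2::ggplot(km, ggplot2::aes(.data$time, .data$survival,
                                   color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "time (days)", y = "survival probability", color = "risk group",
      title = "Kaplan-Meier survival by risk group",
      subtitle = if (!is.null(object$logrank)) {
        sprintf("log-rank p = %.3g", object$logrank$p)
      } else NULL) +
    ggplot2::theme_minimal()
}

#' ROC curve of the best subset of a classifier search
#'
#' @param object a `subset_search` or `roc_result`.
#' @param ... unused.
#' @return a ggplot of the ROC polyline with the chance diagonal.
#' @export
autoplot.subset_search <- function(object, ...) {
  p <- autoplot.roc_result(
    structure(list(auc = object$best$auc, roc = object$best$roc),
              class = "roc_result"))
  p + ggplot2::labs(subtitle = paste("genes:",
                                     paste(object$best$genes, collapse = ", ")))
}

#' @rdname autoplot.subset_search
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' RNs prioritization bar chart
#'
#' @param object an `rns_table`.
#' @param top_n how many genes to show.
#' @param ... unused.
#' @return a ggplot of RNs scores, highest first.
#' @export
autoplot.rns_table <- function(object, top_n = 10, ...) {
  d <- utils::head(object, top_n)
  ggplot2::ggplot(d, ggplot2::aes(.data$RNs,
                                  stats::reorder(.data$gene_id, .data$RNs))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "RNs score", y = NULL,
                  title = "Gene prioritization by RNs") +
    ggplot2::theme_minimal()
}
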