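#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a ROC curve with its selected cutoff
#'
#' @param object A `roc_curve` from [compute_roc()].
#' @param ... Unused.
#' @return A ggplot: FPR against TPR, with the operating point at the
#'   maximum of TPR - FPR marked.
#' @method autoplot roc_curve
#' @export
autoplot.roc_curve <- function(object, ...) {
  cut <- select_cutoff(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point(data = cut, colour = "red", size = 2) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  subtitle = sprintf("cutoff ratio %.4g (J = %.3f)",
                                     cut$threshold, cut$j)) +
    ggplot2::theme_minimal()
}

#' Plot all replicate ROC curves of an extraction
#'
#' @param object A `surfaceome_extraction` with computed curves.
#' @param ... Unused.
#' @return A ggplot of the per-replicate ROC curves with each selected
#'   operating point.
#' @method autoplot surfaceome_extraction
#' @export
autoplot.surfaceome_extraction <- function(object, ...) {
  if (is.null(object$curves)) {
    stop("extraction was run with injected thresholds; no ROC curves",
         call. = FALSE)
  }
  curves <- dplyr::bind_rows(
    lapply(object$curves, tibble::as_tibble), .id = "replicate"
  )
  cuts <- object$cutoffs
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point(data = cuts, colour = "red", size = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$replicate)) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate") +
    ggplot2::theme_minimal()
}

#' Volcano plot of the moderated interaction fit
#'
#' @param object A `moderated_fit` from [fit_interaction_model()].
#' @param fdr FDR threshold colouring significant proteins.
#' @param ... Unused.
#' @return A ggplot: interaction log2 fold change against -log10 p.
#' @method autoplot moderated_fit
#' @export
autoplot.moderated_fit <- function(object, fdr = 0.05, ...) {
  d <- dplyr::mutate(object$results,
                     significant = .data$q < fdr)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$b3,
                                  y = -log10(.data$p),
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey50", `TRUE` = "firebrick"),
      name = sprintf("q < %.2g", fdr)
    ) +
    ggplot2::labs(
      x = expression(b[3] ~ "(mature vs developing, log2)"),
      y = expression(-log[10](p))
    ) +
    ggplot2::theme_minimal()
}
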