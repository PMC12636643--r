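#' Volcano plot of differential abundance results
#'
#' @param object a `dap_table` from [dap_linear()].
#' @param p_cutoff horizontal significance line (raw p).
#' @param label_top number of top proteins to label.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.dap_table <- function(object, p_cutoff = 0.05, label_top = 10, ...) {
  df <- dplyr::mutate(object,
                      sig = .data$p_value < p_cutoff,
                      nlp = -log10(pmax(.data$p_value, 1e-300)))
  lab <- df |> dplyr::arrange(.data$p_value) |> head(label_top)
  ggplot2::ggplot(df, ggplot2::aes(.data$coefficient, .data$nlp)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$sig), alpha = 0.6,
                        show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::geom_hline(yintercept = -log10(p_cutoff), linetype = 2) +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$protein_id),
                       size = 2.7, vjust = -0.6) +
    ggplot2::labs(x = "coefficient (log2 abundance per trait unit)",
                  y = expression(-log[10] ~ p)) +
    ggplot2::theme_minimal()
}

#' Module enrichment Z-score plot
#'
#' Bars of per-module Z scores with the dashed line at the smallest Z among
#' FDR-significant modules.
#'
#' @param object an `enrichment_result`, ideally after [fdr_over_modules()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.enrichment_result <- function(object, ...) {
  thr <- attr(object, "z_threshold")
  gg <- ggplot2::ggplot(object,
                        ggplot2::aes(stats::reorder(.data$module_id, -.data$z),
                                     .data$z)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "module", y = "enrichment Z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (!is.null(thr) && is.finite(thr)) {
    gg <- gg + ggplot2::geom_hline(yintercept = thr, linetype = 2,
                                   colour = "red")
  }
  gg
}

#' ROC curves of a panel evaluation
#'
#' One translucent step curve per permuted run, with the run achieving the
#' median AUC highlighted.
#'
#' @param object a `panel_eval` from [evaluate_panel()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.panel_eval <- function(object, ...) {
  med_run <- object$runs$run[which.min(abs(object$runs$auc -
                                             object$median_auc))]
  ggplot2::ggplot(object$roc, ggplot2::aes(.data$fpr, .data$tpr,
                                           group = .data$run)) +
    ggplot2::geom_step(alpha = 0.15, colour = "grey40") +
    ggplot2::geom_step(data = dplyr::filter(object$roc,
                                            .data$run == med_run),
                       colour = "firebrick", linewidth = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("median AUC %.2f [%.2f-%.2f], %d runs",
                      object$median_auc, object$auc_ci[1], object$auc_ci[2],
                      object$n_runs)) +
    ggplot2::theme_minimal()
}

#' Selection-frequency plot of a stability-selected panel
#'
#' @param object a `panel_selection` from [stability_select()].
#' @param top show only the `top` most frequently selected features.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.panel_selection <- function(object, top = 30, ...) {
  df <- head(dplyr::arrange(object, dplyr::desc(.data$frequency)), top)
  ggplot2::ggplot(df, ggplot2::aes(stats::reorder(.data$feature,
                                                  .data$frequency),
                                   .data$frequency,
                                   fill = .data$selected)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = attr(object, "threshold"), linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "bootstrap selection frequency") +
    ggplot2::theme_minimal()
}

#' Positional-probability heatmap of a fitted event sequence
#'
#' @param object an `event_sequence` from [fit_event_sequence()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.event_sequence <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(biomarker = factor(.data$biomarker, levels = rev(object$order)))
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$biomarker,
                                   fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "event position", y = NULL) +
    ggplot2::theme_minimal()
}
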