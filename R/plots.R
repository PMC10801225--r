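## Figure builders.  All plots are drawn from data already present in
## the JSON/CSV artifacts; they add no information of their own.

#' Paired factual/counterfactual influence bar chart
#'
#' Horizontal bars of the display-normalized feature influences for the
#' predicted class (left panel) and the runner-up class (right panel).
#'
#' @param bundle an `ExplanationBundle`.
#' @return A ggplot object.
#' @export
plot_influences <- function(bundle) {
  df <- rbind(
    data.frame(feature = names(bundle$normalized$factual),
               influence = as.numeric(bundle$normalized$factual),
               case = paste0("factual: ", bundle$predicted)),
    data.frame(feature = names(bundle$normalized$counterfactual),
               influence = as.numeric(bundle$normalized$counterfactual),
               case = paste0("counterfactual: ", bundle$runner_up)))
  df$case <- factor(df$case, levels = unique(df$case))
  df$feature <- factor(df$feature, levels = rev(feature_names()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$influence,
                                   y = .data$feature,
                                   fill = .data$influence > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(~case) +
    ggplot2::labs(x = "normalized influence", y = NULL,
                  title = sprintf("Node %s: predicted %s (p = %.2f)",
                                  bundle$id, bundle$predicted,
                                  max(bundle$probabilities))) +
    ggplot2::theme_minimal()
}

#' Modality-group influence chart
#'
#' @param bundle an `ExplanationBundle`.
#' @return A ggplot object (bars per group, factual vs counterfactual).
#' @export
plot_group_influences <- function(bundle) {
  G <- bundle$group_influences
  df <- rbind(
    data.frame(group = rownames(G), influence = G[, bundle$predicted],
               case = paste0("factual: ", bundle$predicted)),
    data.frame(group = rownames(G), influence = G[, bundle$runner_up],
               case = paste0("counterfactual: ", bundle$runner_up)))
  df$case <- factor(df$case, levels = unique(df$case))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$influence, y = .data$group,
                                   fill = .data$influence > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(~case) +
    ggplot2::labs(x = "probability variation", y = NULL) +
    ggplot2::theme_minimal()
}

#' Neighbor class composition chart
#'
#' @param bundle an `ExplanationBundle`.
#' @return A ggplot object (percentage of connected subjects per class).
#' @export
plot_neighbor_profile <- function(bundle) {
  df <- data.frame(class = factor(names(bundle$neighbor_profile),
                                  levels = class_levels()),
                   pct = as.numeric(bundle$neighbor_profile))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$pct,
                                   fill = .data$class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "% of connected subjects") +
    ggplot2::theme_minimal()
}

#' Explanation-stability distances across thresholds
#'
#' @param report a `StabilityReport`.
#' @return A ggplot object (per-feature |max - min| influence distance,
#'   one line per threshold).
#' @export
plot_stability <- function(report) {
  D <- report$distances
  df <- do.call(rbind, lapply(seq_len(nrow(D)), function(t)
    data.frame(threshold = rownames(D)[t], feature = colnames(D),
               distance = D[t, ])))
  df$feature <- factor(df$feature, levels = feature_names())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature,
                                   y = .data$distance,
                                   group = .data$threshold,
                                   colour = .data$threshold)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "|max - min| influence") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Decomposition-vs-Shapley agreement scatter
#'
#' @param agreement result of [method_agreement()].
#' @return A ggplot object, one panel per predicted class, with the
#'   per-class Pearson r in the panel label.
#' @export
plot_agreement <- function(agreement) {
  df <- agreement$pairs
  rlab <- vapply(class_levels(), function(cl) {
    r <- agreement$per_class[[cl]]$r
    sprintf("%s (r = %.3f)", cl, if (is.null(r)) NA_real_ else r)
  }, "")
  df$panel <- factor(rlab[df$class], levels = rlab)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$shapley,
                                   y = .data$decomposition)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = "Shapley attribution",
                  y = "decomposition influence") +
    ggplot2::theme_minimal()
}

## save a plot, preferring SVG when the device is available
save_figure <- function(p, path_base, width = 8, height = 5) {
  if (capabilities("cairo")) {
    path <- paste0(path_base, ".svg")
    grDevices::svg(path, width = width, height = height)
  } else {
    path <- paste0(path_base, ".png")
    grDevices::png(path, width = width * 100, height = height * 100)
  }
  print(p)
  grDevices::dev.off()
  invisible(path)
}
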