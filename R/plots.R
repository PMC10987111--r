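#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_abline geom_hline
#'   geom_vline geom_tile facet_wrap labs theme_minimal scale_fill_gradient2
#'   autoplot
NULL

#' Plot the training loss curve
#'
#' @param object A `gat_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gat_model <- function(object, ...) {
  ggplot(object$loss_history, aes(x = .data$epoch, y = .data$loss)) +
    geom_line(color = "#2c7fb8") +
    labs(x = "epoch", y = "training MSE (normalized labels)",
         title = "Graph-attention regressor training loss") +
    theme_minimal()
}

#' Parity plot of predictions against observations
#'
#' @param object An `eval_report` from [evaluate_model()].
#' @param ... Unused.
#' @return A ggplot, one panel per split, with the identity line.
#' @export
autoplot.eval_report <- function(object, ...) {
  resid <- attr(object, "residuals")
  ggplot(resid, aes(x = .data$observed, y = .data$predicted)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, color = "grey50") +
    geom_point(alpha = 0.4, size = 0.8, color = "#2c7fb8") +
    facet_wrap(~split) +
    labs(x = "observed label", y = "predicted label") +
    theme_minimal()
}

#' Calibrated B/K score map of candidate payloads
#'
#' Scatter of the reference-calibrated delta scores; the reference payload
#' sits at the (0, 0) origin and the dashed line marks the bystander
#' threshold on the absolute B score.
#'
#' @param object A `payload_scores` tibble from [score_candidates()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.payload_scores <- function(object, ...) {
  cfg <- attr(object, "config")
  ref <- attr(object, "reference")
  p <- ggplot(object, aes(x = .data$delta_b, y = .data$delta_k)) +
    geom_hline(yintercept = 0, color = "grey80") +
    geom_vline(xintercept = 0, color = "grey80") +
    geom_point(aes(color = .data$bystander_flag), size = 2) +
    labs(x = "delta B score (vs reference)",
         y = "delta K score (vs reference)",
         color = "bystander flag") +
    theme_minimal()
  if (!is.null(cfg) && !is.null(ref)) {
    p <- p + geom_vline(xintercept = cfg$b_threshold - ref[["b"]],
                        linetype = 2, color = "#d95f02")
  }
  p
}

#' Heat map of candidate scores
#'
#' @param tab A `score_heatmap_table` from [score_heatmap_table()].
#' @return A ggplot tile map (candidate x metric), values scaled per metric.
#' @export
plot_score_heatmap <- function(tab) {
  tab <- dplyr::mutate(dplyr::group_by(tab, .data$metric),
                       scaled = as.numeric(scale(.data$value)))
  ggplot(tab, aes(x = .data$metric, y = .data$id, fill = .data$scaled)) +
    geom_tile(color = "white") +
    scale_fill_gradient2(low = "#4575b4", mid = "#ffffbf", high = "#d73027",
                         name = "z score") +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}
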