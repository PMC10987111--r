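#' Squared Pearson correlation
#'
#' The model-selection and evaluation metric: the square of the Pearson
#' correlation coefficient between predictions and observations. Note that it
#' is sign-blind (`pearson_r2(-y, y)` is 1) and differs from the coefficient
#' of determination for biased predictions; see [r_squared()] for the latter.
#' Returns 0 with a warning when either vector has zero variance.
#'
#' @param pred,obs Finite numeric vectors of equal length >= 2.
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' pearson_r2(c(1, 2, 3), c(1.1, 2.2, 2.9))
pearson_r2 <- function(pred, obs) {
  if (length(pred) != length(obs)) {
    stop_bk("`pred` and `obs` must have equal length.", "bkscore_config_error")
  }
  if (length(pred) < 2L || any(!is.finite(pred)) || any(!is.finite(obs))) {
    stop_bk("Need >= 2 finite values in both vectors.",
            "bkscore_config_error")
  }
  if (sd(pred) == 0 || sd(obs) == 0) {
    warn("Zero variance in predictions or observations; Pearson R2 set to 0.")
    return(0)
  }
  cor(pred, obs)^2
}

#' Coefficient of determination
#'
#' Secondary metric: `1 - SS_res / SS_tot`. Can be negative for models worse
#' than the mean predictor.
#'
#' @inheritParams pearson_r2
#' @return A number `<= 1`.
#' @export
r_squared <- function(pred, obs) {
  if (length(pred) != length(obs)) {
    stop_bk("`pred` and `obs` must have equal length.", "bkscore_config_error")
  }
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) {
    warn("Zero variance in observations; coefficient of determination NaN.")
    return(NaN)
  }
  1 - sum((obs - pred)^2) / ss_tot
}

#' Evaluate a trained model on dataset splits
#'
#' Predicts every record and summarizes squared Pearson correlation per
#' split.
#'
#' @param model A `gat_model` or `baseline_model`.
#' @param ds A [labeled_dataset()].
#' @param split Optional [random_split()]; without it the whole dataset is
#'   reported as one `"all"` split.
#' @param graphs Optional precomputed graphs aligned with `ds`.
#' @return An `eval_report` tibble with columns `split`, `n`, `pearson_r2`,
#'   `r_squared`; per-molecule residuals are attached as attribute
#'   `residuals` (tibble: id, split, observed, predicted, residual).
#' @export
evaluate_model <- function(model, ds, split = NULL, graphs = NULL) {
  pred <- if (inherits(model, "gat_model")) {
    g <- graphs %||% (if ("graph" %in% names(ds)) ds$graph
                      else featurize_smiles(ds$canonical_smiles))
    predict(model, g)
  } else {
    predict(model, ds)
  }
  split_col <- if (is.null(split)) rep("all", nrow(ds))
               else as.character(split$split)
  resid <- tibble(id = ds$id, split = split_col, observed = ds$label,
                  predicted = pred, residual = pred - ds$label)
  lev <- if (is.null(split)) unique(split_col)
         else c("train", "valid", "test")
  out <- dplyr::summarise(
    dplyr::group_by(resid, split = factor(split_col, levels = lev)),
    n = dplyr::n(),
    pearson_r2 = pearson_r2(.data$predicted, .data$observed),
    r_squared = r_squared(.data$predicted, .data$observed),
    .groups = "drop")
  structure(out, residuals = resid,
            class = c("eval_report", class(out)))
}
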