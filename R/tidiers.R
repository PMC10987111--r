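#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the training history of a GAT model
#'
#' @param x A `gat_model`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: `epoch`, `loss`.
#' @export
tidy.gat_model <- function(x, ...) x$loss_history

#' One-row summary of a trained GAT model
#'
#' @param x A `gat_model`.
#' @param ... Unused.
#' @return Tibble: layer/width configuration, parameter count, training
#'   size, epochs and final normalized training loss.
#' @export
glance.gat_model <- function(x, ...) {
  tibble(
    n_layers = x$gat_config$n_layers,
    head_agg = paste(x$gat_config$head_agg_modes, collapse = "/"),
    n_params = sum(vapply(x$params, length, 0L)),
    n_train = x$n_train,
    n_epochs = nrow(x$loss_history),
    final_loss = utils::tail(x$loss_history$loss, 1),
    label_kind = x$label_kind,
    schema = x$schema_version)
}

#' Tidy a tuning run
#'
#' @param x A `tune_result` from [tune_gat()].
#' @param ... Unused.
#' @return The trial table (one row per sampled configuration).
#' @export
tidy.tune_result <- function(x, ...) x$trials

#' @export
glance.tune_result <- function(x, ...) {
  dplyr::bind_cols(tibble(n_trials = nrow(x$trials),
                          n_failed = sum(x$trials$failed)),
                   x$best_trial["valid_pearson_r2"])
}

#' Tidy a panel validation
#'
#' @param x A `panel_validation` from [validate_panel()].
#' @param ... Unused.
#' @return Per-payload table with predicted and observed flags.
#' @export
tidy.panel_validation <- function(x, ...) x$details

#' @export
glance.panel_validation <- function(x, ...) x$metrics
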