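#' Hyperparameter search space
#'
#' The bounded space the reference protocol searched: learning rate and
#' weight decay log-uniform, epochs integer-uniform, batch size and
#' predictor width categorical, predictor dropout log-uniform. Sampled
#' values always lie inside the bounds.
#'
#' @param lr_range Log-uniform bounds for the learning rate.
#' @param weight_decay_range Log-uniform bounds for the weight decay.
#' @param n_epochs_range Integer bounds for the number of epochs.
#' @param batch_size_choices Categorical batch sizes.
#' @param predictor_hidden_choices Categorical predictor widths.
#' @param predictor_dropout_range Log-uniform bounds for dropout.
#' @param n_trials Number of sampled configurations.
#' @param seed Integer seed for the sampler.
#' @return A `hyperparameter_space`.
#' @export
hyperparameter_space <- function(lr_range = c(1e-5, 1e-2),
                                 weight_decay_range = c(1e-6, 1e-3),
                                 n_epochs_range = c(200L, 500L),
                                 batch_size_choices = c(32L, 64L, 128L, 256L),
                                 predictor_hidden_choices = c(32L, 64L,
                                                              128L, 256L),
                                 predictor_dropout_range = c(0.1, 0.6),
                                 n_trials = 20L, seed = 0L) {
  for (rg in list(lr_range, weight_decay_range, predictor_dropout_range)) {
    if (length(rg) != 2L || any(rg <= 0) || rg[1] > rg[2]) {
      stop_bk("Ranges must be positive increasing pairs.",
              "bkscore_config_error")
    }
  }
  if (n_trials < 1L) stop_bk("`n_trials` must be >= 1.",
                             "bkscore_config_error")
  structure(list(lr_range = lr_range,
                 weight_decay_range = weight_decay_range,
                 n_epochs_range = as.integer(n_epochs_range),
                 batch_size_choices = as.integer(batch_size_choices),
                 predictor_hidden_choices = as.integer(predictor_hidden_choices),
                 predictor_dropout_range = predictor_dropout_range,
                 n_trials = as.integer(n_trials), seed = as.integer(seed)),
            class = "hyperparameter_space")
}

log_uniform <- function(n, range) {
  exp(runif(n, log(range[1]), log(range[2])))
}

#' Sample trial configurations from a search space
#'
#' @param space A [hyperparameter_space()].
#' @return Tibble with one row per trial: `trial`, `learning_rate`,
#'   `weight_decay`, `n_epochs`, `batch_size`, `predictor_hidden_feats`,
#'   `predictor_dropout`.
#' @export
sample_trials <- function(space) {
  withr::with_seed(space$seed, tibble(
    trial = seq_len(space$n_trials),
    learning_rate = log_uniform(space$n_trials, space$lr_range),
    weight_decay = log_uniform(space$n_trials, space$weight_decay_range),
    n_epochs = sample(seq(space$n_epochs_range[1], space$n_epochs_range[2]),
                      space$n_trials, replace = TRUE),
    batch_size = sample(space$batch_size_choices, space$n_trials,
                        replace = TRUE),
    predictor_hidden_feats = sample(space$predictor_hidden_choices,
                                    space$n_trials, replace = TRUE),
    predictor_dropout = log_uniform(space$n_trials,
                                    space$predictor_dropout_range)))
}

#' Random-search hyperparameter tuning on validation Pearson R2
#'
#' Samples trial configurations from the bounded space, trains the graph
#' regressor for each, and selects the trial maximizing the squared Pearson
#' correlation on the validation split. Fully reproducible from the space's
#' seed; the trial table (parameters and objective) is returned for audit.
#'
#' @param ds A [labeled_dataset()].
#' @param split A [random_split()].
#' @param space A [hyperparameter_space()].
#' @param gat_config_base Architecture; trial rows override its predictor
#'   width/dropout, the trial's optimizer settings override the training
#'   defaults.
#' @param graphs Optional precomputed graphs.
#' @param verbose Report per-trial objective.
#' @return A `tune_result` list: `best_train_config`, `best_gat_config`,
#'   `best_trial`, and `trials` (tibble with `valid_pearson_r2` and
#'   `failed`).
#' @export
tune_gat <- function(ds, split, space = hyperparameter_space(),
                     gat_config_base = gat_config(), graphs = NULL,
                     verbose = FALSE) {
  trials <- sample_trials(space)
  if (is.null(graphs)) {
    graphs <- if ("graph" %in% names(ds)) ds$graph
              else featurize_smiles(ds$canonical_smiles)
  }
  obj <- rep(NA_real_, nrow(trials))
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    cfg <- gat_config_base
    cfg$predictor_hidden_feats <- tr$predictor_hidden_feats
    cfg$predictor_dropout <- tr$predictor_dropout
    tc <- train_config(learning_rate = tr$learning_rate,
                       weight_decay = tr$weight_decay,
                       n_epochs = tr$n_epochs, batch_size = tr$batch_size,
                       seed = space$seed + i)
    obj[i] <- tryCatch({
      m <- train_gat(ds, split, gat_config = cfg, train_config = tc,
                     graphs = graphs)
      ix <- split_indices(ds, split, "valid")
      pearson_r2(predict(m, graphs[ix]), ds$label[ix])
    }, error = function(e) NA_real_)
    if (verbose) {
      message(sprintf("trial %d/%d: valid R2 = %s", i, nrow(trials),
                      format(obj[i], digits = 4)))
    }
  }
  trials$valid_pearson_r2 <- obj
  trials$failed <- !is.finite(obj)
  if (all(trials$failed)) {
    stop_bk("All tuning trials failed.", "bkscore_training_failure")
  }
  best <- trials[which.max(trials$valid_pearson_r2), ]
  best_cfg <- gat_config_base
  best_cfg$predictor_hidden_feats <- best$predictor_hidden_feats
  best_cfg$predictor_dropout <- best$predictor_dropout
  structure(list(
    best_train_config = train_config(
      learning_rate = best$learning_rate, weight_decay = best$weight_decay,
      n_epochs = best$n_epochs, batch_size = best$batch_size,
      seed = space$seed + best$trial),
    best_gat_config = best_cfg, best_trial = best, trials = trials),
    class = "tune_result")
}
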