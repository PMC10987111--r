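#' Specify a fingerprint baseline regressor
#'
#' The reference models the graph regressor is compared against, all fit on
#' Morgan fingerprints of the same dataset: support vector regression (RBF),
#' gradient-boosted trees, Bayesian ridge regression, and random forest.
#'
#' @param kind One of `"support_vector_regression"`,
#'   `"gradient_boosted_trees"`, `"bayesian_ridge"`, `"random_forest"`.
#' @param hyperparameters Named list overriding the model's defaults
#'   (SVR: `cost`, `gamma`; boosted trees: `n_estimators`, `max_depth`,
#'   `learning_rate`; random forest: `n_estimators`, `max_features`).
#' @param seed Integer seed for the stochastic learners.
#' @return A `baseline_spec`.
#' @export
baseline_spec <- function(kind = c("support_vector_regression",
                                   "gradient_boosted_trees",
                                   "bayesian_ridge", "random_forest"),
                          hyperparameters = list(), seed = 0L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, hyperparameters = hyperparameters,
                 seed = as.integer(seed)),
            class = "baseline_spec")
}

# evidence-maximization Bayesian ridge regression (conjugate Gaussian prior
# on the weights, Gamma hyperpriors at their flat limit); iteratively
# re-estimates the noise precision alpha and weight precision lambda
fit_bayesian_ridge <- function(X, y, max_iter = 300L, tol = 1e-4) {
  n <- nrow(X); p <- ncol(X)
  xb <- colMeans(X); yb <- mean(y)
  Xc <- sweep(X, 2, xb)
  yc <- y - yb
  s <- svd(Xc, nu = 0)
  d2 <- s$d^2
  Vty <- crossprod(Xc, yc)
  alpha <- 1 / max(var(yc), 1e-7)
  lambda <- 1
  coef_from <- function(alpha, lambda) {
    # ridge solution in the right singular basis
    scale <- s$d^2 + lambda / alpha
    drop(s$v %*% ((crossprod(s$v, Vty)) / scale))
  }
  for (it in seq_len(max_iter)) {
    w <- coef_from(alpha, lambda)
    gamma_eff <- sum(d2 / (d2 + lambda / alpha))
    resid <- yc - drop(Xc %*% w)
    lambda_new <- (gamma_eff + 1e-6) / (sum(w^2) + 1e-6)
    alpha_new <- (n - gamma_eff + 1e-6) / (sum(resid^2) + 1e-6)
    done <- abs(log(alpha_new / alpha)) < tol &&
            abs(log(lambda_new / lambda)) < tol
    alpha <- alpha_new; lambda <- lambda_new
    if (done) break
  }
  w <- coef_from(alpha, lambda)
  list(coef = w, intercept = yb - sum(xb * w), alpha = alpha,
       lambda = lambda)
}

#' Train a fingerprint baseline model
#'
#' Labels are standardized with a transform fit on the given training labels
#' (or a supplied frozen normalizer) and predictions are de-normalized back
#' to original units, mirroring the graph model's protocol. Deterministic
#' given the spec's seed.
#'
#' @param spec A [baseline_spec()].
#' @param fingerprints Numeric matrix, one row per molecule.
#' @param labels Numeric vector aligned with `fingerprints` rows.
#' @param normalizer Optional frozen [fit_normalizer()] transform; by default
#'   one is fit on `labels`.
#' @return A `baseline_model` with a [predict()] method taking a fingerprint
#'   matrix (or a data frame with a SMILES column).
#' @export
train_baseline <- function(spec, fingerprints, labels, normalizer = NULL) {
  stopifnot(inherits(spec, "baseline_spec"))
  X <- as.matrix(fingerprints)
  if (nrow(X) != length(labels)) {
    stop_bk("`fingerprints` rows and `labels` length differ.",
            "bkscore_config_error")
  }
  nz <- normalizer %||% fit_normalizer(labels)
  yn <- normalizer_apply(nz, labels)
  hp <- spec$hyperparameters
  fit <- withr::with_seed(spec$seed, switch(
    spec$kind,
    support_vector_regression = e1071::svm(
      x = X, y = yn, type = "eps-regression", kernel = "radial",
      cost = hp$cost %||% 1,
      gamma = hp$gamma %||% (1 / ncol(X)), scale = FALSE),
    gradient_boosted_trees = xgboost::xgboost(
      x = X, y = yn,
      nrounds = hp$n_estimators %||% 300L,
      max_depth = hp$max_depth %||% 6L,
      learning_rate = hp$learning_rate %||% 0.1,
      nthreads = 1L, verbosity = 0L, seed = spec$seed),
    bayesian_ridge = fit_bayesian_ridge(X, yn),
    random_forest = randomForest::randomForest(
      x = X, y = yn,
      ntree = hp$n_estimators %||% 300L,
      mtry = if (identical(hp$max_features, "sqrt") ||
                 is.null(hp$max_features)) floor(sqrt(ncol(X)))
             else max(1L, floor(ncol(X) * hp$max_features))),
    stop_bk(sprintf("Unknown baseline kind '%s'.", spec$kind),
            "bkscore_config_error")))
  structure(list(spec = spec, fit = fit, normalizer = nz,
                 radius = attr(fingerprints, "radius") %||% 2L,
                 n_bits = ncol(X)),
            class = "baseline_model")
}

#' @export
predict.baseline_model <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata
       else morgan_matrix(newdata, radius = object$radius,
                          n_bits = object$n_bits)
  zn <- switch(object$spec$kind,
    bayesian_ridge = drop(X %*% object$fit$coef) + object$fit$intercept,
    predict(object$fit, X))
  normalizer_invert(object$normalizer, unname(zn))
}

#' Compare the GAT regressor against fingerprint baselines
#'
#' Fits every model on the identical train split, with one shared label
#' normalizer, and reports squared Pearson correlation per split — the
#' model-by-split comparison table of the evaluation protocol. A model that
#' errors is reported as a failed row rather than aborting the table.
#'
#' @param ds A [labeled_dataset()].
#' @param split A [random_split()] assignment.
#' @param gat_config,train_config Configuration for the graph model.
#' @param baseline_specs List of [baseline_spec()]s.
#' @param radius,n_bits Morgan fingerprint settings for the baselines.
#' @param graphs Optional precomputed graphs for the GAT.
#' @return A `model_comparison` tibble: one row per model with columns
#'   `model`, `train_r2`, `valid_r2`, `test_r2`, `n_train`, `n_valid`,
#'   `n_test`, `failed`.
#' @export
compare_models <- function(ds, split, gat_config = bkscore::gat_config(),
                           train_config = bkscore::train_config(),
                           baseline_specs = list(
                             baseline_spec("support_vector_regression"),
                             baseline_spec("gradient_boosted_trees"),
                             baseline_spec("bayesian_ridge"),
                             baseline_spec("random_forest")),
                           radius = 2L, n_bits = 2048L, graphs = NULL) {
  idx_train <- split_indices(ds, split, "train")
  ns <- table(split$split)
  nz <- fit_normalizer(ds$label[idx_train])

  eval_preds <- function(pred) {
    vapply(c("train", "valid", "test"), function(w) {
      ix <- split_indices(ds, split, w)
      pearson_r2(pred[ix], ds$label[ix])
    }, numeric(1))
  }

  rows <- list()
  gat_row <- tryCatch({
    m <- train_gat(ds, split, gat_config = gat_config,
                   train_config = train_config, graphs = graphs)
    g <- graphs %||% (if ("graph" %in% names(ds)) ds$graph
                      else featurize_smiles(ds$canonical_smiles))
    c(eval_preds(predict(m, g)), failed = 0)
  }, error = function(e) c(train = NA_real_, valid = NA_real_,
                           test = NA_real_, failed = 1))
  rows[["graph_attention"]] <- gat_row

  fps <- morgan_matrix(ds, smiles_col = "canonical_smiles", radius = radius,
                       n_bits = n_bits)
  for (bs in baseline_specs) {
    rows[[bs$kind]] <- tryCatch({
      m <- train_baseline(bs, fps[idx_train, , drop = FALSE],
                          ds$label[idx_train], normalizer = nz)
      c(eval_preds(predict(m, fps)), failed = 0)
    }, error = function(e) c(train = NA_real_, valid = NA_real_,
                             test = NA_real_, failed = 1))
  }

  out <- tibble(
    model = names(rows),
    train_r2 = vapply(rows, `[[`, 0, 1L),
    valid_r2 = vapply(rows, `[[`, 0, 2L),
    test_r2 = vapply(rows, `[[`, 0, 3L),
    n_train = unname(ns[["train"]]), n_valid = unname(ns[["valid"]]),
    n_test = unname(ns[["test"]]),
    failed = vapply(rows, `[[`, 0, 4L) == 1)
  structure(out, class = c("model_comparison", class(out)))
}
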