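#' Training configuration for the GAT regressor
#'
#' Defaults are the best configuration found by the reference hyperparameter
#' study for the permeability model: batch size 32, learning rate
#' 1.4547080624370068e-4, 416 epochs, weight decay 3.655402125086186e-5.
#' (The matching predictor settings — 128 hidden units, dropout 0.2086 —
#' live in [gat_config()].)
#'
#' @param learning_rate Adam learning rate.
#' @param weight_decay L2 penalty coupled into the gradient (Adam style).
#' @param n_epochs Number of passes over the training split.
#' @param batch_size Molecules per gradient step.
#' @param seed Integer seed; all training randomness (initialization, batch
#'   shuffling, dropout) derives from it.
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 1.4547080624370068e-4,
                         weight_decay = 3.655402125086186e-5,
                         n_epochs = 416L, batch_size = 32L, seed = 0L) {
  for (nm in c("learning_rate", "weight_decay")) {
    check_scalar_number(get(nm), nm)
  }
  if (learning_rate <= 0 || weight_decay < 0 || n_epochs < 1 ||
      batch_size < 1) {
    stop_bk("Training settings must be positive.", "bkscore_config_error")
  }
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 n_epochs = as.integer(n_epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

# reverse-mode gradients of the mean-squared error through the full network;
# mirrors gat_forward() step by step
gat_backward <- function(params, config, batch, cache, dyhat) {
  grads <- list()
  G <- batch$G
  Fw <- ncol(cache$H_final)

  d <- matrix(dyhat, ncol = 1L)
  grads$b2 <- matrix(sum(d), 1L, 1L)
  grads$w2 <- crossprod(cache$Rd, d)
  dR <- tcrossprod(d, params$w2)
  if (!is.null(cache$dropout_mask)) dR <- dR * cache$dropout_mask
  dA1 <- dR * (cache$A1 > 0)
  grads$W1 <- crossprod(cache$emb, dA1)
  grads$b1 <- matrix(colSums(dA1), 1L)
  demb <- tcrossprod(dA1, params$W1)

  dmean <- demb[, seq_len(Fw), drop = FALSE]
  dmax <- demb[, Fw + seq_len(Fw), drop = FALSE]
  dH <- (dmean / batch$n_nodes)[batch$graph_id, , drop = FALSE]
  idx <- cbind(as.vector(cache$amax), rep(seq_len(Fw), each = G))
  dH[idx] <- dH[idx] + as.vector(dmax)

  src <- batch$src; dst <- batch$dst
  for (l in rev(seq_len(config$n_layers))) {
    lc <- cache$layers[[l]]
    nh <- config$heads_per_layer[l]
    fl <- config$hidden_feats_per_layer[l]
    flatten <- config$head_agg_modes[l] == "flatten"
    dH_in <- matrix(0, nrow(lc$H_in), ncol(lc$H_in))
    for (h in seq_len(nh)) {
      hc <- lc$heads[[h]]
      pre <- sprintf("l%d_h%d_", l, h)
      W <- params[[paste0(pre, "W")]]
      a_d <- params[[paste0(pre, "a_dst")]]
      a_s <- params[[paste0(pre, "a_src")]]

      dout <- if (flatten) {
        dH[, (h - 1L) * fl + seq_len(fl), drop = FALSE]
      } else {
        dH / nh
      }
      dS <- dout * elu_grad(hc$S)
      dS_dst <- dS[dst, , drop = FALSE]
      Z_src <- hc$Z[src, , drop = FALSE]
      dalpha <- rowSums(dS_dst * Z_src)
      dZ <- rowsum(dS_dst * hc$alpha, src)
      csum <- drop(rowsum(hc$alpha * dalpha, dst))
      de <- hc$alpha * (dalpha - csum[dst])
      dpre <- de * leaky_relu_grad(hc$logit_pre, config$leaky_slope)
      ds_d <- drop(rowsum(dpre, dst))
      ds_s <- drop(rowsum(dpre, src))
      dZ <- dZ + outer(ds_d, drop(a_d)) + outer(ds_s, drop(a_s))
      grads[[paste0(pre, "a_dst")]] <- crossprod(hc$Z, matrix(ds_d, ncol = 1L))
      grads[[paste0(pre, "a_src")]] <- crossprod(hc$Z, matrix(ds_s, ncol = 1L))
      grads[[paste0(pre, "W")]] <- crossprod(lc$H_in, dZ)
      dH_in <- dH_in + tcrossprod(dZ, W)
    }
    dH <- dH_in
  }
  grads
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]] + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train the graph-attention regressor
#'
#' Minimizes mean-squared error on normalized labels with Adam. The label
#' normalizer is fit on the training split only and frozen into the returned
#' model; every source of randomness (weight initialization, batch shuffling,
#' dropout) derives from `train_config$seed`, so two runs with one seed are
#' identical.
#'
#' @param ds A [labeled_dataset()].
#' @param split Optional [random_split()] assignment; rows marked `"train"`
#'   are used. `NULL` trains on every record.
#' @param gat_config A [gat_config()].
#' @param train_config A [train_config()].
#' @param graphs Optional precomputed list of `molgraph`s aligned with `ds`
#'   rows (otherwise `ds$graph` is used or SMILES are featurized).
#' @param verbose Print per-epoch loss every 25 epochs.
#' @return A `gat_model`: flat parameter list, both configs, the frozen
#'   normalizer, schema version, and a `loss_history` tibble (epoch, loss).
#' @export
train_gat <- function(ds, split = NULL, gat_config = bkscore::gat_config(),
                      train_config = bkscore::train_config(),
                      graphs = NULL, verbose = FALSE) {
  schema <- feature_schema()
  if (is.null(graphs)) {
    graphs <- if ("graph" %in% names(ds)) ds$graph
              else featurize_smiles(ds$canonical_smiles, schema)
  }
  check_graphs_schema(graphs, schema$version)
  idx <- if (is.null(split)) seq_len(nrow(ds))
         else split_indices(ds, split, "train")
  if (!length(idx)) {
    stop_bk("Training split is empty.", "bkscore_empty_dataset")
  }
  y_train <- ds$label[idx]
  nz <- fit_normalizer(y_train)
  yn <- normalizer_apply(nz, y_train)
  g_train <- graphs[idx]
  n_train <- length(idx)
  d_node <- ncol(g_train[[1]]$node_features)
  p_drop <- gat_config$predictor_dropout
  bs <- train_config$batch_size

  full_batch <- if (n_train <= bs) build_batch(g_train) else NULL

  fit <- withr::with_seed(train_config$seed, {
    params <- gat_init_params(gat_config, d_node)
    state <- adam_init(params)
    losses <- numeric(train_config$n_epochs)
    for (epoch in seq_len(train_config$n_epochs)) {
      perm <- sample.int(n_train)
      starts <- seq(1L, n_train, by = bs)
      epoch_loss <- 0
      for (s in starts) {
        take <- perm[s:min(s + bs - 1L, n_train)]
        batch <- if (!is.null(full_batch) && length(take) == n_train) {
          full_batch
        } else {
          build_batch(g_train[take])
        }
        yb <- if (!is.null(full_batch) && length(take) == n_train) {
          yn
        } else {
          yn[take]
        }
        mask <- if (p_drop > 0) {
          matrix((runif(batch$G * gat_config$predictor_hidden_feats) >
                    p_drop) / (1 - p_drop),
                 batch$G, gat_config$predictor_hidden_feats)
        } else NULL
        fw <- gat_forward(params, gat_config, batch, dropout_mask = mask,
                          keep_cache = TRUE)
        resid <- fw$yhat - yb
        loss <- mean(resid^2)
        if (!is.finite(loss)) {
          stop_bk(sprintf("Training diverged (non-finite loss) at epoch %d.",
                          epoch), "bkscore_training_failure")
        }
        grads <- gat_backward(params, gat_config, batch, fw$cache,
                              2 * resid / batch$G)
        upd <- adam_step(params, grads, state, train_config$learning_rate,
                         train_config$weight_decay)
        params <- upd$params; state <- upd$state
        epoch_loss <- epoch_loss + loss * length(take)
      }
      losses[epoch] <- epoch_loss / n_train
      if (verbose && (epoch %% 25L == 0L || epoch == 1L)) {
        message(sprintf("epoch %4d  loss %.5f", epoch, losses[epoch]))
      }
    }
    list(params = params, losses = losses)
  })

  structure(list(params = fit$params, gat_config = gat_config,
                 train_config = train_config, normalizer = nz,
                 schema_version = schema$version, d_node = d_node,
                 label_kind = attr(ds, "label_kind") %||% "unknown",
                 n_train = n_train,
                 loss_history = tibble(epoch = seq_along(fit$losses),
                                       loss = fit$losses),
                 format_version = "bkscore-checkpoint-1"),
            class = "gat_model")
}
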