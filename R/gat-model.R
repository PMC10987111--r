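#' Graph-attention network configuration
#'
#' Architecture of the molecular-graph regressor: stacked multi-head
#' graph-attention layers, a permutation-invariant mean/max readout, and a
#' dense + dropout prediction head. Defaults follow the best reported
#' configuration of the approach: three attention layers with mean, mean and
#' flatten head aggregation, a 128-unit predictor and dropout 0.2086.
#'
#' Per head, a layer computes attention logits
#' `e_ij = LeakyReLU(a' [W h_i || W h_j])` over the neighbors `j` of node `i`
#' (self-loops included), normalizes them with a softmax over `j`, and emits
#' `h'_i = ELU(sum_j alpha_ij W h_j)`. Heads are combined per layer either by
#' elementwise mean or by concatenation ("flatten").
#'
#' @param n_layers Number of attention layers (default 3).
#' @param heads_per_layer Integer vector of attention heads per layer.
#' @param hidden_feats_per_layer Per-head output width of each layer.
#' @param head_agg_modes `"mean"` or `"flatten"` per layer.
#' @param predictor_hidden_feats Width of the dense prediction layer.
#' @param predictor_dropout Dropout probability in `[0, 1)` applied to the
#'   predictor hidden units during training only.
#' @param readout Graph readout; `"mean_max_concat"` concatenates the
#'   elementwise mean and max over nodes.
#' @param leaky_slope Negative slope of the LeakyReLU in the attention logits.
#' @return A `gat_config` object.
#' @export
gat_config <- function(n_layers = 3L,
                       heads_per_layer = rep(4L, n_layers),
                       hidden_feats_per_layer = rep(64L, n_layers),
                       head_agg_modes = c(rep("mean", n_layers - 1L),
                                          "flatten"),
                       predictor_hidden_feats = 128L,
                       predictor_dropout = 0.208576001608173,
                       readout = "mean_max_concat",
                       leaky_slope = 0.2) {
  n_layers <- as.integer(n_layers)
  if (n_layers < 1L) stop_bk("Need >= 1 layer.", "bkscore_config_error")
  heads_per_layer <- as.integer(rep_len(heads_per_layer, n_layers))
  hidden_feats_per_layer <- as.integer(rep_len(hidden_feats_per_layer,
                                               n_layers))
  if (length(head_agg_modes) != n_layers ||
      !all(head_agg_modes %in% c("mean", "flatten"))) {
    stop_bk("`head_agg_modes` must give 'mean' or 'flatten' for each layer.",
            "bkscore_config_error")
  }
  if (any(heads_per_layer < 1L) || any(hidden_feats_per_layer < 1L) ||
      predictor_hidden_feats < 1L) {
    stop_bk("All widths and head counts must be positive.",
            "bkscore_config_error")
  }
  if (predictor_dropout < 0 || predictor_dropout >= 1) {
    stop_bk("`predictor_dropout` must be in [0, 1).", "bkscore_config_error")
  }
  if (!identical(readout, "mean_max_concat")) {
    stop_bk("Only the 'mean_max_concat' readout is defined.",
            "bkscore_config_error")
  }
  structure(list(n_layers = n_layers, heads_per_layer = heads_per_layer,
                 hidden_feats_per_layer = hidden_feats_per_layer,
                 head_agg_modes = head_agg_modes,
                 predictor_hidden_feats = as.integer(predictor_hidden_feats),
                 predictor_dropout = predictor_dropout, readout = readout,
                 leaky_slope = leaky_slope),
            class = "gat_config")
}

# input width of each attention layer and final embedding width
gat_dims <- function(config, d_node) {
  d_in <- integer(config$n_layers)
  d <- d_node
  for (l in seq_len(config$n_layers)) {
    d_in[l] <- d
    d <- if (config$head_agg_modes[l] == "flatten") {
      config$hidden_feats_per_layer[l] * config$heads_per_layer[l]
    } else {
      config$hidden_feats_per_layer[l]
    }
  }
  list(d_in = d_in, d_out = d, d_emb = 2L * d)
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

# initialize the flat parameter list (call inside a seeded RNG context)
gat_init_params <- function(config, d_node) {
  dims <- gat_dims(config, d_node)
  params <- list()
  for (l in seq_len(config$n_layers)) {
    fl <- config$hidden_feats_per_layer[l]
    for (h in seq_len(config$heads_per_layer[l])) {
      pre <- sprintf("l%d_h%d_", l, h)
      params[[paste0(pre, "W")]] <- glorot(dims$d_in[l], fl)
      params[[paste0(pre, "a_dst")]] <- glorot(fl, 1L)
      params[[paste0(pre, "a_src")]] <- glorot(fl, 1L)
    }
  }
  params$W1 <- glorot(dims$d_emb, config$predictor_hidden_feats)
  params$b1 <- matrix(0, 1L, config$predictor_hidden_feats)
  params$w2 <- glorot(config$predictor_hidden_feats, 1L)
  params$b2 <- matrix(0, 1L, 1L)
  params
}

# stack molecular graphs into one batch with self-loops and grouping indices
build_batch <- function(graphs) {
  n_nodes <- vapply(graphs, `[[`, 0L, "n_atoms")
  offset <- cumsum(c(0L, n_nodes[-length(n_nodes)]))
  N <- sum(n_nodes)
  X <- do.call(rbind, lapply(graphs, `[[`, "node_features"))
  src <- integer(0); dst <- integer(0)
  for (g in seq_along(graphs)) {
    a <- graphs[[g]]$arcs
    if (nrow(a)) {
      src <- c(src, a[, "src"] + offset[g])
      dst <- c(dst, a[, "dst"] + offset[g])
    }
  }
  # self-loops: every node attends to itself
  src <- c(src, seq_len(N)); dst <- c(dst, seq_len(N))
  graph_id <- rep(seq_along(graphs), n_nodes)
  list(X = X, src = src, dst = dst, graph_id = graph_id,
       n_nodes = n_nodes, N = N, G = length(graphs),
       gsplit = split(seq_len(N), graph_id))
}

# permutation-invariant graph readout: concatenation of the elementwise
# mean and elementwise max over each graph's nodes (argmax rows kept for
# backprop)
readout_mean_max <- function(H, batch) {
  if (batch$N < 1L) stop_bk("Empty graph batch.", "bkscore_config_error")
  Fw <- ncol(H)
  mean_part <- rowsum(H, batch$graph_id) / batch$n_nodes
  amax <- t(vapply(batch$gsplit, function(ix) {
    ix[max.col(t(H[ix, , drop = FALSE]), ties.method = "first")]
  }, integer(Fw)))
  if (batch$G == 1L) amax <- matrix(amax, nrow = 1L)
  max_part <- matrix(H[cbind(as.vector(amax),
                             rep(seq_len(Fw), each = batch$G))],
                     batch$G, Fw)
  list(emb = cbind(mean_part, max_part), amax = amax)
}

# full forward pass; returns normalized-scale predictions plus caches needed
# for backprop and, optionally, the attention coefficients
gat_forward <- function(params, config, batch, dropout_mask = NULL,
                        keep_cache = FALSE, keep_attention = FALSE) {
  H <- batch$X
  src <- batch$src; dst <- batch$dst
  slope <- config$leaky_slope
  layers_cache <- vector("list", config$n_layers)
  attention <- if (keep_attention) vector("list", config$n_layers) else NULL

  for (l in seq_len(config$n_layers)) {
    nh <- config$heads_per_layer[l]
    heads_out <- vector("list", nh)
    heads_cache <- if (keep_cache) vector("list", nh) else NULL
    att_l <- if (keep_attention) vector("list", nh) else NULL
    for (h in seq_len(nh)) {
      pre <- sprintf("l%d_h%d_", l, h)
      W <- params[[paste0(pre, "W")]]
      a_d <- params[[paste0(pre, "a_dst")]]
      a_s <- params[[paste0(pre, "a_src")]]
      Z <- H %*% W
      s_d <- drop(Z %*% a_d); s_s <- drop(Z %*% a_s)
      logit_pre <- s_d[dst] + s_s[src]
      e <- leaky_relu(logit_pre, slope)
      # softmax over each node's neighborhood; global-max shift is exact in
      # double precision unless a group sits > ~600 logits below the overall
      # maximum, in which case fall back to exact per-group maxima
      ex <- exp(e - max(e))
      den <- as.vector(rowsum(ex, dst))
      # (NaN logits, e.g. from a diverged optimizer, propagate to the loss
      # where training reports them as a failure)
      if (!anyNA(den) && any(den == 0)) {
        gm <- group_max(e, split(seq_along(dst), dst))
        ex <- exp(e - unname(gm)[dst])
        den <- as.vector(rowsum(ex, dst))
      }
      alpha <- ex / den[dst]
      S <- rowsum(Z[src, , drop = FALSE] * alpha, dst)
      heads_out[[h]] <- elu(S)
      if (keep_cache) {
        heads_cache[[h]] <- list(Z = Z, alpha = alpha, S = S,
                                 logit_pre = logit_pre)
      }
      if (keep_attention) att_l[[h]] <- alpha
    }
    out <- if (config$head_agg_modes[l] == "flatten") {
      do.call(cbind, heads_out)
    } else {
      Reduce(`+`, heads_out) / nh
    }
    if (keep_cache) layers_cache[[l]] <- list(H_in = H, heads = heads_cache)
    if (keep_attention) attention[[l]] <- att_l
    H <- out
  }

  ro <- readout_mean_max(H, batch)
  emb <- ro$emb
  amax <- ro$amax

  A1 <- sweep(emb %*% params$W1, 2, params$b1, `+`)
  R <- relu(A1)
  Rd <- if (is.null(dropout_mask)) R else R * dropout_mask
  yhat <- unname(drop(Rd %*% params$w2)) + drop(params$b2)

  res <- list(yhat = yhat)
  if (keep_cache) {
    res$cache <- list(layers = layers_cache, H_final = H, emb = emb,
                      amax = amax, A1 = A1, R = R, Rd = Rd,
                      dropout_mask = dropout_mask)
  }
  if (keep_attention) res$attention <- attention
  res
}

check_graphs_schema <- function(graphs, version) {
  vers <- vapply(graphs, `[[`, "", "schema_version")
  if (!all(vers == version)) {
    stop_bk(sprintf(
      "Graphs were featurized under schema '%s' but the model expects '%s'.",
      paste(unique(vers), collapse = ","), version),
      "bkscore_incompatible")
  }
}

as_graph_list <- function(newdata, schema_version) {
  if (inherits(newdata, "molgraph")) return(list(newdata))
  if (is.character(newdata)) {
    return(featurize_smiles(newdata, feature_schema(schema_version)))
  }
  if (is.data.frame(newdata)) {
    if ("graph" %in% names(newdata)) return(newdata$graph)
    if ("canonical_smiles" %in% names(newdata)) {
      return(featurize_smiles(newdata$canonical_smiles,
                              feature_schema(schema_version)))
    }
    if ("smiles" %in% names(newdata)) {
      return(featurize_smiles(newdata$smiles,
                              feature_schema(schema_version)))
    }
    stop_bk("No SMILES or graph column found in `newdata`.",
            "bkscore_schema_error")
  }
  if (is.list(newdata)) return(newdata)
  stop_bk("Unsupported `newdata` type.", "bkscore_schema_error")
}

#' Predict labels with a trained GAT model
#'
#' Runs the attention network with dropout inactive and de-normalizes the
#' output through the normalization transform frozen at training time, so
#' predictions are in the label's original units.
#'
#' @param object A `gat_model` from [train_gat()].
#' @param newdata SMILES character vector, data frame with a `smiles`/
#'   `canonical_smiles`/`graph` column, a `molgraph`, or a list of graphs.
#' @param batch_size Graphs per forward pass.
#' @param ... Unused.
#' @return Numeric vector of predictions in original label units.
#' @export
predict.gat_model <- function(object, newdata, batch_size = 256L, ...) {
  graphs <- as_graph_list(newdata, object$schema_version)
  if (!length(graphs)) return(numeric(0))
  check_graphs_schema(graphs, object$schema_version)
  chunks <- split(seq_along(graphs),
                  ceiling(seq_along(graphs) / batch_size))
  out <- unlist(lapply(chunks, function(ix) {
    batch <- build_batch(graphs[ix])
    gat_forward(object$params, object$gat_config, batch)$yhat
  }), use.names = FALSE)
  normalizer_invert(object$normalizer, out)
}

#' Attention coefficients of a model on one molecule
#'
#' Returns a tidy table of the softmax-normalized attention weights of every
#' layer and head, one row per directed arc (self-loops included). For each
#' attending atom the weights over its neighborhood sum to one.
#'
#' @param model A `gat_model`.
#' @param graph A `molgraph` (or a single SMILES string).
#' @return Tibble with columns `layer`, `head`, `src`, `dst`, `alpha`.
#' @export
gat_attention <- function(model, graph) {
  if (is.character(graph)) {
    graph <- smiles_to_graph(graph, feature_schema(model$schema_version))
  }
  batch <- build_batch(list(graph))
  res <- gat_forward(model$params, model$gat_config, batch,
                     keep_attention = TRUE)
  purrr::map_dfr(seq_along(res$attention), function(l) {
    purrr::map_dfr(seq_along(res$attention[[l]]), function(h) {
      tibble(layer = l, head = h, src = batch$src, dst = batch$dst,
             alpha = res$attention[[l]][[h]])
    })
  })
}

#' @export
print.gat_model <- function(x, ...) {
  d <- gat_dims(x$gat_config, x$d_node)
  cat("<gat_model> ", x$gat_config$n_layers, " attention layers (",
      paste(x$gat_config$head_agg_modes, collapse = "/"), "), ",
      "embedding ", d$d_emb, ", schema ", x$schema_version, "\n", sep = "")
  cat("  trained ", nrow(x$loss_history), " epochs on n = ", x$n_train,
      "; final loss ", signif(utils::tail(x$loss_history$loss, 1), 4),
      " (normalized MSE)\n", sep = "")
  invisible(x)
}
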