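# shared fixtures, built in code and cached for the session

.bk_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .bk_cache)) {
    assign(key, force(expr), envir = .bk_cache)
  }
  get(key, envir = .bk_cache)
}

# the default synthetic study task (n = 2000, ceiling ~0.9); generated once
default_synth_ds <- function() {
  cached("default_ds", suppressMessages(generate_dataset(synthetic_spec())))
}

# a small labeled dataset with precomputed graphs for fast training tests
small_synth_ds <- function(n = 60, seed = 7) {
  cached(sprintf("small_ds_%d_%d", n, seed),
         suppressMessages(generate_dataset(
           synthetic_spec(n_molecules = n, seed = seed))))
}

tiny_gat_config <- function(hidden = 8L, predictor = 16L, dropout = 0) {
  gat_config(heads_per_layer = c(2L, 2L, 2L),
             hidden_feats_per_layer = rep(hidden, 3L),
             predictor_hidden_feats = predictor,
             predictor_dropout = dropout)
}

# an initialized (untrained) model around seeded weights, for tests that
# exercise the forward pass without paying for training
stub_gat_model <- function(seed = 1, config = tiny_gat_config(),
                           d_node = 30L) {
  params <- withr::with_seed(seed, bkscore:::gat_init_params(config, d_node))
  structure(list(params = params, gat_config = config,
                 train_config = train_config(n_epochs = 1L, seed = seed),
                 normalizer = structure(list(mean = 0, sd = 1),
                                        class = "normalizer"),
                 schema_version = feature_schema()$version, d_node = d_node,
                 label_kind = "synthetic", n_train = 0L,
                 loss_history = tibble::tibble(epoch = integer(0),
                                               loss = numeric(0)),
                 format_version = "bkscore-checkpoint-1"),
            class = "gat_model")
}

# reorder the atoms of a molecular graph by a permutation
permute_graph <- function(g, perm) {
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  g$node_features <- g$node_features[perm, , drop = FALSE]
  g$arcs <- cbind(src = inv[g$arcs[, "src"]], dst = inv[g$arcs[, "dst"]])
  g
}

# a bag of valid, structurally varied test molecules
test_molecules <- function() {
  c("CCO", "C", "c1ccccc1", "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
    "CC(=O)Nc1ccc(O)cc1", "N[C@@H](C)C(=O)O", "C#N", "CC(C)(C)C",
    "C1CCOCC1", "c1ccncc1", "OC(=O)c1ccccc1O", "CCS", "FC(F)F",
    "C1CC1", "O=C=O", "CCCCCCCC", "c1ccc2ccccc2c1", "CC(=O)OCC",
    "C1CCNCC1", "CN(C)C")
}

expect_bk_error <- function(expr, class) {
  expect_error(expr, class = class)
}
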