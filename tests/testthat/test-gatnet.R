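# the attention layers, readout, prediction and checkpointing

test_that("attention weights are probability vectors over neighborhoods", {
  model <- stub_gat_model(seed = 2)
  for (smi in c("CCO", "c1ccccc1", "CC(C)CC(=O)O")) {
    att <- gat_attention(model, smi)
    sums <- dplyr::summarise(dplyr::group_by(att, layer, head, dst),
                             s = sum(alpha), .groups = "drop")
    expect_true(all(abs(sums$s - 1) < 1e-6))
    expect_true(all(att$alpha >= 0))
  }
})

test_that("zero attention vectors give uniform attention on a 2-node path", {
  cfg <- gat_config(n_layers = 1L, heads_per_layer = 1L,
                    hidden_feats_per_layer = 4L, head_agg_modes = "mean",
                    predictor_hidden_feats = 4L, predictor_dropout = 0)
  model <- stub_gat_model(seed = 1, config = cfg)
  model$params$l1_h1_a_dst[] <- 0
  model$params$l1_h1_a_src[] <- 0
  att <- gat_attention(model, smiles_to_graph("CC"))
  expect_equal(att$alpha, rep(0.5, 4), tolerance = 1e-12)
})

test_that("a hand-checked 3-node path matches the closed-form equations", {
  cfg <- gat_config(n_layers = 1L, heads_per_layer = 1L,
                    hidden_feats_per_layer = 2L, head_agg_modes = "mean",
                    predictor_hidden_feats = 2L, predictor_dropout = 0)
  g <- list(node_features = matrix(c(1, 0, 0, 0, 1, 0), 3, 2, byrow = TRUE),
            arcs = cbind(src = c(1L, 2L, 2L, 3L), dst = c(2L, 1L, 3L, 2L)),
            n_atoms = 3L, canonical_smiles = "synthetic-path",
            schema_version = feature_schema()$version)
  params <- withr::with_seed(5, bkscore:::gat_init_params(cfg, 2L))
  batch <- bkscore:::build_batch(list(g))
  fw <- bkscore:::gat_forward(params, cfg, batch)
  expect_equal(fw$yhat, naive_gat_forward(params, cfg, list(g)),
               tolerance = 1e-6)
})

test_that("the mean||max readout matches hand arithmetic", {
  H <- matrix(c(0, 1, 2, 3), 2, 2, byrow = TRUE)
  batch <- list(N = 2L, G = 1L, graph_id = c(1L, 1L), n_nodes = 2L,
                gsplit = list(`1` = 1:2))
  ro <- bkscore:::readout_mean_max(H, batch)
  expect_equal(drop(ro$emb), c(1, 2, 2, 3))

  # single node: embedding is the node repeated
  h1 <- matrix(c(4, -1), 1, 2)
  b1 <- list(N = 1L, G = 1L, graph_id = 1L, n_nodes = 1L,
             gsplit = list(`1` = 1L))
  expect_equal(drop(bkscore:::readout_mean_max(h1, b1)$emb), c(4, -1, 4, -1))
})

test_that("predictions are deterministic, batchable and permutation-invariant", {
  model <- stub_gat_model(seed = 3)
  graphs <- featurize_molecules(
    tibble::tibble(smiles = test_molecules()))$graph

  p1 <- predict(model, graphs)
  p2 <- predict(model, graphs)
  expect_identical(p1, p2)

  # batch of one equals the batched value
  expect_equal(predict(model, graphs[1]), p1[1], tolerance = 1e-12)

  # permuting atom order leaves the prediction unchanged
  for (g in graphs[c(3, 4, 5)]) {
    perm <- withr::with_seed(g$n_atoms, sample(g$n_atoms))
    expect_equal(predict(model, list(permute_graph(g, perm))),
                 predict(model, list(g)), tolerance = 1e-5)
  }

  # permuted-atom SMILES spelling of the same molecule scores identically
  expect_equal(predict(model, "Cn1cnc2c1c(=O)n(C)c(=O)n2C"),
               predict(model, "O=c1n(C)c(=O)n(C)c2ncn(C)c12"),
               tolerance = 1e-6)
})

test_that("backpropagation matches finite differences", {
  cfg <- tiny_gat_config(hidden = 5L, predictor = 7L)
  graphs <- featurize_molecules(
    tibble::tibble(smiles = c("CCO", "c1ccccc1", "CC(=O)N", "C#N")))$graph
  params <- withr::with_seed(11, bkscore:::gat_init_params(cfg, 30L))
  batch <- bkscore:::build_batch(graphs)
  y <- withr::with_seed(12, rnorm(4))
  lossfun <- function(p) {
    mean((bkscore:::gat_forward(p, cfg, batch)$yhat - y)^2)
  }
  fw <- bkscore:::gat_forward(params, cfg, batch, keep_cache = TRUE)
  gr <- bkscore:::gat_backward(params, cfg, batch, fw$cache,
                               2 * (fw$yhat - y) / batch$G)
  for (nm in c("l1_h1_W", "l2_h2_a_dst", "l3_h1_a_src", "W1", "w2")) {
    k <- withr::with_seed(13, sample(length(params[[nm]]), 4))
    for (i in k) {
      eps <- 1e-6
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (lossfun(pp) - lossfun(pm)) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("schema tags guard prediction compatibility", {
  model <- stub_gat_model()
  g <- smiles_to_graph("CCO")
  g$schema_version <- "bk-atom-v999"
  expect_bk_error(predict(model, list(g)), "bkscore_incompatible")
})

test_that("checkpoints round-trip bit-identically and fail loudly", {
  ds <- small_synth_ds()
  cfg <- tiny_gat_config()
  m <- train_gat(ds, gat_config = cfg,
                 train_config = train_config(learning_rate = 1e-3,
                                             n_epochs = 3L, seed = 5))
  probe <- ds$graph[1:10]
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(predict(m, probe), predict(m2, probe))

  # wrong schema tag
  m_bad <- m; m_bad$schema_version <- "bk-atom-v999"
  path2 <- withr::local_tempfile(fileext = ".rds")
  saveRDS(m_bad, path2)
  expect_bk_error(load_model(path2), "bkscore_incompatible")

  # corrupted file is a parse error, not silent garbage
  path3 <- withr::local_tempfile(fileext = ".rds")
  writeLines("this is not a checkpoint", path3)
  expect_bk_error(load_model(path3), "bkscore_io_error")
  expect_bk_error(load_model("no/such/file.rds"), "bkscore_io_error")
})
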