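# SMILES parsing, graph featurization and circular fingerprints

test_that("small molecules produce the expected graph shapes", {
  g <- smiles_to_graph("CCO")
  expect_equal(g$n_atoms, 3L)
  expect_equal(nrow(g$arcs), 4L)  # 2 bonds, each as two directed arcs
  expect_equal(ncol(g$node_features), feature_schema()$d_node)

  g1 <- smiles_to_graph("C")
  expect_equal(g1$n_atoms, 1L)
  expect_equal(nrow(g1$arcs), 0L)
})

test_that("featurization is invariant to the SMILES spelling", {
  # randomized re-spellings generated with an independent toolkit (RDKit)
  mols <- test_molecules()
  script <- paste(
    "import sys",
    "from rdkit import Chem",
    "for s in sys.stdin.read().split():",
    "    m = Chem.MolFromSmiles(s)",
    "    for _ in range(10):",
    "        print(Chem.MolToSmiles(m, doRandom=True), end=';')",
    "    print()",
    sep = "\n")
  res <- suppressWarnings(system2("python", c("-c", shQuote(script)),
                                  input = paste(mols, collapse = "\n"),
                                  stdout = TRUE, stderr = FALSE))
  expect_length(res, length(mols))
  for (i in seq_along(mols)) {
    ref <- smiles_to_graph(mols[i])
    spellings <- setdiff(strsplit(res[i], ";", fixed = TRUE)[[1]], "")
    for (sp in unique(spellings)) {
      g <- smiles_to_graph(sp)
      expect_identical(g$node_features, ref$node_features)
      expect_identical(g$arcs, ref$arcs)
    }
  }
})

test_that("arc sets are symmetric and widths fixed across a batch", {
  graphs <- featurize_molecules(
    tibble::tibble(smiles = test_molecules()))$graph
  widths <- vapply(graphs, function(g) ncol(g$node_features), 0L)
  expect_true(all(widths == widths[1]))
  for (g in graphs) {
    if (!nrow(g$arcs)) next
    fwd <- paste(g$arcs[, "src"], g$arcs[, "dst"])
    rev <- paste(g$arcs[, "dst"], g$arcs[, "src"])
    expect_setequal(fwd, rev)
  }
})

test_that("invalid SMILES raise errors that carry the offending string", {
  err <- tryCatch(smiles_to_graph("notasmiles((("),
                  bkscore_invalid_molecule = identity)
  expect_s3_class(err, "bkscore_invalid_molecule")
  expect_match(conditionMessage(err), "notasmiles", fixed = TRUE)
  expect_bk_error(canonicalize_smiles(""), "bkscore_invalid_molecule")
})

test_that("salts are reduced to their largest fragment with a warning", {
  expect_warning(out <- canonicalize_smiles("CC(=O)[O-].[Na+]"),
                 "fragments")
  expect_identical(out, canonicalize_smiles("CC(=O)[O-]",
                                            keep_largest_fragment = FALSE))
})

test_that("charged and chiral atoms are encoded in the node features", {
  schema <- feature_schema()
  charge_col <- 18L  # element(11) + degree(6) + 1
  g <- smiles_to_graph("C[N+](C)(C)C", schema)
  expect_equal(sum(g$node_features[, charge_col]), 1)
  g2 <- smiles_to_graph("N[C@@H](C)C(=O)O", schema)
  expect_equal(sum(g2$node_features[, schema$d_node]), 1)
})

test_that("morgan fingerprints behave like a circular fingerprint", {
  # methane has only its radius-0 environment
  fp <- morgan_fingerprint("C", radius = 2, n_bits = 2048)
  expect_equal(sum(fp$bits), 1L)
  expect_length(fp$bits, 2048L)

  # canonical invariance and determinism
  expect_identical(morgan_fingerprint("OCC")$bits,
                   morgan_fingerprint("CCO")$bits)
  expect_identical(morgan_fingerprint("CCO")$bits,
                   morgan_fingerprint("CCO")$bits)

  # distinct molecules differ
  expect_false(identical(morgan_fingerprint("CCO")$bits,
                         morgan_fingerprint("CCN")$bits))

  # folding: a wider fingerprint has at least as many distinct on-bits
  m_small <- morgan_matrix("Cn1cnc2c1c(=O)n(C)c(=O)n2C", n_bits = 64L)
  m_large <- morgan_matrix("Cn1cnc2c1c(=O)n(C)c(=O)n2C", n_bits = 4096L)
  expect_lte(sum(m_small), sum(m_large))
  # and every identifier lands inside the requested width
  expect_equal(ncol(m_small), 64L)
})

test_that("radius-0 fingerprints count distinct atom types", {
  # ethanol has three distinct atom environments at radius 0 (CH3, CH2, OH)
  m <- morgan_matrix("CCO", radius = 0L, n_bits = 2048L)
  expect_equal(sum(m), 3L)
  # benzene's six aromatic CH atoms share one environment
  m2 <- morgan_matrix("c1ccccc1", radius = 0L, n_bits = 2048L)
  expect_equal(sum(m2), 1L)
})
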