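# the B-K scoring, calibration, thresholding and panel validation layer

# oracle stub scorers built from the synthetic ground-truth functions
b_stub <- function() {
  spec <- synthetic_spec()
  function(smiles) ground_truth_label(spec, smiles)
}
k_stub <- function() {
  spec <- synthetic_spec(label_function = "ring_hetero_mix",
                         coefficients = c(1, 0.3, 0.1, 0.4))
  function(smiles) ground_truth_label(spec, smiles)
}

test_that("the permeability cut-off converts exactly to the B-score scale", {
  expect_identical(logpapp_cms_to_nms(-5.5), 1.5)
  expect_identical(scoring_config()$b_threshold, 1.5)
})

test_that("the reference payload calibrates to exactly (0, 0)", {
  ref <- "CCc1ccc2c(c1)cccn2"
  cand <- suppressMessages(generate_dataset(
    synthetic_spec(10, generator = "scaffold_series")))$canonical_smiles
  sc <- score_candidates(b_stub(), k_stub(), cand,
                         scoring_config(reference_smiles = ref))
  ref_row <- sc[sc$canonical_smiles == canonicalize_smiles(ref), ]
  expect_equal(nrow(ref_row), 1L)
  expect_identical(ref_row$delta_b, 0)
  expect_identical(ref_row$delta_k, 0)
})

test_that("calibration is a pure shift between candidates", {
  cand <- suppressMessages(generate_dataset(
    synthetic_spec(8, generator = "scaffold_series")))$canonical_smiles
  sc1 <- score_candidates(b_stub(), k_stub(), cand,
                          scoring_config(reference_smiles = cand[1]))
  sc2 <- score_candidates(b_stub(), k_stub(), cand,
                          scoring_config(reference_smiles = cand[5]))
  expect_equal(diff(sc1$delta_b), diff(sc2$delta_b), tolerance = 1e-12)
  expect_equal(diff(sc1$delta_k), diff(sc2$delta_k), tolerance = 1e-12)
})

test_that("the bystander flag is inclusive at the threshold and monotone", {
  # scorer pinned to exact values via a lookup stub
  cand <- c("CCO", "CCN", "CCS")
  can <- canonicalize_smiles(cand)
  vals <- c(1.5, 1.49999, 2.0)
  lookup <- function(smiles) vals[match(smiles, can)]
  sc <- score_candidates(lookup, function(s) rep(0, length(s)), cand,
                         scoring_config(reference_smiles = "CCO"))
  expect_identical(sc$bystander_flag, c(TRUE, FALSE, TRUE))
  expect_true(all(diff(sc$bystander_flag[order(sc$b_score)]) >= 0))
})

test_that("invalid candidates are reported, never dropped silently", {
  expect_warning(
    sc <- score_candidates(b_stub(), k_stub(),
                           c("CCO", "not-a-smiles-at-all!!", "CCN"),
                           scoring_config(reference_smiles = "CCO")),
    "unparseable")
  expect_equal(nrow(sc), 2L)
  expect_equal(nrow(attr(sc, "rejects")), 1L)

  expect_bk_error(
    score_candidates(b_stub(), k_stub(), "CCO",
                     scoring_config(reference_smiles = "zzz$$$")),
    "bkscore_config_error")
})

test_that("ranking is descending with deterministic SMILES tie-breaks", {
  cand <- c("CCCO", "CCN", "CCCS")
  can <- canonicalize_smiles(cand)
  vals <- setNames(c(2.0, 1.0, 3.0), can)
  sc <- score_candidates(function(s) unname(vals[s]),
                         function(s) rep(0, length(s)),
                         cand, scoring_config(reference_smiles = "CCCO"))
  rk <- rank_candidates(sc, key = "b_score")
  expect_equal(rk$b_score, c(3.0, 2.0, 1.0))

  # exact ties resolve lexicographically by canonical SMILES
  tied <- score_candidates(function(s) rep(1, length(s)),
                           function(s) rep(0, length(s)),
                           cand, scoring_config(reference_smiles = "CCCO"))
  rk2 <- rank_candidates(tied, key = "b_score")
  expect_equal(rk2$canonical_smiles, sort(can))

  one <- rank_candidates(sc[1, ], key = "bk_score")
  expect_equal(nrow(one), 1L)
})

test_that("bk ranking recovers the ground-truth ordering with oracle stubs", {
  bs <- b_stub(); ks <- k_stub()
  for (seed in 1:10) {
    cand <- suppressMessages(generate_dataset(
      synthetic_spec(12, seed = seed, noise_sd = 0)))$canonical_smiles
    sc <- score_candidates(bs, ks, cand,
                           scoring_config(reference_smiles = cand[1]))
    truth <- bs(sc$canonical_smiles) + ks(sc$canonical_smiles)
    rk <- rank_candidates(sc, key = "bk_score")
    ranked_truth <- truth[match(rk$canonical_smiles, sc$canonical_smiles)]
    # top candidate attains the ground-truth optimum (ties allowed), and
    # the whole ranking is non-increasing in ground truth
    expect_equal(ranked_truth[1], max(truth))
    expect_true(all(diff(ranked_truth) <= 1e-9))
  }
})

test_that("panel validation counts the confusion matrix correctly", {
  # 10 payloads with fixed predicted scores: 6 TP, 1 FN, 2 TN, 1 FP
  smis <- c("CCO", "CCN", "CCS", "CCC", "CCCC", "CCCO",
            "CCCN", "CCCS", "CCCCC", "CCCCO")
  can <- canonicalize_smiles(smis)
  b_vals <- setNames(c(2, 2, 2, 2, 2, 2, 1, 1, 1, 2), can)
  labels <- c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  v <- validate_panel(function(s) unname(b_vals[s]),
                      tibble::tibble(smiles = smis, bystander_label = labels))
  expect_equal(unname(v$counts), c(6L, 1L, 2L, 1L))
  expect_equal(v$metrics$accuracy, 0.8)
  expect_equal(v$metrics$sensitivity, 6 / 7)
  expect_equal(v$metrics$specificity, 2 / 3)

  perfect <- validate_panel(function(s) ifelse(unname(b_vals[s]) > 1.5, 2, 1),
                            tibble::tibble(smiles = smis,
                                           bystander_label = b_vals[can] > 1.5))
  expect_equal(perfect$metrics$accuracy, 1.0)

  expect_bk_error(
    validate_panel(function(s) 1,
                   tibble::tibble(smiles = "zzz$$$", bystander_label = TRUE)),
    "bkscore_empty_dataset")
})

test_that("the heat-map table is tidy and tracks rank correlation", {
  cand <- suppressMessages(generate_dataset(
    synthetic_spec(3, generator = "scaffold_series")))$canonical_smiles
  sc <- score_candidates(b_stub(), k_stub(), cand,
                         scoring_config(reference_smiles = cand[1]))
  tab <- score_heatmap_table(sc)
  expect_equal(nrow(tab), 9L)  # 3 candidates x 3 metrics

  tab2 <- score_heatmap_table(sc, measured_pic50 = sc$bk_score)
  expect_equal(nrow(tab2), 12L)
  expect_equal(attr(tab2, "rank_correlation"), 1.0)

  # a monotone potency readout with mild noise keeps high rank correlation
  cand20 <- suppressMessages(generate_dataset(
    synthetic_spec(20, seed = 21)))$canonical_smiles
  sc20 <- score_candidates(b_stub(), k_stub(), cand20,
                           scoring_config(reference_smiles = cand20[1]))
  pic50 <- 2 * sc20$bk_score + withr::with_seed(1,
    rnorm(nrow(sc20), 0, 0.05 * sd(sc20$bk_score)))
  tab3 <- score_heatmap_table(sc20, measured_pic50 = pic50)
  expect_gt(attr(tab3, "rank_correlation"), 0.9)
})

test_that("gat models plug into the scoring layer", {
  ds <- small_synth_ds()
  m <- train_gat(ds, gat_config = tiny_gat_config(),
                 train_config = train_config(learning_rate = 1e-3,
                                             n_epochs = 3L, seed = 2))
  sc <- score_candidates(m, m, ds$canonical_smiles[1:5],
                         scoring_config(reference_smiles =
                                          ds$canonical_smiles[1]))
  expect_equal(nrow(sc), 5L)
  expect_equal(sc$delta_b[1], 0)
  expect_s3_class(autoplot(sc), "ggplot")
})
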