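# training loop, evaluation metric and hyperparameter search

test_that("pearson_r2 matches the closed-form correlation", {
  obs <- c(1, 2, 3, 4)
  expect_equal(pearson_r2(obs, obs), 1.0)
  expect_equal(pearson_r2(-obs, obs), 1.0)  # sign-blind by definition

  pred <- c(1.1, 1.9, 3.2, 3.8)
  # independent hand computation of the Pearson formula
  manual <- (sum((pred - mean(pred)) * (obs - mean(obs))) /
               sqrt(sum((pred - mean(pred))^2) * sum((obs - mean(obs))^2)))^2
  expect_equal(pearson_r2(pred, obs), manual, tolerance = 1e-10)

  expect_warning(z <- pearson_r2(rep(1, 4), obs), "Zero variance")
  expect_equal(z, 0)
  expect_bk_error(pearson_r2(1:3, 1:4), "bkscore_config_error")
})

test_that("training is deterministic given the seed", {
  ds <- small_synth_ds()
  tc <- train_config(learning_rate = 1e-3, n_epochs = 4L, batch_size = 16L,
                     seed = 9)
  m1 <- train_gat(ds, gat_config = tiny_gat_config(dropout = 0.2),
                  train_config = tc)
  m2 <- train_gat(ds, gat_config = tiny_gat_config(dropout = 0.2),
                  train_config = tc)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(m1$params, m2$params)
})

test_that("training fails explicitly on an empty split or divergence", {
  ds <- small_synth_ds()
  sp <- random_split(ds, seed = 1)
  sp$split[] <- "test"
  expect_bk_error(train_gat(ds, sp), "bkscore_empty_dataset")

  err <- tryCatch(
    train_gat(ds, gat_config = tiny_gat_config(),
              train_config = train_config(learning_rate = 1e100,
                                          n_epochs = 10L, seed = 1)),
    bkscore_training_failure = identity)
  expect_s3_class(err, "bkscore_training_failure")
  expect_match(conditionMessage(err), "epoch")
})

test_that("a wide model memorizes a tiny training set", {
  ds <- small_synth_ds(n = 32, seed = 3)
  m <- train_gat(ds,
                 gat_config = gat_config(hidden_feats_per_layer = c(32, 32, 32),
                                         predictor_dropout = 0),
                 train_config = train_config(learning_rate = 3e-3,
                                             weight_decay = 0,
                                             n_epochs = 220L, seed = 1))
  expect_lt(utils::tail(m$loss_history$loss, 1), 0.05)
})

test_that("evaluate_model reports per-split metrics with residuals", {
  ds <- small_synth_ds()
  sp <- random_split(ds, seed = 2)
  m <- train_gat(ds, sp, gat_config = tiny_gat_config(),
                 train_config = train_config(learning_rate = 1e-3,
                                             n_epochs = 5L, seed = 2))
  ev <- evaluate_model(m, ds, sp)
  expect_setequal(as.character(ev$split), c("train", "valid", "test"))
  expect_equal(sum(ev$n), nrow(ds))
  expect_true(all(ev$pearson_r2 >= 0 & ev$pearson_r2 <= 1))
  resid <- attr(ev, "residuals")
  expect_equal(nrow(resid), nrow(ds))
  expect_equal(resid$predicted - resid$observed, resid$residual)
})

test_that("trial sampling is reproducible and respects every bound", {
  space <- hyperparameter_space(n_trials = 100L, seed = 4)
  t1 <- sample_trials(space)
  t2 <- sample_trials(space)
  expect_identical(t1, t2)
  expect_true(all(t1$learning_rate >= 1e-5 & t1$learning_rate <= 1e-2))
  expect_true(all(t1$weight_decay >= 1e-6 & t1$weight_decay <= 1e-3))
  expect_true(all(t1$n_epochs >= 200L & t1$n_epochs <= 500L))
  expect_true(all(t1$batch_size %in% c(32L, 64L, 128L, 256L)))
  expect_true(all(t1$predictor_hidden_feats %in% c(32L, 64L, 128L, 256L)))
  expect_true(all(t1$predictor_dropout >= 0.1 & t1$predictor_dropout <= 0.6))
})

test_that("random search selects the best validation trial reproducibly", {
  ds <- small_synth_ds()
  sp <- random_split(ds, seed = 5)
  space <- hyperparameter_space(n_epochs_range = c(4L, 8L),
                                batch_size_choices = 16L,
                                predictor_hidden_choices = c(8L, 16L),
                                n_trials = 4L, seed = 6)
  res <- tune_gat(ds, sp, space, gat_config_base = tiny_gat_config())
  expect_equal(nrow(res$trials), 4L)
  expect_equal(res$best_trial$valid_pearson_r2,
               max(res$trials$valid_pearson_r2, na.rm = TRUE))
  expect_s3_class(res$best_train_config, "train_config")
  # re-running reproduces the trial table exactly
  res2 <- tune_gat(ds, sp, space, gat_config_base = tiny_gat_config())
  expect_identical(res$trials, res2$trials)
  # tiny learning rates cannot fit the task within a few epochs, so the
  # winner must not come from the bottom of the sampled range
  expect_gt(res$best_trial$learning_rate,
            min(res$trials$learning_rate))
})

test_that("test labels are never read during training or tuning", {
  ds <- small_synth_ds()
  sp <- random_split(ds, seed = 7)
  ds$label[sp$split == "test"] <- NaN  # any read would poison the fit
  m <- train_gat(ds, sp, gat_config = tiny_gat_config(),
                 train_config = train_config(learning_rate = 1e-3,
                                             n_epochs = 3L, seed = 1))
  expect_true(all(is.finite(m$loss_history$loss)))
  space <- hyperparameter_space(n_epochs_range = c(2L, 3L),
                                batch_size_choices = 32L,
                                predictor_hidden_choices = 8L,
                                n_trials = 2L, seed = 1)
  res <- tune_gat(ds, sp, space, gat_config_base = tiny_gat_config())
  expect_true(all(is.finite(res$trials$valid_pearson_r2)))
})

test_that("tidy and glance summarize fitted models", {
  ds <- small_synth_ds()
  m <- train_gat(ds, gat_config = tiny_gat_config(),
                 train_config = train_config(learning_rate = 1e-3,
                                             n_epochs = 3L, seed = 1))
  expect_identical(tidy(m), m$loss_history)
  g <- glance(m)
  expect_equal(g$n_epochs, 3L)
  expect_equal(g$n_train, nrow(ds))
  expect_equal(g$head_agg, "mean/mean/flatten")
})
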