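test_that("stratified k-fold partitions evenly without overlap", {
  set.seed(41)
  y <- rep_len(0:1, 1200)
  folds <- kfold_split(y, 10, seed = 3)
  expect_equal(as.vector(table(folds)), rep(120L, 10)) # 1200 / 10
  expect_equal(sort(unique(folds)), 1:10)
  # stratification: each fold holds 60 of each class
  for (k in 1:10) expect_equal(as.vector(table(y[folds == k])), c(60L, 60L))
  expect_identical(folds, kfold_split(y, 10, seed = 3))
  expect_false(identical(folds, kfold_split(y, 10, seed = 4)))
  expect_error(kfold_split(0:1, 10, seed = 1), class = "eegcaps_argument_error")
})

test_that("confusion metrics reproduce hand arithmetic", {
  # hand-built 2x2 confusion [[40,10],[5,45]]
  truth <- c(rep(0, 50), rep(1, 50))
  pred <- c(rep(0, 40), rep(1, 10), rep(0, 5), rep(1, 45))
  m <- confusion_metrics(truth, pred, 2)
  expect_equal(unname(m$confusion), matrix(c(40, 5, 10, 45), 2))
  expect_equal(m$accuracy, 85)
  expect_equal(m$per_class$recall, c(80, 90))
  expect_equal(m$per_class$precision, 100 * c(40 / 45, 45 / 55))
  expect_equal(m$precision, mean(100 * c(40 / 45, 45 / 55)))
  expect_equal(m$f1, 100 * mean(c(2 * (40 / 45) * 0.8 / (40 / 45 + 0.8),
                                  2 * (45 / 55) * 0.9 / (45 / 55 + 0.9))))
  # perfect predictions
  mp <- confusion_metrics(truth, truth, 2)
  expect_equal(c(mp$accuracy, mp$f1, mp$recall, mp$precision),
               c(100, 100, 100, 100))
  expect_true(all(mp$confusion[upper.tri(mp$confusion) |
                                 lower.tri(mp$confusion)] == 0))
  # constant predictor on balanced binary data
  mc <- confusion_metrics(truth, rep(0, 100), 2)
  expect_equal(mc$accuracy, 50)
  expect_equal(mc$per_class$recall, c(100, 0))
})

test_that("an untrained binary model sits at the chance plateau", {
  samples <- normalize_maps(tiny_samples())
  Xf <- eegcaps:::samples_to_matrix(samples)
  y <- eegcaps:::sample_classes(samples)
  cfg <- model_config_small()
  lg <- eegcaps:::model_loss_grad(model_init(cfg, seed = 11), Xf, y, cfg,
                                  training = FALSE)
  expect_equal(lg$loss, log(2), tolerance = 0.02)
})

test_that("training reduces loss on separable synthetic data", {
  samples <- tiny_samples() # effect_size = 2: strongly separable
  cfg <- model_config_small()
  ck <- train_fold(samples, cfg, train_config(batch_size = 20, max_epochs = 8,
                                              seed = 4))
  expect_true(all(is.finite(ck$loss_curve)))
  expect_lt(ck$loss_curve[8], ck$loss_curve[1])
  ev <- evaluate_model(ck, samples)
  expect_gt(ev$accuracy, 60)
  expect_equal(sum(ev$confusion), length(samples))
  expect_equal(ev$accuracy, 100 * sum(diag(ev$confusion)) / sum(ev$confusion))
})

test_that("evaluation refuses an empty test set", {
  samples <- tiny_samples()
  cfg <- model_config_small()
  ck <- train_fold(samples[1:8], cfg, train_config(batch_size = 8, max_epochs = 1,
                                                   seed = 1))
  expect_error(evaluate_model(ck, list()), class = "eegcaps_argument_error")
})

test_that("cross-validation aggregates fold metrics and is reproducible", {
  samples <- tiny_samples()[1:20]
  cfg <- tiny_model_cfg(T = 4)
  tc <- train_config(batch_size = 10, max_epochs = 2, n_folds = 2, seed = 6)
  rep1 <- run_cv(samples, cfg, tc)
  expect_s3_class(rep1, "eval_report")
  expect_equal(nrow(rep1$per_fold), 2)
  expect_equal(sum(rep1$per_fold$n_test), 20)
  expect_equal(unname(rep1$mean["accuracy"]), mean(rep1$per_fold$accuracy))
  expect_equal(sum(rep1$confusion), 20)
  # identical master seed -> byte-identical serialised report
  rep2 <- run_cv(samples, cfg, tc)
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  write_eval_report(rep1, f1)
  write_eval_report(rep2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("scrambled labels drive held-out accuracy to chance", {
  samples <- tiny_samples()
  scr <- eegcaps:::local_seed(99, {
    y <- sample(eegcaps:::sample_classes(samples))
    for (i in seq_along(samples)) samples[[i]]$label$class <- y[i]
    samples
  })
  cfg <- tiny_model_cfg(T = 4)
  ck <- train_fold(scr[1:28], cfg, train_config(batch_size = 14, max_epochs = 4,
                                                seed = 8))
  ev <- evaluate_model(ck, scr[29:40])
  expect_lt(ev$accuracy, 90) # no signal to generalise from
})
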