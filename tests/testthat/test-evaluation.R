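test_that("stratified folds balance sizes and classes at n = 83", {
  labels <- c(rep("MI", 41), rep("MCI", 42))
  folds <- stratified_folds(labels, k = 5, seed = 3)
  sizes <- as.integer(table(folds))
  expect_equal(sort(sizes), c(16, 16, 17, 17, 17))
  per_class <- table(labels, folds)
  expect_true(all(apply(per_class, 1, function(x) diff(range(x)) <= 1)))
  expect_error(stratified_folds(c("MI", "MCI"), k = 5), "smaller than")
})

test_that("pooled CV tests every record exactly once and reaches high accuracy on separable data", {
  df <- make_signal_features(n_per_class = 50, delta = 6, seed = 21)
  cfg <- model_config(proms_mask = rep(FALSE, 7), seed = 22)
  res <- kfold_cv(df, df$label, cfg)
  expect_equal(res$cm$tp + res$cm$fn + res$cm$fp + res$cm$tn, 100)
  expect_equal(nrow(res$predictions), 100)
  expect_gte(res$metrics$accuracy, 90)
  expect_error(kfold_cv(df, rep("MI", 100), cfg), "both classes")
})

test_that("shuffled labels give chance-level pooled accuracy", {
  df <- make_signal_features(n_per_class = 50, delta = 6, seed = 23)
  cfg <- model_config(proms_mask = rep(FALSE, 7), epochs = 100)
  set.seed(24)
  accs <- vapply(1:5, function(r) {
    cfg$seed <- 30 + r
    shuffled <- sample(df$label)
    kfold_cv(df, shuffled, cfg)$metrics$accuracy
  }, numeric(1))
  # binomial null at n = 100: 50% +/- 2 sigma = +/- 10, with slack for the
  # small replicate count
  expect_lt(abs(mean(accs) - 50), 12)
})

test_that("baselines exercise the domain masks", {
  df <- make_signal_features(n_per_class = 30, delta = 6,
                             signal_features = c("range", "min_angle"),
                             seed = 25)
  cfg <- model_config(seed = 26)
  angle_res <- baseline_eval(df, df$label, "angle", cfg)
  proms_res <- baseline_eval(df, df$label, "proms", cfg)
  both_res <- baseline_eval(df, df$label, "both", cfg)
  expect_gte(angle_res$metrics$accuracy, 90)
  # PROMs carry no signal in this construction
  expect_lt(proms_res$metrics$accuracy, angle_res$metrics$accuracy)
  expect_equal(both_res$cm$tp + both_res$cm$fn + both_res$cm$fp +
                 both_res$cm$tn, 60)
})

test_that("subset search enumerates every PROMs subset and finds the signal", {
  df <- make_signal_features(n_per_class = 15, delta = 6,
                             signal_features = "sbt", seed = 27)
  cfg <- model_config(seed = 28, epochs = 40)
  ranking <- subset_search(df, df$label, "proms", cfg)
  expect_equal(nrow(ranking), 128)
  expect_equal(length(unique(ranking$mask)), 128)
  expect_equal(sum(ranking$n_features == 0), 1)
  expect_equal(sort(ranking$rank), 1:128)
  best <- ranking[ranking$rank == 1, ]
  expect_match(best$features, "sbt")
  all_mask <- ranking[ranking$n_features == 7, ]
  expect_gte(best$f1, all_mask$f1)
  # the empty subset is recorded as a majority-class predictor, not trained
  empty <- ranking[ranking$n_features == 0, ]
  expect_equal(empty$tp + empty$fn + empty$fp + empty$tn, 30)
  expect_gt(empty$rank, 1)
})

test_that("subset ranking is invariant to evaluation order via per-mask seeds", {
  df <- make_signal_features(n_per_class = 10, delta = 4,
                             signal_features = "sbt", seed = 29)
  cfg <- model_config(seed = 30, epochs = 25)
  r1 <- subset_search(df, df$label, "proms", cfg)
  r2 <- subset_search(df, df$label, "proms", cfg)
  expect_identical(r1$f1, r2$f1)
  expect_identical(r1$mask, r2$mask)
})

test_that("ablation isolates the signal-carrying feature", {
  df <- make_signal_features(n_per_class = 30, delta = 6,
                             signal_features = "range", seed = 31)
  cfg <- model_config(seed = 32, epochs = 150)
  mask <- c(angle_feature_names(), proms_feature_names()) %in%
    c("range", "variance", "std_dev")
  tab <- ablation(df, df$label, mask, cfg)
  expect_equal(nrow(tab), 3)
  delta_signal <- tab$delta_accuracy[tab$feature == "range"]
  delta_noise <- tab$delta_accuracy[tab$feature != "range"]
  expect_gte(delta_signal, 20)
  expect_true(all(abs(delta_noise) <= 10))
  expect_error(ablation(df, df$label, c("range"), cfg), "at least 2")
  expect_error(ablation(df, df$label, c("range", "bogus"), cfg), "unknown")
})

test_that("evaluation report carries baselines and significance blocks", {
  df <- make_signal_features(n_per_class = 15, delta = 6, seed = 33)
  cfg <- model_config(seed = 34, epochs = 50)
  report <- evaluation_report(df, df$label, cfg, k = 5, alpha = 0.001)
  expect_named(report$baselines, c("both", "angle", "proms"))
  expect_equal(report$n, 30)
  expect_equal(report$significance$per_fold$n, 6)
  expect_equal(report$significance$pooled$n, 30)
  expect_true(report$significance$pooled$threshold > 50)
})
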