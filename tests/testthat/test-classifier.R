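# builds a one-feature angle-stream model with hand-set parameters so the
# forward pass can be checked against pencil-and-paper arithmetic
identity_model <- function() {
  cfg <- model_config(angle_mask = c(TRUE, rep(FALSE, 8)),
                      proms_mask = rep(FALSE, 7), seed = 1)
  model <- init_classifier(cfg)
  st <- model$streams$angle
  st$run_mean <- 0
  st$run_var <- 1 - cfg$bn_eps    # makes the normalisation exactly identity
  st$gamma <- 1; st$beta <- 0
  st$W <- matrix(1, 1, 1)
  model$streams$angle <- st
  model$final$w <- matrix(1, 1, 1)
  model$final$b <- 0
  model
}

test_that("zeroed weights yield probability one half", {
  model <- identity_model()
  model$streams$angle$W <- matrix(0, 1, 1)
  model$final$w <- matrix(0, 1, 1)
  out <- model_forward(model, c(variance = 3.7))
  expect_equal(out$probability, 0.5)
})

test_that("forward pass matches a hand-computed sigmoid", {
  model <- identity_model()
  out <- model_forward(model, c(variance = 2))
  expect_equal(out$probability, plogis(2), tolerance = 1e-9)
  expect_equal(out$label, "MI")
  # negative post-normalisation input is zeroed by the ReLU
  out_neg <- model_forward(model, c(variance = -2))
  expect_equal(out_neg$probability, 0.5)
})

test_that("training separates well-separated clusters", {
  df <- make_signal_features(n_per_class = 40, delta = 6,
                             signal_features = "range", seed = 2)
  cfg <- model_config(angle_mask = angle_feature_names() == "range",
                      proms_mask = rep(FALSE, 7), seed = 5)
  model <- train_classifier(df, df$label, cfg)
  pred <- predict(model, df)
  expect_gte(mean(pred$label == df$label), 0.95)
})

test_that("training is deterministic under a fixed seed", {
  df <- make_signal_features(n_per_class = 15, seed = 3)
  cfg <- model_config(seed = 42, epochs = 50)
  m1 <- train_classifier(df, df$label, cfg)
  m2 <- train_classifier(df, df$label, cfg)
  expect_identical(m1$streams, m2$streams)
  expect_identical(m1$final, m2$final)
  expect_identical(m1$loss_history, m2$loss_history)
})

test_that("degenerate training sets are rejected", {
  df <- make_signal_features(n_per_class = 10, seed = 4)
  expect_error(train_classifier(df, rep("MI", nrow(df)), model_config()),
               "single class")
  expect_error(train_classifier(df[1:3, ], c("MI", "MI", "MCI"),
                                model_config()), "2 examples per class")
})

test_that("BCE loss is essentially non-increasing on separable data", {
  df <- make_signal_features(n_per_class = 40, delta = 6,
                             signal_features = "range", seed = 6)
  cfg <- model_config(angle_mask = angle_feature_names() == "range",
                      proms_mask = rep(FALSE, 7), seed = 7)
  model <- train_classifier(df, df$label, cfg)
  upticks <- diff(model$loss_history) > 1e-12
  expect_lte(mean(upticks), 0.05)
  expect_lt(tail(model$loss_history, 1), model$loss_history[1])
})

test_that("prediction contracts: untrained, empty, and extra features", {
  cfg <- model_config(seed = 1, epochs = 20)
  expect_error(predict(init_classifier(cfg),
                       make_signal_features(5, seed = 8)), "not been trained")
  df <- make_signal_features(n_per_class = 10, seed = 9)
  model <- train_classifier(df, df$label, cfg)
  empty <- predict(model, df[0, ])
  expect_equal(nrow(empty), 0)
  # a masked-out / unused column is ignored
  cfg1 <- model_config(angle_mask = angle_feature_names() == "range",
                       proms_mask = rep(FALSE, 7), seed = 2, epochs = 20)
  m1 <- train_classifier(df, df$label, cfg1)
  df2 <- df
  df2$vas <- df2$vas + 1000
  expect_equal(predict(m1, df2), predict(m1, df))
})

test_that("feature rescaling is absorbed by batch normalisation", {
  df <- make_signal_features(n_per_class = 25, delta = 3, seed = 10)
  cfg <- model_config(proms_mask = rep(FALSE, 7), seed = 11, epochs = 150)
  base <- kfold_cv(df, df$label, cfg)
  df_scaled <- df
  df_scaled$range <- df_scaled$range * 10
  scaled <- kfold_cv(df_scaled, df_scaled$label, cfg)
  expect_equal(scaled$metrics$accuracy, base$metrics$accuracy)
})

test_that("a PROMs-only stream drops the angle stream entirely", {
  df <- make_signal_features(n_per_class = 12, delta = 4,
                             signal_features = "sbt", seed = 12)
  cfg <- model_config(angle_mask = rep(FALSE, 9),
                      proms_mask = proms_feature_names() == "sbt",
                      seed = 13, epochs = 200)
  model <- train_classifier(df, df$label, cfg)
  expect_named(model$streams, "proms")
  expect_gte(mean(predict(model, df)$label == df$label), 0.9)
})

test_that("model JSON round-trips exactly", {
  df <- make_signal_features(n_per_class = 10, seed = 14)
  cfg <- model_config(seed = 15, epochs = 30)
  model <- train_classifier(df, df$label, cfg)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  save_model(model, path)
  restored <- load_model(path)
  expect_equal(restored$streams, model$streams, tolerance = 1e-12)
  expect_equal(restored$final$w, model$final$w)
  expect_equal(predict(restored, df), predict(model, df))
})

test_that("config validation rejects empty masks and bad hyperparameters", {
  expect_error(model_config(angle_mask = rep(FALSE, 9),
                            proms_mask = rep(FALSE, 7)), "at least one")
  expect_error(model_config(learning_rate = 0), "learning_rate")
  expect_error(model_config(epochs = 0), "epochs")
})
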