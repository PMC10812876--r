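# The four supervised architectures: training, prediction contracts,
# cross-validation plumbing and serialisation.

test_that("all four architectures separate the easy panel almost perfectly", {
  test <- separable_test()
  for (arch in c("nn", "xgb", "rf", "svm")) {
    fit <- toy_classifier(arch)
    acc <- confusion_accuracy(predict(fit, test), test$class)$accuracy
    expect_gte(acc, 0.99)
  }
})

test_that("class probabilities are proper and predictions deterministic", {
  fit <- toy_classifier("rf")
  test <- separable_test()
  prob <- predict(fit, test, type = "prob")
  expect_equal(unname(rowSums(prob)), rep(1, nrow(prob)), tolerance = 1e-9)
  expect_true(all(prob >= 0 & prob <= 1))
  expect_identical(predict(fit, test, type = "prob"), prob)
  lab <- predict(fit, test)
  expect_identical(as.character(lab),
                   c("redundant", "unique")[max.col(prob)])
})

test_that("dimension mismatches and task mix-ups raise classified errors", {
  fit <- toy_classifier("rf")
  expect_error(predict(fit, matrix(0, 2, 9)), class = "oudel_invalid_input")
  expect_error(predict(fit, separable_test(), type = "params"),
               class = "oudel_invalid_input")
  reg <- toy_regressor("rf")
  expect_error(predict(reg, separable_test(), type = "class"),
               class = "oudel_invalid_input")
  expect_error(train_deletion_classifier(separable_train()[0, ], "rf"),
               class = "oudel_invalid_input")
})

test_that("single-class training degenerates to a constant predictor", {
  train <- dplyr::filter(separable_train(), class == "redundant")
  expect_warning(fit <- train_deletion_classifier(train, "rf", seed = 1),
                 "single class")
  expect_true(all(predict(fit, separable_test()) == "redundant"))
})

test_that("cross-validation selects reproducibly and records the grid", {
  grid <- tibble::tibble(log10_cost = c(-1, 1), kernel_gamma = c(0.5, 0.5))
  f1 <- train_deletion_classifier(separable_train(), "svm", grid = grid,
                                  seed = 9)
  f2 <- train_deletion_classifier(separable_train(), "svm", grid = grid,
                                  seed = 9)
  expect_identical(f1$hyperparameters, f2$hyperparameters)
  expect_identical(f1$cv$cv_loss, f2$cv$cv_loss)
  expect_equal(nrow(f1$cv), 2L)
  expect_false(any(is.na(f1$cv$cv_loss)))
})

test_that("training on a pre-standardised copy gives identical predictions", {
  # standardisation statistics come from the training data only, so an
  # already-standardised copy must induce the same fitted model
  train <- separable_train()
  X <- oudel:::feature_matrix(train)
  ctr <- colMeans(X); scl <- apply(X, 2, sd)
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  train_std <- train
  train_std[colnames(X)] <- as.data.frame(Xs)
  f_raw <- train_deletion_classifier(train, "svm", grid = grid1("svm"), seed = 3)
  f_std <- train_deletion_classifier(train_std, "svm", grid = grid1("svm"), seed = 3)
  test <- separable_test()
  Xt <- oudel:::feature_matrix(test)
  Xt_std <- sweep(sweep(Xt, 2, ctr), 2, scl, "/")
  expect_equal(predict(f_raw, Xt, type = "prob"),
               predict(f_std, Xt_std, type = "prob"), tolerance = 1e-6)
})

test_that("regressors return the 3m-target layout and recover easy optima", {
  test <- separable_test()
  for (arch in c("nn", "rf")) {
    reg <- toy_regressor(arch)
    pred <- predict(reg, test, type = "params")
    expect_equal(dim(pred), c(nrow(test), 6L))
    expect_identical(colnames(pred), oudel:::target_names(2))
    expect_true(all(is.finite(pred)))
    # strong selection, tiny drift: the observed e_D is essentially theta1,
    # so predicted theta1 should track it closely
    err <- abs(pred[, "theta1_1"] - test$theta1_1)
    expect_lt(median(err), 0.2)
  }
})

test_that("serialised predictors reproduce predictions bit-identically", {
  test <- separable_test()
  for (arch in c("nn", "xgb", "rf", "svm")) {
    fit <- toy_classifier(arch)
    path <- withr::local_tempfile(fileext = ".rds")
    save_predictor(fit, path)
    back <- load_predictor(path)
    expect_identical(predict(back, test, type = "prob"),
                     predict(fit, test, type = "prob"))
  }
  expect_error(suppressWarnings(
    load_predictor(withr::local_tempfile(fileext = ".rds"))))
})

test_that("grids have the documented shapes and tie-break ordering", {
  full_nn <- default_grid("nn")
  expect_equal(nrow(full_nn), 6 * 11 * 25)
  red_nn <- default_grid("nn", reduced = TRUE)
  expect_equal(sort(unique(red_nn$n_hidden_layers)), c(0L, 2L, 5L))
  expect_equal(sort(unique(red_nn$log10_lambda)), c(-12, -7.5, -3))
  # negligible penalties collapse the gamma axis to a single point
  expect_equal(sort(unique(red_nn$gamma[red_nn$log10_lambda == -3])),
               c(0, 0.5, 1))
  expect_true(all(red_nn$gamma[red_nn$log10_lambda < -6] == 0))
  expect_equal(nrow(red_nn), 15L)
  # simpler models first within the grid ordering
  expect_true(!is.unsorted(full_nn$n_hidden_layers))
  full_xgb <- default_grid("xgb")
  expect_equal(nrow(full_xgb), 6 * 11 * 25 * 4)
  expect_equal(nrow(default_grid("svm")), 7 * 11)
  expect_equal(default_grid("rf")$num_trees, 500)
})

test_that("broom-style accessors summarise fitted predictors", {
  fit <- toy_classifier("rf")
  td <- tidy(fit)
  expect_true(all(c("term", "estimate") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$architecture, "rf")
  expect_equal(gl$task, "classification")
})
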