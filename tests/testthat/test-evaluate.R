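# ROC curves, operating points, confusion matrices, error distributions and
# the experiment drivers.

test_that("ROC curves are monotone staircases anchored at the corners", {
  withr::with_seed(14, {
    for (i in 1:20) {
      n <- 200
      labels <- sample(c("redundant", "unique"), n, replace = TRUE)
      scores <- round(runif(n), 2)  # rounding forces ties
      curve <- roc_curve(scores, labels)
      expect_equal(curve$fpr[1], 0)
      expect_equal(curve$tpr[1], 0)
      expect_equal(curve$fpr[nrow(curve)], 1)
      expect_equal(curve$tpr[nrow(curve)], 1)
      expect_true(!is.unsorted(curve$fpr))
      expect_true(!is.unsorted(curve$tpr))
    }
  })
})

test_that("AUC matches an independent ROC implementation on tied scores", {
  withr::with_seed(15, {
    for (i in 1:10) {
      labels <- sample(c("redundant", "unique"), 300, replace = TRUE)
      scores <- round(rnorm(300) + (labels == "unique"), 1)
      ours <- roc_auc(roc_curve(scores, labels))
      theirs <- suppressMessages(as.numeric(pROC::auc(
        pROC::roc(labels, scores, levels = c("redundant", "unique"),
                  direction = "<"))))
      expect_equal(ours, theirs, tolerance = 1e-9)
    }
  })
})

test_that("perfect, null and reversed scores give the expected AUC", {
  labels <- rep(c("redundant", "unique"), each = 50)
  perfect <- c(runif(50, 0, 0.4), runif(50, 0.6, 1))
  expect_equal(roc_auc(roc_curve(perfect, labels)), 1)
  expect_equal(roc_auc(roc_curve(-perfect, labels)),
               1 - roc_auc(roc_curve(perfect, labels)))
  withr::with_seed(16, {
    null_scores <- runif(10000)
    null_labels <- sample(c("redundant", "unique"), 10000, replace = TRUE)
    expect_lt(abs(roc_auc(roc_curve(null_scores, null_labels)) - 0.5), 0.02)
  })
  expect_error(roc_curve(1:5, rep("unique", 5)),
               class = "oudel_invalid_input")
})

test_that("power at bounded FPR uses the conservative step convention", {
  labels <- rep(c("redundant", "unique"), each = 50)
  perfect <- c(runif(50, 0, 0.4), runif(50, 0.6, 1))
  curve <- roc_curve(perfect, labels)
  expect_equal(power_at_fpr(curve, 0.05), 1)
  expect_equal(power_at_fpr(curve, 1), 1)
  # hand-built staircase: scores .9(u) .8(r) .7(u) .6(r):
  # at fpr 0 the achievable tpr is 0.5; no interpolation beyond it
  curve2 <- roc_curve(c(0.9, 0.8, 0.7, 0.6),
                      c("unique", "redundant", "unique", "redundant"))
  expect_equal(power_at_fpr(curve2, 0.25), 0.5)
  expect_equal(power_at_fpr(curve2, 0.49), 0.5)
  expect_equal(power_at_fpr(curve2, 0.5), 1)
  withr::with_seed(17, {
    null_scores <- runif(20000)
    null_labels <- sample(c("redundant", "unique"), 20000, replace = TRUE)
    p <- power_at_fpr(roc_curve(null_scores, null_labels), 0.05)
    expect_lt(abs(p - 0.05), 0.02)
  })
})

test_that("confusion matrices and accuracy agree with direct arithmetic", {
  all_u <- rep("unique", 4)
  expect_equal(confusion_accuracy(all_u, all_u)$accuracy, 1)
  flipped <- confusion_accuracy(rep("redundant", 4), all_u)
  expect_equal(flipped$accuracy, 0)
  # counts 90/10 and 20/80 give accuracy (90+80)/200
  truth <- rep(c("redundant", "unique"), each = 100)
  pred <- c(rep("redundant", 90), rep("unique", 10),
            rep("redundant", 20), rep("unique", 80))
  cm <- confusion_accuracy(pred, truth)
  expect_equal(cm$accuracy, 0.85)
  expect_equal(unname(rowSums(cm$rates)), c(1, 1))
  expect_equal(cm$accuracy, sum(diag(cm$counts)) / sum(cm$counts))
  expect_error(confusion_accuracy(all_u, all_u[1:2]),
               class = "oudel_invalid_input")
})

test_that("error distributions are signed, grouped and shift-equivariant", {
  sim <- simulate_deletion_data(sim_config(n_events = 30, m = 2), seed = 19)
  truth <- oudel:::target_matrix(sim$data)
  zero <- error_distributions(truth, sim)
  expect_true(all(zero$error == 0))
  expect_equal(nrow(zero), 30 * 6)
  expect_equal(sum(zero$output == "theta1"), 30 * 2)
  shifted <- error_distributions(truth + 0.3, sim)
  expect_equal(shifted$error, rep(0.3, nrow(shifted)))
  expect_true(all(c("redundant", "unique") %in% zero$class))
  expect_error(error_distributions(truth[, 1:3], sim),
               class = "oudel_invalid_input")
})

test_that("region performance tables cover the grid reproducibly", {
  regions <- default_regions()[c(1, 9), ]
  cls <- toy_classifier("rf")
  cfg <- sim_config(n_events = 60, m = 2)
  t1 <- region_performance(cls, regions = regions, n_events = 60,
                           config = cfg, seed = 23)
  t2 <- region_performance(cls, regions = regions, n_events = 60,
                           config = cfg, seed = 23)
  expect_equal(nrow(t1), 2L)
  expect_identical(t1, t2)
  expect_true(all(c("power", "accuracy") %in% names(t1)))
  expect_error(region_performance(cls, regions = default_regions()[0, ]),
               class = "oudel_invalid_input")
})

test_that("the noise experiment reports per-architecture power by noise sd", {
  models <- list(rf = toy_classifier("rf"))
  tab <- noise_experiment(models, sds = c(0.001, 1),
                          config = sim_config(n_events = 80, m = 2),
                          n_events = 80, seed = 27)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$architecture, c("rf", "rf"))
  expect_true(all(tab$power >= 0 & tab$power <= 1))
})
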