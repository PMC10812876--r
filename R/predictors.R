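# Supervised predictors for deletion-event classification (redundant vs
# unique) and 3m-output parameter regression: feed-forward neural network
# (in-package), gradient-boosted trees (xgboost), random forest (ranger) and
# radial-basis SVM (e1071).  Hyperparameters are selected by 5-fold
# cross-validation over the architecture's grid; the winner is refit on the
# full training data.

CLASS_LEVELS <- c("redundant", "unique")

# hyperparameter grids --------------------------------------------------------

# endpoints-plus-midpoint shrink used by `reduced = TRUE`
reduce_axis <- function(v) unique(v[c(1L, ceiling(length(v) / 2), length(v))])

#' Default hyperparameter grid of an architecture
#'
#' Full grids: NN - hidden layers L in 0..5, 11 mixing values gamma on
#' \[0, 1\], 25 penalty scales log10(lambda) on \[-12, -3\]; XGB - depth D in
#' 1..6, the same gamma and lambda axes, 4 learning rates on \[0.01, 0.3\];
#' SVM - 7 log10(C) on \[-3, 3\] and 11 kernel widths on \[0.001, 5\]; RF -
#' none (500 trees).  With `reduced = TRUE` every axis shrinks to its
#' endpoints plus midpoint, a desk-scale mode for exploratory runs.
#'
#' @param architecture One of `"nn"`, `"xgb"`, `"rf"`, `"svm"`.
#' @param reduced Use the endpoints-plus-midpoint grid?
#' @return A tibble with one row per hyperparameter combination.
#' @export
default_grid <- function(architecture = c("nn", "xgb", "rf", "svm"),
                         reduced = FALSE) {
  architecture <- match.arg(architecture)
  shrink <- if (reduced) reduce_axis else identity
  g <- switch(architecture,
    nn = expand.grid(
      n_hidden_layers = shrink(0:5),
      gamma = shrink(seq(0, 1, length.out = 11)),
      log10_lambda = shrink(seq(-12, -3, length.out = 25))),
    xgb = expand.grid(
      max_depth = shrink(1:6),
      gamma = shrink(seq(0, 1, length.out = 11)),
      log10_lambda = shrink(seq(-12, -3, length.out = 25)),
      eta = shrink(seq(0.01, 0.3, length.out = 4))),
    svm = expand.grid(
      log10_cost = shrink(seq(-3, 3, length.out = 7)),
      kernel_gamma = shrink(seq(0.001, 5, length.out = 11))),
    rf = expand.grid(num_trees = 500))
  # in reduced mode, combinations whose penalty is numerically negligible
  # (lambda <= 1e-6) are identical regardless of the mixing gamma; keep one
  if (reduced && "log10_lambda" %in% names(g)) {
    g <- g[g$log10_lambda > -6 | g$gamma == 0, , drop = FALSE]
  }
  # simpler models first so ties in CV loss resolve toward them: small
  # L/D first, then larger penalty
  if (architecture == "nn") {
    g <- g[order(g$n_hidden_layers, -g$log10_lambda, g$gamma), ]
  } else if (architecture == "xgb") {
    g <- g[order(g$max_depth, -g$log10_lambda, g$gamma, g$eta), ]
  }
  as_tibble(g)
}

# architecture backends -------------------------------------------------------

# Each backend takes standardised-or-raw features as decided here, one
# hyperparameter row `hp`, and returns a fit usable by arch_predict().
# `val` (optional row indices) supplies an early-stopping watch set for xgb.

arch_uses_standardised <- function(architecture) {
  architecture %in% c("nn", "svm")
}

arch_fit <- function(architecture, X, y, hp, task, ctrl, watch = NULL) {
  switch(architecture,
    nn = {
      Y <- if (task == "classification") {
        cbind(redundant = as.numeric(y == "redundant"),
              unique = as.numeric(y == "unique"))
      } else {
        y
      }
      nn_train(X, Y, n_hidden_layers = hp$n_hidden_layers,
               lambda = 10^hp$log10_lambda, gamma = hp$gamma,
               hidden_width = ctrl$hidden_width,
               max_epochs = ctrl$max_epochs, patience = ctrl$patience,
               batch_size = ctrl$batch_size, lr = ctrl$learning_rate,
               task = task)
    },
    xgb = {
      lam <- 10^hp$log10_lambda
      params <- list(
        max_depth = hp$max_depth, eta = hp$eta,
        lambda = lam * (1 - hp$gamma), alpha = lam * hp$gamma,
        nthread = 1, tree_method = "hist",
        objective = if (task == "classification") "binary:logistic"
                    else "reg:squarederror",
        eval_metric = if (task == "classification") "logloss" else "rmse")
      fit_one <- function(lab, wlab) {
        # booster handles are occasionally invalidated by the garbage
        # collector mid-training; retry once after an explicit gc
        for (attempt in 1:3) {
          fit <- tryCatch({
            dtr <- xgboost::xgb.DMatrix(X, label = lab)
            if (!is.null(watch)) {
              dva <- xgboost::xgb.DMatrix(watch$X, label = wlab)
              xgboost::xgb.train(params, dtr, nrounds = ctrl$rounds,
                                 evals = list(val = dva),
                                 early_stopping_rounds = ctrl$early_stop,
                                 verbose = 0)
            } else {
              xgboost::xgb.train(params, dtr, nrounds = ctrl$rounds,
                                 verbose = 0)
            }
          }, error = function(e) if (attempt == 3) rlang::abort(conditionMessage(e)) else NULL)
          if (!is.null(fit)) return(fit)
          gc()
        }
      }
      if (task == "classification") {
        fit_one(as.numeric(y == "unique"),
                if (!is.null(watch)) as.numeric(watch$y == "unique"))
      } else {
        lapply(seq_len(ncol(y)), function(j) {
          fit_one(y[, j], if (!is.null(watch)) watch$y[, j])
        })
      }
    },
    rf = {
      if (task == "classification") {
        ranger::ranger(x = X, y = factor(y, CLASS_LEVELS),
                       num.trees = hp$num_trees, probability = TRUE,
                       num.threads = 1, seed = ctrl$seed %||% 1L)
      } else {
        lapply(seq_len(ncol(y)), function(j) {
          ranger::ranger(x = X, y = y[, j], num.trees = hp$num_trees,
                         num.threads = 1,
                         seed = (ctrl$seed %||% 1L) + j)
        })
      }
    },
    svm = {
      if (task == "classification") {
        fit <- e1071::svm(X, factor(y, CLASS_LEVELS), type = "C-classification",
                          kernel = "radial", cost = 10^hp$log10_cost,
                          gamma = hp$kernel_gamma, scale = FALSE)
        dvm <- attr(predict(fit, X, decision.values = TRUE),
                    "decision.values")
        # orient the decision value so larger means "unique"
        sgn <- if (startsWith(colnames(dvm)[1], "unique/")) 1 else -1
        cal <- suppressWarnings(
          stats::glm.fit(cbind(1, sgn * as.numeric(dvm)),
                         as.numeric(y == "unique"),
                         family = stats::binomial()))
        list(svm = fit, sign = sgn, calibration = cal$coefficients)
      } else {
        lapply(seq_len(ncol(y)), function(j) {
          e1071::svm(X, y[, j], type = "eps-regression", kernel = "radial",
                     cost = 10^hp$log10_cost, gamma = hp$kernel_gamma,
                     scale = FALSE)
        })
      }
    })
}

arch_predict <- function(architecture, fit, X, task) {
  if (task == "classification") {
    p_unique <- switch(architecture,
      nn = nn_output(fit$net, X, "classification")[, 2L],
      xgb = predict(fit, xgboost::xgb.DMatrix(X)),
      rf = {
        pr <- predict(fit, data = as.data.frame(X), num.threads = 1)$predictions
        if ("unique" %in% colnames(pr)) pr[, "unique"] else pr[, 2L]
      },
      svm = {
        dv <- as.numeric(attr(predict(fit$svm, X, decision.values = TRUE),
                              "decision.values")) * fit$sign
        stats::plogis(fit$calibration[1] + fit$calibration[2] * dv)
      })
    cbind(redundant = 1 - p_unique, unique = p_unique)
  } else {
    switch(architecture,
      nn = nn_output(fit$net, X, "regression"),
      xgb = vapply(fit, function(f) predict(f, xgboost::xgb.DMatrix(X)),
                   numeric(nrow(X))),
      rf = vapply(fit, function(f) {
        predict(f, data = as.data.frame(X), num.threads = 1)$predictions
      }, numeric(nrow(X))),
      svm = vapply(fit, function(f) as.numeric(predict(f, X)),
                   numeric(nrow(X))))
  }
}

# losses ----------------------------------------------------------------------

cross_entropy <- function(prob_unique, y) {
  p <- pmin(pmax(ifelse(y == "unique", prob_unique, 1 - prob_unique),
                 1e-12), 1)
  -mean(log(p))
}

# cross-validated loss of every grid row; returns the grid with a cv_loss col
cv_grid <- function(architecture, X, y, grid, folds, task, ctrl, verbose) {
  n <- nrow(X)
  fold_id <- sample(rep_len(seq_len(folds), n))
  losses <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    hp <- grid[g, , drop = FALSE]
    fold_loss <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      Xtr <- X[tr, , drop = FALSE]
      Xte <- X[!tr, , drop = FALSE]
      ytr <- if (is.matrix(y)) y[tr, , drop = FALSE] else y[tr]
      yte <- if (is.matrix(y)) y[!tr, , drop = FALSE] else y[!tr]
      watch <- if (architecture == "xgb") list(X = Xte, y = yte) else NULL
      fit <- arch_fit(architecture, Xtr, ytr, hp, task, ctrl, watch)
      pred <- arch_predict(architecture, fit, Xte, task)
      fold_loss[f] <- if (task == "classification") {
        cross_entropy(pred[, "unique"], yte)
      } else {
        mean((pred - yte)^2)
      }
    }
    losses[g] <- mean(fold_loss)
    if (verbose) {
      message(sprintf("  grid %d/%d: cv loss %.5f", g, nrow(grid), losses[g]))
    }
  }
  grid$cv_loss <- losses
  grid
}

# shared trainer --------------------------------------------------------------

resolve_training_frame <- function(data) {
  df <- if (inherits(data, "oudel_sim")) data$data else as_tibble(data)
  X <- feature_matrix(df)
  if (any(!is.finite(X))) stop_invalid("Features contain non-finite values.")
  if (nrow(X) == 0L) stop_invalid("Training data is empty.")
  list(df = df, X = X, m = ncol(X) / 3L)
}

train_predictor <- function(data, architecture, task, grid, folds, reduced,
                            seed, verbose, ctrl_overrides) {
  architecture <- match.arg(architecture, c("nn", "xgb", "rf", "svm"))
  res <- resolve_training_frame(data)
  ctrl <- modifyList(list(hidden_width = 64L, max_epochs = 500L,
                          patience = 150L, batch_size = 128L,
                          learning_rate = 3e-3, rounds = 500L,
                          early_stop = 50L, cv_max_epochs = 80L,
                          cv_patience = 20L, cv_batch_size = 512L,
                          seed = seed),
                     ctrl_overrides)
  if (is.null(grid)) grid <- default_grid(architecture, reduced = reduced)

  if (task == "classification") {
    if (!"class" %in% names(res$df)) {
      stop_invalid("Training data needs a `class` column.")
    }
    y <- as.character(res$df$class)
    if (!all(y %in% CLASS_LEVELS)) {
      stop_invalid("`class` must be 'redundant' or 'unique'.")
    }
    single_class <- length(unique(y)) == 1L
    if (single_class) {
      warn("Training data contains a single class; the model will always predict it.")
    }
  } else {
    y <- target_matrix(res$df)
    if (any(!is.finite(y))) stop_invalid("Targets contain non-finite values.")
  }

  X <- res$X
  scaling <- NULL
  if (arch_uses_standardised(architecture)) {
    ctr <- colMeans(X)
    scl <- pmax(apply(X, 2L, sd), 1e-12)
    X <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
    scaling <- list(center = ctr, scale = scl)
  }
  t_scaling <- NULL
  if (task == "regression" && architecture == "nn") {
    tc <- colMeans(y); ts <- pmax(apply(y, 2L, sd), 1e-12)
    y <- sweep(sweep(y, 2L, tc), 2L, ts, "/")
    t_scaling <- list(center = tc, scale = ts)
  }

  with_seed(seed, {
    if (task == "classification" && single_class) {
      cv <- grid[1L, , drop = FALSE]
      cv$cv_loss <- NA_real_
      fit <- list(constant_class = unique(y))
      best <- cv[1L, ]
    } else {
      cv <- if (nrow(grid) > 1L) {
        # the grid search runs each network on a shorter epoch budget than
        # the final refit; relative ranking is stable well before full
        # convergence
        ctrl_cv <- ctrl
        ctrl_cv$max_epochs <- min(ctrl$cv_max_epochs, ctrl$max_epochs)
        ctrl_cv$patience <- min(ctrl$cv_patience, ctrl$patience)
        ctrl_cv$batch_size <- max(ctrl$cv_batch_size, ctrl$batch_size)
        cv_grid(architecture, X, y, grid, folds, task, ctrl_cv, verbose)
      } else {
        grid$cv_loss <- NA_real_
        grid
      }
      best <- cv[which.min(replace(cv$cv_loss, is.na(cv$cv_loss), Inf)), ]
      if (all(is.na(cv$cv_loss))) best <- cv[1L, ]
      fit <- arch_fit(architecture, X, y, best, task, ctrl)
    }
    structure(list(
      architecture = architecture, task = task, fit = fit,
      hyperparameters = best[setdiff(names(best), "cv_loss")],
      cv = cv, scaling = scaling, t_scaling = t_scaling, m = res$m,
      levels = CLASS_LEVELS, folds = folds, seed = seed,
      package_version = as.character(utils::packageVersion("oudel"))),
      class = c(paste0("oudel_", architecture), "oudel_predictor"))
  })
}

#' Train a redundant-vs-unique classifier
#'
#' Grid-searches the architecture's hyperparameters by stratified-free 5-fold
#' cross-validation on classification cross-entropy, then refits the winning
#' configuration on the full training data.  Features are standardised with
#' training-set statistics for the NN and SVM; trees see raw features.
#'
#' @param data An `oudel_sim` object or a data frame with a `class` column
#'   and feature columns in the [event_features()] layout.
#' @param architecture `"nn"`, `"xgb"`, `"rf"` or `"svm"`.
#' @param grid Optional custom hyperparameter tibble (see [default_grid()]).
#' @param folds Number of cross-validation folds.
#' @param reduced Use the endpoints-plus-midpoint grid (desk-scale mode).
#' @param seed Optional integer seed controlling folds, initialisation and
#'   any stochastic fitting.
#' @param verbose Report per-grid-point cross-validation loss.
#' @param ... Training controls: `hidden_width`, `max_epochs`, `patience`,
#'   `batch_size` (NN); `rounds`, `early_stop` (XGB).
#' @return An `oudel_predictor` object.
#' @examples
#' sim <- simulate_deletion_data(n_events = 60, m = 2, seed = 1)
#' fit <- train_deletion_classifier(sim, "rf", seed = 1)
#' predict(fit, sim)[1:3]
#' @export
train_deletion_classifier <- function(data, architecture = "nn", grid = NULL,
                                      folds = 5L, reduced = FALSE,
                                      seed = NULL, verbose = FALSE, ...) {
  train_predictor(data, architecture, "classification", grid, folds, reduced,
                  seed, verbose, list(...))
}

#' Train a 3m-output parameter regressor
#'
#' Fits the per-condition `(theta1, theta2, log10sv)` targets: the NN as one
#' multi-output network, the tree and kernel architectures as one model per
#' output dimension.  Cross-validation minimises mean squared error across
#' all outputs.
#'
#' @inheritParams train_deletion_classifier
#' @return An `oudel_predictor` object with `task = "regression"`.
#' @export
train_deletion_regressor <- function(data, architecture = "nn", grid = NULL,
                                     folds = 5L, reduced = FALSE,
                                     seed = NULL, verbose = FALSE, ...) {
  train_predictor(data, architecture, "regression", grid, folds, reduced,
                  seed, verbose, list(...))
}

# prediction ------------------------------------------------------------------

resolve_newdata <- function(object, newdata) {
  X <- if (is.matrix(newdata)) {
    newdata
  } else if (is.numeric(newdata)) {
    matrix(newdata, nrow = 1L)
  } else {
    feature_matrix(newdata)
  }
  if (ncol(X) != 3L * object$m) {
    stop_invalid(sprintf(
      "Feature dimension mismatch: model expects 3m = %d columns, got %d.",
      3L * object$m, ncol(X)))
  }
  if (!is.null(object$scaling)) {
    X <- sweep(sweep(X, 2L, object$scaling$center), 2L,
               object$scaling$scale, "/")
  }
  X
}

#' Predict classes, class probabilities or parameters
#'
#' @param object An `oudel_predictor`.
#' @param newdata An `oudel_sim`, data frame with feature columns, numeric
#'   matrix, or single feature vector.
#' @param type `"class"` (labels), `"prob"` (matrix of class probabilities;
#'   the `"unique"` column is the ROC score), or `"params"` (matrix of
#'   per-condition parameter estimates) — the latter only for regressors.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.oudel_predictor <- function(object, newdata,
                                    type = c("class", "prob", "params"),
                                    ...) {
  type <- match.arg(type)
  X <- resolve_newdata(object, newdata)
  if (object$task == "classification") {
    if (type == "params") {
      stop_invalid("`type = 'params'` needs a regression model.")
    }
    prob <- if (!is.null(object$fit$constant_class)) {
      p <- matrix(0, nrow(X), 2L, dimnames = list(NULL, CLASS_LEVELS))
      p[, object$fit$constant_class] <- 1
      p
    } else {
      arch_predict(object$architecture, object$fit, X, "classification")
    }
    if (type == "prob") return(prob)
    factor(CLASS_LEVELS[max.col(prob, ties.method = "first")], CLASS_LEVELS)
  } else {
    if (type == "class") {
      stop_invalid("`type = 'class'` needs a classification model.")
    }
    out <- arch_predict(object$architecture, object$fit, X, "regression")
    if (!is.null(object$t_scaling)) {
      out <- sweep(sweep(out, 2L, object$t_scaling$scale, "*"), 2L,
                   object$t_scaling$center, "+")
    }
    colnames(out) <- target_names(object$m)
    out
  }
}

#' @export
print.oudel_predictor <- function(x, ...) {
  cat(sprintf("<oudel_predictor> %s %s (m = %d)\n", toupper(x$architecture),
              x$task, x$m))
  hp <- x$hyperparameters
  if (ncol(hp)) {
    cat("  selected:",
        paste(sprintf("%s = %.4g", names(hp), as.numeric(hp[1, ])),
              collapse = ", "), "\n")
  }
  if (!all(is.na(x$cv$cv_loss))) {
    cat(sprintf("  cv loss: %.5f over %d grid points (%d folds)\n",
                min(x$cv$cv_loss, na.rm = TRUE), nrow(x$cv), x$folds))
  }
  invisible(x)
}

#' @export
tidy.oudel_predictor <- function(x, ...) {
  hp <- x$hyperparameters
  tibble(term = names(hp), estimate = as.numeric(hp[1, ]))
}

#' @export
glance.oudel_predictor <- function(x, ...) {
  tibble(architecture = x$architecture, task = x$task, m = x$m,
         n_grid = nrow(x$cv),
         cv_loss = if (all(is.na(x$cv$cv_loss))) NA_real_
                   else min(x$cv$cv_loss, na.rm = TRUE),
         folds = x$folds)
}

# serialisation ---------------------------------------------------------------

#' Save / load a trained predictor
#'
#' The bundle records the architecture, selected hyperparameters,
#' standardisation statistics, fitted state and provenance; the loader
#' validates the format tag.  Predictions round-trip bit-identically.
#'
#' @param object An `oudel_predictor`.
#' @param path File path.
#' @return `load_predictor()` returns the restored `oudel_predictor`.
#' @export
save_predictor <- function(object, path) {
  if (!inherits(object, "oudel_predictor")) {
    stop_invalid("`object` must be an oudel_predictor.")
  }
  if (inherits(object$fit, "xgb.Booster")) {
    object$fit <- xgboost::xgb.save.raw(object$fit)
    object$fit_format <- "xgb_raw"
  } else if (object$architecture == "xgb" && is.list(object$fit) &&
             is.null(object$fit$constant_class)) {
    object$fit <- lapply(object$fit, xgboost::xgb.save.raw)
    object$fit_format <- "xgb_raw_list"
  }
  saveRDS(list(format = "oudel_predictor_bundle_v1", model = object), path)
  invisible(path)
}

#' @rdname save_predictor
#' @export
load_predictor <- function(path) {
  bundle <- readRDS(path)
  if (!identical(bundle$format, "oudel_predictor_bundle_v1")) {
    stop_invalid("File is not an oudel predictor bundle.")
  }
  object <- bundle$model
  if (identical(object$fit_format, "xgb_raw")) {
    object$fit <- xgboost::xgb.load.raw(object$fit)
  } else if (identical(object$fit_format, "xgb_raw_list")) {
    object$fit <- lapply(object$fit, xgboost::xgb.load.raw)
  }
  object$fit_format <- NULL
  object
}
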