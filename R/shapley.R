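# Sampling-based Shapley feature attribution for trained classifiers.
# Monte-Carlo estimate over random feature permutations and random background
# rows (Strumbelj-Kononenko sampling); the value function is the predicted
# probability of the "unique" class.

#' Shapley feature importance of a trained classifier
#'
#' Estimates, for a sample of observations, the Shapley contribution of each
#' of the 3m features to the predicted "unique" probability, and reports the
#' mean absolute contribution per feature.  Contributions are approximated by
#' Monte-Carlo sampling over random feature orderings with marginal values
#' imputed from a background sample of the supplied data.
#'
#' @param model A classification `oudel_predictor`.
#' @param data An `oudel_sim` or data frame supplying both the observations
#'   to explain and the background distribution.
#' @param n_background Number of rows used as the background sample.
#' @param n_explain Number of observations to explain (drawn from `data`).
#' @param n_perm Monte-Carlo permutations per observation.
#' @param seed Optional integer seed.
#' @return A tibble with columns `feature`, `role` (D/S/L), `condition`, and
#'   `mean_abs_shapley`, sorted by decreasing importance.
#' @export
shapley_importance <- function(model, data, n_background = 100L,
                               n_explain = 100L, n_perm = 20L, seed = NULL) {
  if (!inherits(model, "oudel_predictor") || model$task != "classification") {
    stop_invalid("`model` must be a classification oudel_predictor.")
  }
  X <- if (is.matrix(data)) data else feature_matrix(data)
  p <- ncol(X)
  if (p != 3L * model$m) stop_invalid("Feature dimension mismatch.")
  f <- function(mat) predict(model, mat, type = "prob")[, "unique"]

  with_seed(seed, {
    bg_idx <- sample.int(nrow(X), min(n_background, nrow(X)))
    ex_idx <- sample.int(nrow(X), min(n_explain, nrow(X)))
    BG <- X[bg_idx, , drop = FALSE]
    phi <- matrix(0, length(ex_idx), p)
    for (t in seq_len(n_perm)) {
      perm <- sample.int(p)
      b <- BG[sample.int(nrow(BG), length(ex_idx), replace = TRUE), ,
              drop = FALSE]
      # walk the permutation once: start from the background row and switch
      # features to the explained row one at a time; successive prediction
      # differences are the per-feature contributions for this draw
      cur <- b
      prev_pred <- f(cur)
      for (j in perm) {
        cur[, j] <- X[ex_idx, j]
        new_pred <- f(cur)
        phi[, j] <- phi[, j] + (new_pred - prev_pred)
        prev_pred <- new_pred
      }
    }
    phi <- phi / n_perm
    imp <- colMeans(abs(phi))
    nm <- feature_names(model$m)
    out <- tibble(
      feature = nm,
      role = sub("^e([DSL])_\\d+$", "\\1", nm),
      condition = as.integer(sub("^e[DSL]_(\\d+)$", "\\1", nm)),
      mean_abs_shapley = imp)
    dplyr::arrange(out, dplyr::desc(.data$mean_abs_shapley))
  })
}

#' Summarise Shapley importance by gene role
#'
#' @param importance Output of [shapley_importance()].
#' @return A tibble with one row per role (D, S, L) and the mean importance
#'   of its features.
#' @export
shapley_by_role <- function(importance) {
  dplyr::summarise(dplyr::group_by(importance, .data$role),
                   mean_importance = mean(.data$mean_abs_shapley),
                   .groups = "drop")
}
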