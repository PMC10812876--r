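# Shared fixtures.  Everything is generated in code at test time; the heavy
# study-scale pipeline is built lazily once per session and reused across
# test files.

.oudel_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .oudel_cache, inherits = FALSE)) {
    assign(key, builder(), envir = .oudel_cache)
  }
  get(key, envir = .oudel_cache, inherits = FALSE)
}

# An easy, nearly separable two-condition panel: redundant events share one
# optimum; unique events have optima at least 4 apart.  Strong selection and
# tiny drift make the classes almost non-overlapping.
make_separable_panel <- function(n_events, m = 2L, seed = 1) {
  withr::with_seed(seed, {
    n_red <- n_events %/% 2L
    rows <- lapply(seq_len(n_events), function(i) {
      lab <- if (i <= n_red) "redundant" else "unique"
      th1 <- if (lab == "redundant") runif(m, 0, 5) else runif(m, 4.5, 5)
      th2 <- if (lab == "redundant") th1 else runif(m, 0, 0.5)
      alpha <- rep(1000, m); s2 <- rep(0.01, m); t_ds <- runif(1)
      tr <- t(vapply(seq_len(m), function(k) {
        ou_sample(1, th1[k], th2[k], alpha[k], s2[k], t_ds)[1, ]
      }, numeric(3)))
      c(event_features(tr),
        stats::setNames(as.vector(rbind(th1, th2,
                                        stationary_variance_log10(s2, alpha))),
                        oudel:::target_names(m)),
        class = lab)
    })
    df <- as.data.frame(do.call(rbind, rows))
    num <- setdiff(names(df), "class")
    df[num] <- lapply(df[num], as.numeric)
    df$event_id <- sprintf("toy%04d", seq_len(n_events))
    tibble::as_tibble(df)[sample.int(n_events), ]
  })
}

separable_train <- function() {
  cache_get("separable_train", function() make_separable_panel(600, seed = 11))
}

separable_test <- function() {
  cache_get("separable_test", function() make_separable_panel(200, seed = 12))
}

# one-row hyperparameter grids so unit tests stay fast
grid1 <- function(architecture) {
  switch(architecture,
    nn = tibble::tibble(n_hidden_layers = 1L, gamma = 0, log10_lambda = -4),
    xgb = tibble::tibble(max_depth = 3L, gamma = 0.5, log10_lambda = -8,
                         eta = 0.155),
    svm = tibble::tibble(log10_cost = 0, kernel_gamma = 0.5),
    rf = tibble::tibble(num_trees = 500))
}

toy_classifier <- function(architecture = "rf") {
  cache_get(paste0("toy_cls_", architecture), function() {
    train_deletion_classifier(separable_train(), architecture,
                              grid = grid1(architecture), seed = 5,
                              max_epochs = 200L)
  })
}

toy_regressor <- function(architecture = "rf") {
  cache_get(paste0("toy_reg_", architecture), function() {
    train_deletion_regressor(separable_train(), architecture,
                             grid = grid1(architecture), seed = 6,
                             max_epochs = 200L)
  })
}
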