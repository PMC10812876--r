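# The labelled-dataset generator: parameter draws, rejection sampling,
# class balance, determinism, noise injection and TSV persistence.

test_that("configuration is validated", {
  expect_error(sim_config(theta_range = c(5, 0)), class = "oudel_invalid_input")
  expect_error(sim_config(m = 0), class = "oudel_invalid_input")
  expect_error(sim_config(class_proportions = c(0.5, 0.6)),
               class = "oudel_invalid_input")
  expect_error(sim_config(bounds = c(2, 1)), class = "oudel_invalid_input")
  expect_error(sim_config(noise_sd = -1), class = "oudel_invalid_input")
})

test_that("event parameter draws respect the class definition", {
  cfg <- sim_config()
  red <- draw_event_params(cfg, "redundant", seed = 1)
  expect_identical(red$conditions$theta1, red$conditions$theta2)
  uni <- draw_event_params(cfg, "unique", seed = 2)
  expect_true(all(uni$conditions$theta1 != uni$conditions$theta2))
  expect_equal(nrow(red$conditions), cfg$m)
  # event-level sharing replicates one parameter set across conditions
  cfg_ev <- sim_config(param_sharing = "event")
  ev <- draw_event_params(cfg_ev, "unique", seed = 3)
  expect_equal(length(unique(ev$conditions$alpha)), 1L)
  expect_equal(length(unique(ev$conditions$theta1)), 1L)
})

test_that("log10(alpha) draws are uniform over the stated range", {
  cfg <- sim_config(n_events = 4000, m = 1, bounds = c(-Inf, Inf))
  sim <- simulate_deletion_data(cfg, seed = 17)
  ks <- stats::ks.test(log10(sim$params$alpha), "punif", 0, 3)
  expect_gt(ks$p.value, 0.01)
  ks2 <- stats::ks.test(log10(sim$params$sigma_sq), "punif", -2, 3)
  expect_gt(ks2$p.value, 0.01)
})

test_that("rejection sampling honours the acceptance bounds", {
  cfg <- sim_config(n_events = 200, m = 3)
  sim <- simulate_deletion_data(cfg, seed = 5)
  feats <- sim$data[, oudel:::sim_feature_cols(sim$data)]
  expect_true(all(feats >= 0 & feats <= 5))
  # infeasible bounds exhaust the attempt budget with a clear error
  bad <- sim_config(n_events = 2, theta_range = c(0, 5),
                    log10_sigma_sq_range = c(-2, -2), bounds = c(10, 11),
                    max_attempts = 2000)
  expect_error(simulate_event(bad, "redundant", seed = 1),
               class = "oudel_rejection_exhausted")
})

test_that("class counts follow the configured proportions exactly", {
  sim <- simulate_deletion_data(sim_config(n_events = 400), seed = 8)
  expect_equal(unname(table(sim$data$class)["redundant"]), 200L,
               ignore_attr = TRUE)
  skew <- simulate_deletion_data(
    sim_config(n_events = 10,
               class_proportions = c(redundant = 0.9, unique = 0.1)),
    seed = 9)
  expect_equal(sum(skew$data$class == "redundant"), 9L)
})

test_that("datasets are deterministic under a fixed seed", {
  a <- simulate_deletion_data(sim_config(n_events = 50), seed = 123)
  b <- simulate_deletion_data(sim_config(n_events = 50), seed = 123)
  expect_identical(a$data, b$data)
  expect_identical(a$params, b$params)
})

test_that("targets are the deterministic transform of the stored truth", {
  sim <- simulate_deletion_data(sim_config(n_events = 60), seed = 10)
  pars <- sim$params
  for (i in sample(nrow(sim$data), 10)) {
    ev <- sim$data$event_id[i]
    p <- pars[pars$event_id == ev, ]
    expect_equal(
      as.numeric(sim$data[i, oudel:::target_names(6)]),
      as.vector(rbind(p$theta1, p$theta2,
                      stationary_variance_log10(p$sigma_sq, p$alpha))))
  }
})

test_that("simulated event structure matches the feature layout", {
  cfg <- sim_config(n_events = 1, m = 4)
  ev <- simulate_event(cfg, "unique", seed = 3)
  expect_length(ev$features, 12L)
  expect_named(ev$features, feature_names(4))
  expect_length(ev$target, 12L)
  expect_equal(nrow(ev$params$conditions), 4L)
})

test_that("noise injection perturbs features only, by the stated amount", {
  sim <- simulate_deletion_data(sim_config(n_events = 800, m = 2), seed = 30)
  same <- add_expression_noise(sim, 0)
  expect_identical(same$data, sim$data)
  noisy <- add_expression_noise(sim, 1, seed = 31)
  expect_identical(noisy$data$class, sim$data$class)
  expect_identical(noisy$data[, oudel:::target_names(2)],
                   sim$data[, oudel:::target_names(2)])
  dd <- as.matrix(noisy$data[, feature_names(2)]) -
    as.matrix(sim$data[, feature_names(2)])
  # per-cell sd of the added noise ~ 1 with SE ~ 1/sqrt(2n)
  expect_lt(abs(sd(dd) - 1), 4 / sqrt(2 * length(dd)))
  expect_error(add_expression_noise(sim, -0.1), class = "oudel_invalid_input")
})

test_that("ancestral-optimum scenario datasets are produced and labelled", {
  cfg <- sim_config(n_events = 40, scenario = "theta0")
  sim <- simulate_deletion_data(cfg, seed = 12)
  expect_true("theta0" %in% names(sim$params))
  expect_equal(nrow(sim$data), 40L)
  red <- sim$params[sim$params$class == "redundant", ]
  expect_identical(red$theta1, red$theta2)
})

test_that("TSV round trip preserves the dataset bit-exactly", {
  dir <- withr::local_tempdir()
  sim <- simulate_deletion_data(sim_config(n_events = 25, m = 2), seed = 77)
  write_sim_dataset(sim, dir, prefix = "rt")
  back <- read_sim_dataset(dir, prefix = "rt")
  merged <- back$data[match(sim$data$event_id, back$data$event_id), ]
  for (col in c(feature_names(2), oudel:::target_names(2))) {
    expect_identical(merged[[col]], sim$data[[col]])
  }
  expect_identical(merged$class, sim$data$class)
  expect_equal(back$config$n_events, sim$config$n_events)
  expect_error(read_sim_dataset(dir, prefix = "nope"),
               class = "oudel_invalid_input")
})
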