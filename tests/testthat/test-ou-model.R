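# The OU generative layer: means, covariances, sampling, log-likelihood,
# stationary variance and the feature-vector layout.

test_that("OU mean follows the optimum-shift formula", {
  # redundant collapse: shared optimum gives a flat mean vector
  expect_equal(unname(ou_mean(3, 3, 7, 0.4)[1, ]), c(3, 3, 3))
  # direct evaluation: (1 - e^-0.5) * 2 + e^-0.5 * 0
  mu <- ou_mean(2, 0, 1, 0.5)[1, ]
  expect_equal(unname(mu), c(0.786939, 0.786939, 0), tolerance = 1e-5)
  # strong selection pins D and S at theta1
  mu_fast <- ou_mean(2, 0, 1000, 0.5)[1, ]
  expect_equal(unname(mu_fast), c(2, 2, 0), tolerance = 1e-6)
  expect_error(ou_mean(NA, 0, 1, 0.5), class = "oudel_invalid_input")
})

test_that("OU mean of D and S is a convex combination of the optima", {
  withr::with_seed(42, {
    for (i in 1:200) {
      th1 <- runif(1, -5, 5); th2 <- runif(1, -5, 5)
      mu <- ou_mean(th1, th2, 10^runif(1, -2, 3), runif(1))[1, ]
      expect_identical(mu[["D"]], mu[["S"]])
      expect_gte(mu[["D"]], min(th1, th2) - 1e-12)
      expect_lte(mu[["D"]], max(th1, th2) + 1e-12)
    }
  })
})

test_that("OU covariance has the stationary structure", {
  sig <- ou_covariance(0.5, 1, 0.5)
  expect_equal(unname(diag(sig)), rep(1, 3))
  expect_equal(sig["D", "S"], 0.606531, tolerance = 1e-5)
  expect_equal(sig["D", "L"], 0.367879, tolerance = 1e-5)
  expect_equal(sig["S", "L"], 0.367879, tolerance = 1e-5)
  # sigma_sq / (2 alpha) = 1 on the diagonal
  expect_equal(unname(diag(ou_covariance(2, 4, 0.3))), rep(1, 3))
  expect_error(ou_covariance(-1, 1, 0.5), class = "oudel_invalid_input")
  expect_error(ou_covariance(1, 0, 0.5), class = "oudel_invalid_input")
})

test_that("OU covariance is symmetric positive definite across the prior", {
  withr::with_seed(7, {
    for (i in 1:1000) {
      alpha <- 10^runif(1, 0, 3)
      s2 <- 10^runif(1, -2, 3)
      t_ds <- runif(1)
      sig <- ou_covariance(alpha, s2, t_ds)
      expect_identical(sig, t(sig))
      ev <- eigen(sig, symmetric = TRUE, only.values = TRUE)$values
      expect_gt(min(ev), 0)
    }
  })
})

test_that("log-likelihood matches an independent MVN density", {
  # frozen from the closed-form constant -0.5 * (3 log 2pi + log det(Sigma))
  mu <- ou_mean(2, 0, 0.5, 0.5)[1, ]
  expect_equal(ou_loglik(mu, 2, 0, 0.5, 1, 0.5), -2.435227, tolerance = 1e-6)
  # translation invariance of the location family
  e <- c(1.3, 0.2, 2.2)
  expect_equal(ou_loglik(e, 2, 0, 1, 1, 0.5),
               ou_loglik(e + 10, 12, 10, 1, 1, 0.5))
  # oracle equivalence on random draws
  withr::with_seed(99, {
    for (i in 1:200) {
      th1 <- runif(1, 0, 5); th2 <- runif(1, 0, 5)
      alpha <- 10^runif(1, 0, 3); s2 <- 10^runif(1, -2, 3)
      t_ds <- runif(1, 0.01, 0.99)
      e <- rnorm(3, 2, 2)
      expect_equal(
        ou_loglik(e, th1, th2, alpha, s2, t_ds),
        mvtnorm::dmvnorm(e, ou_mean(th1, th2, alpha, t_ds)[1, ],
                         ou_covariance(alpha, s2, t_ds), log = TRUE),
        tolerance = 1e-8)
    }
  })
})

test_that("sampling is seed-reproducible and concentrates at vanishing noise", {
  a <- ou_sample(5, 2, 0, 1, 1, 0.5, seed = 123)
  b <- ou_sample(5, 2, 0, 1, 1, 0.5, seed = 123)
  expect_identical(a, b)
  tight <- ou_sample(10, 1.5, 0.5, 1, 1e-12, 0.5, seed = 1)
  mu <- ou_mean(1.5, 0.5, 1, 0.5)[1, ]
  expect_true(all(abs(sweep(tight, 2, mu)) < 1e-4))
})

test_that("stationary variance is computed on the log10 scale", {
  expect_equal(stationary_variance_log10(1, 0.5), 0)
  expect_equal(stationary_variance_log10(1000, 1), log10(500))
  expect_equal(stationary_variance_log10(0.01, 1000), -5.30103,
               tolerance = 1e-6)
  expect_error(stationary_variance_log10(-1, 1), class = "oudel_invalid_input")
})

test_that("feature vectors use condition-major D-S-L layout and round-trip", {
  expect_equal(unname(event_features(matrix(c(1, 2, 3), 1))), c(1, 2, 3))
  two <- matrix(1:6, 2, 3, byrow = TRUE)
  expect_equal(unname(event_features(two)), 1:6)
  expect_equal(names(event_features(two)),
               c("eD_1", "eS_1", "eL_1", "eD_2", "eS_2", "eL_2"))
  withr::with_seed(3, {
    tr <- matrix(rnorm(18), 6, 3)
    expect_equal(unname(split_features(event_features(tr))), tr)
  })
  expect_error(event_features(matrix(numeric(0), 0, 3)),
               class = "oudel_invalid_input")
  expect_error(split_features(1:4), class = "oudel_invalid_input")
})

test_that("ancestral-optimum scenario means collapse and saturate correctly", {
  # theta0 = theta1 = theta2 reduces to the flat redundant mean
  expect_equal(unname(oudel:::ou_mean_theta0(2, 2, 2, 1)[1, ]), rep(2, 3))
  # strong selection forgets the ancestral optimum
  expect_equal(unname(oudel:::ou_mean_theta0(0, 3, 1, 1000)[1, ]),
               c(3, 3, 1), tolerance = 1e-6)
  # finite alpha: mu_D - theta1 = (theta0 - theta1) e^-alpha
  m <- oudel:::ou_mean_theta0(4, 1, 2, 0.7)[1, ]
  expect_equal(m[["D"]] - 1, (4 - 1) * exp(-0.7))
  expect_equal(m[["L"]] - 2, (4 - 2) * exp(-0.7))
})
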