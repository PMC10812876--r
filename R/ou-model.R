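# Ornstein-Uhlenbeck model of D/S/L expression after a gene deletion.
#
# A duplication at (scaled) time t_dsl = 1 before the present created two
# copies in the ancestor of two sister species; one copy was later deleted in
# the lineage of species 1.  The surviving single copy in species 1 is the
# "derived" (D) gene, its ortholog in species 2 the "survived" (S) gene, and
# the copy deleted in species 1 but present in species 2 the "lost" (L) gene.
# D and S share expression optimum theta1; L (and the pre-duplication
# ancestor) has optimum theta2.  Expression evolves along the three-tip gene
# tree as an OU process with selection strength alpha and drift rate
# sigma_sq, giving a trivariate normal expression vector per condition.

GENE_ROLES <- c("D", "S", "L")

check_ou_params <- function(theta1, theta2, alpha, sigma_sq, t_ds, t_dsl) {
  if (any(!is.finite(theta1)) || any(!is.finite(theta2))) {
    stop_invalid("Expression optima `theta1` and `theta2` must be finite.")
  }
  check_positive(alpha, "alpha")
  check_positive(sigma_sq, "sigma_sq")
  if (any(!is.finite(t_ds)) || any(t_ds < 0) || any(t_ds > t_dsl)) {
    stop_invalid("`t_ds` must lie in [0, t_dsl].")
  }
  if (any(!is.finite(t_dsl)) || any(t_dsl <= 0)) {
    stop_invalid("`t_dsl` must be positive and finite.")
  }
  invisible(TRUE)
}

#' Expected expression of the D, S and L genes under the OU model
#'
#' Computes the mean of the trivariate normal expression distribution for one
#' condition.  The D and S lineages are pulled toward their shared optimum
#' `theta1` over the time `t_ds` since their divergence, starting from the
#' ancestral optimum `theta2`, so their common mean is the convex combination
#' `(1 - exp(-alpha * t_ds)) * theta1 + exp(-alpha * t_ds) * theta2`.  The L
#' gene keeps the ancestral optimum, so its mean is `theta2`.
#'
#' @param theta1 Expression optimum of the D and S genes (log-expression
#'   units).  Vectorised over conditions.
#' @param theta2 Expression optimum of the L gene and of the pre-duplication
#'   ancestor.
#' @param alpha Selection strength (> 0, per unit tree time).
#' @param t_ds Time since the D-S divergence, in units of the (scaled) time
#'   since duplication.
#' @return A numeric matrix with one row per condition and columns
#'   `D`, `S`, `L`.
#' @examples
#' ou_mean(theta1 = 2, theta2 = 0, alpha = 1, t_ds = 0.5)
#' @export
ou_mean <- function(theta1, theta2, alpha, t_ds) {
  check_ou_params(theta1, theta2, alpha, 1, t_ds, 1)
  w <- exp(-alpha * t_ds)
  mu_ds <- (1 - w) * theta1 + w * theta2
  n <- max(length(theta1), length(theta2), length(alpha), length(t_ds))
  out <- cbind(D = rep_len(mu_ds, n), S = rep_len(mu_ds, n),
               L = rep_len(theta2, n))
  out
}

#' Covariance of D, S and L expression under the OU model
#'
#' The stationary OU covariance for the three-tip gene tree: all three genes
#' have stationary variance `sigma_sq / (2 * alpha)`; D and S covary through
#' their shared history up to `t_ds` before the present, and each covaries
#' with L through the shared history up to the duplication time `t_dsl`.
#'
#' @inheritParams ou_mean
#' @param sigma_sq Drift (Brownian) variance rate (> 0).
#' @param t_dsl Time since the duplication event; scaled to 1 by convention.
#' @return A symmetric positive-definite 3x3 matrix with dimnames
#'   `c("D", "S", "L")`.
#' @examples
#' ou_covariance(alpha = 0.5, sigma_sq = 1, t_ds = 0.5)
#' @export
ou_covariance <- function(alpha, sigma_sq, t_ds, t_dsl = 1) {
  check_ou_params(0, 0, alpha, sigma_sq, t_ds, t_dsl)
  v <- sigma_sq / (2 * alpha)
  r_ds <- exp(-2 * alpha * t_ds)
  r_dsl <- exp(-2 * alpha * t_dsl)
  sig <- v * matrix(c(1, r_ds, r_dsl,
                      r_ds, 1, r_dsl,
                      r_dsl, r_dsl, 1), 3, 3,
                    dimnames = list(GENE_ROLES, GENE_ROLES))
  sig
}

#' Log10 stationary variance of the OU process
#'
#' `log10(sigma_sq / (2 * alpha))`, the equilibrium variance of an OU process
#' on the log10 scale; the package's one-number summary of the strength of
#' drift relative to selection.
#'
#' @inheritParams ou_covariance
#' @return Numeric vector of `log10(sigma_sq / (2 * alpha))`.
#' @examples
#' stationary_variance_log10(sigma_sq = 1, alpha = 0.5)
#' @export
stationary_variance_log10 <- function(sigma_sq, alpha) {
  check_positive(alpha, "alpha")
  check_positive(sigma_sq, "sigma_sq")
  log10(sigma_sq) - log10(2 * alpha)
}

# Cholesky factor with a single jitter retry; near-singular covariances arise
# when t_ds approaches t_dsl and alpha is small.
chol_with_jitter <- function(sig) {
  ch <- tryCatch(chol(sig), error = function(e) NULL)
  if (is.null(ch)) {
    jitter <- 1e-10 * mean(diag(sig))
    ch <- tryCatch(chol(sig + diag(jitter, nrow(sig))), error = function(e) NULL)
    if (is.null(ch)) {
      stop_numerical(
        "OU covariance matrix is numerically singular even after jitter.",
        smallest_eigenvalue = min(eigen(sig, symmetric = TRUE,
                                        only.values = TRUE)$values))
    }
  }
  ch
}

#' Draw expression triples from the OU model
#'
#' Samples `n` independent (D, S, L) expression triples from the trivariate
#' normal distribution with mean [ou_mean()] and covariance
#' [ou_covariance()].
#'
#' @inheritParams ou_covariance
#' @inheritParams ou_mean
#' @param n Number of draws.
#' @param seed Optional integer seed; the caller's RNG state is restored on
#'   exit.
#' @return An `n` x 3 matrix with columns `D`, `S`, `L`.
#' @examples
#' ou_sample(3, theta1 = 2, theta2 = 0, alpha = 1, sigma_sq = 1,
#'           t_ds = 0.5, seed = 1)
#' @export
ou_sample <- function(n, theta1, theta2, alpha, sigma_sq, t_ds, t_dsl = 1,
                      seed = NULL) {
  check_ou_params(theta1, theta2, alpha, sigma_sq, t_ds, t_dsl)
  mu <- ou_mean(theta1, theta2, alpha, t_ds)[1L, ]
  ch <- chol_with_jitter(ou_covariance(alpha, sigma_sq, t_ds, t_dsl))
  with_seed(seed, {
    z <- matrix(rnorm(3L * n), n, 3L)
    sweep(z %*% ch, 2L, mu, "+")
  }) -> e
  colnames(e) <- GENE_ROLES
  e
}

#' Log-likelihood of expression triples under the OU model
#'
#' Log density of the trivariate normal distribution implied by the OU model,
#' evaluated row-wise.
#'
#' @param e A length-3 numeric vector `(e_D, e_S, e_L)` or an `n` x 3 matrix
#'   of triples.
#' @inheritParams ou_sample
#' @return Numeric vector of per-triple log densities.
#' @examples
#' mu <- ou_mean(2, 0, 1, 0.5)[1, ]
#' ou_loglik(mu, theta1 = 2, theta2 = 0, alpha = 1, sigma_sq = 1, t_ds = 0.5)
#' @export
ou_loglik <- function(e, theta1, theta2, alpha, sigma_sq, t_ds, t_dsl = 1) {
  check_ou_params(theta1, theta2, alpha, sigma_sq, t_ds, t_dsl)
  if (is.vector(e)) e <- matrix(e, nrow = 1L)
  if (ncol(e) != 3L || any(!is.finite(e))) {
    stop_invalid("`e` must be a finite length-3 vector or n x 3 matrix.")
  }
  ou_loglik_fast(e, theta1, theta2, alpha, sigma_sq, t_ds, t_dsl,
                 per_row = TRUE)
}

# Closed-form trivariate normal log density for the structured OU covariance
#   Sigma = v * [[1, r, b], [r, 1, b], [b, b, 1]],
# with v = sigma_sq/(2 alpha), r = exp(-2 alpha t_ds), b = exp(-2 alpha t_dsl).
# Inverse and determinant by cofactor expansion; the hot path of the ML fits.
ou_loglik_fast <- function(e, theta1, theta2, alpha, sigma_sq, t_ds, t_dsl,
                           per_row = FALSE) {
  v <- sigma_sq / (2 * alpha)
  r <- exp(-2 * alpha * t_ds)
  b <- exp(-2 * alpha * t_dsl)
  det3 <- 1 + 2 * r * b * b - r * r - 2 * b * b
  if (!is.finite(det3) || det3 <= 0 || v <= 0) {
    stop_numerical("OU covariance matrix is singular.",
                   correlation_determinant = det3)
  }
  w <- exp(-alpha * t_ds)
  mu_ds <- (1 - w) * theta1 + w * theta2
  c1 <- e[, 1L] - mu_ds
  c2 <- e[, 2L] - mu_ds
  c3 <- e[, 3L] - theta2
  i11 <- 1 - b * b
  i12 <- -(r - b * b)
  i13 <- -(b - r * b)
  i33 <- 1 - r * r
  q <- (i11 * (c1 * c1 + c2 * c2) + i33 * c3 * c3 +
          2 * (i12 * c1 * c2 + i13 * (c1 + c2) * c3)) / (det3 * v)
  const <- -0.5 * (3 * log(2 * pi) + 3 * log(v) + log(det3))
  if (per_row) const - 0.5 * q else nrow(e) * const - 0.5 * sum(q)
}

# feature-vector layout ------------------------------------------------------

#' Names of the 3m feature-vector entries
#'
#' The layout is condition-major, D-S-L within condition:
#' `eD_1, eS_1, eL_1, ..., eD_m, eS_m, eL_m`.
#'
#' @param m Number of conditions.
#' @return Character vector of length `3 * m`.
#' @export
feature_names <- function(m) {
  as.vector(outer(paste0("e", GENE_ROLES, "_"), seq_len(m), paste0))
}

target_names <- function(m) {
  as.vector(outer(c("theta1_", "theta2_", "log10sv_"), seq_len(m), paste0))
}

#' Assemble the feature vector of one deletion event
#'
#' Flattens an `m` x 3 matrix of per-condition (D, S, L) expression triples
#' into the 3m-dimensional feature vector used by all predictors.
#'
#' @param triples An `m` x 3 numeric matrix, rows = conditions, columns =
#'   (D, S, L).
#' @return Named numeric vector of length `3 * m`.
#' @seealso [split_features()] for the inverse.
#' @export
event_features <- function(triples) {
  if (is.vector(triples)) triples <- matrix(triples, nrow = 1L)
  if (!is.numeric(triples) || ncol(triples) != 3L || nrow(triples) < 1L) {
    stop_invalid("`triples` must be a non-empty m x 3 numeric matrix.")
  }
  x <- as.vector(t(triples))
  names(x) <- feature_names(nrow(triples))
  x
}

#' Split a feature vector back into per-condition triples
#'
#' @param x Numeric vector of length `3 * m` in the [event_features()]
#'   layout.
#' @return An `m` x 3 matrix with columns `D`, `S`, `L`.
#' @export
split_features <- function(x) {
  if (length(x) %% 3L != 0L || length(x) < 3L) {
    stop_invalid("Feature vectors must have length 3 * m.")
  }
  out <- matrix(x, ncol = 3L, byrow = TRUE)
  colnames(out) <- GENE_ROLES
  out
}

# Means under the alternative ancestral-optimum scenario: the single-copy
# ancestor sat at optimum theta0; after duplication (t_dsl before present)
# the two copies track constant optima theta1 (D/S lineage) and theta2 (L),
# so each tip mean decays from theta0 toward its own optimum over t_dsl.
ou_mean_theta0 <- function(theta0, theta1, theta2, alpha, t_dsl = 1) {
  w <- exp(-alpha * t_dsl)
  mu_ds <- theta1 + (theta0 - theta1) * w
  mu_l <- theta2 + (theta0 - theta2) * w
  n <- max(length(theta0), length(theta1), length(theta2), length(alpha))
  cbind(D = rep_len(mu_ds, n), S = rep_len(mu_ds, n), L = rep_len(mu_l, n))
}
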