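# Maximum-likelihood baseline: fit one shared set of OU parameters
# (theta1, theta2, alpha, sigma_sq, t_ds) to an event's m expression triples
# under the redundant (theta1 = theta2) and unique (unconstrained) models,
# and classify by a likelihood-ratio test with one degree of freedom.
#
# Optimisation is derivative-free (Nelder-Mead) on unconstrained transforms:
# identity for the optima, log for alpha and sigma_sq, logit for t_ds.

#' Configuration of the maximum-likelihood / LRT classifier
#'
#' @param n_starts Number of random multi-start initialisations per fit.
#' @param theta_range,log10_alpha_range,log10_sigma_sq_range,t_ds_range
#'   Ranges from which start points are drawn.
#' @param reltol Relative convergence tolerance passed to the optimiser.
#' @param maxit Iteration cap per start.
#' @param level Significance level of the LRT ("unique" is called when
#'   `p < level`).
#' @param per_condition If `TRUE`, fit a separate five-parameter model per
#'   condition instead of one shared set (sensitivity-analysis mode; the
#'   default shared fit is the baseline procedure).
#' @return A list of class `oudel_lrt_config`.
#' @export
lrt_config <- function(n_starts = 10L,
                       theta_range = c(0, 5),
                       log10_alpha_range = c(0, 3),
                       log10_sigma_sq_range = c(-2, 3),
                       t_ds_range = c(0, 1),
                       reltol = 1e-8,
                       maxit = 2000L,
                       level = 0.05,
                       per_condition = FALSE) {
  if (n_starts < 1L) stop_invalid("`n_starts` must be >= 1.")
  if (level <= 0 || level >= 1) stop_invalid("`level` must be in (0, 1).")
  structure(list(n_starts = as.integer(n_starts), theta_range = theta_range,
                 log10_alpha_range = log10_alpha_range,
                 log10_sigma_sq_range = log10_sigma_sq_range,
                 t_ds_range = t_ds_range, reltol = reltol,
                 maxit = as.integer(maxit), level = level,
                 per_condition = per_condition),
            class = "oudel_lrt_config")
}

# transforms between natural and unconstrained scales ------------------------

lrt_to_unconstrained <- function(theta1, theta2, alpha, sigma_sq, t_ds) {
  t_ds <- min(max(t_ds, 1e-9), 1 - 1e-9)
  c(theta1, theta2, log(alpha), log(sigma_sq), log(t_ds / (1 - t_ds)))
}

lrt_to_natural <- function(par) {
  list(theta1 = par[1], theta2 = par[2], alpha = exp(par[3]),
       sigma_sq = exp(par[4]), t_ds = 1 / (1 + exp(-par[5])))
}

# joint negative log-likelihood on the transformed scale; `constrained`
# collapses theta2 onto theta1 (the parameter vector then has 4 entries)
lrt_negloglik <- function(par, e_mat, constrained) {
  full <- if (constrained) c(par[1], par[1], par[2:4]) else par
  p <- lrt_to_natural(full)
  if (!all(is.finite(unlist(p))) || p$alpha > 1e12 || p$sigma_sq > 1e12) {
    return(1e10)
  }
  ll <- tryCatch(
    ou_loglik_fast(e_mat, p$theta1, p$theta2, p$alpha, p$sigma_sq, p$t_ds, 1),
    error = function(e) -Inf)
  if (!is.finite(ll)) 1e10 else -ll
}

random_start <- function(cfg, constrained) {
  th <- runif(2, cfg$theta_range[1], cfg$theta_range[2])
  par <- lrt_to_unconstrained(
    th[1], th[2],
    10^runif(1, cfg$log10_alpha_range[1], cfg$log10_alpha_range[2]),
    10^runif(1, cfg$log10_sigma_sq_range[1], cfg$log10_sigma_sq_range[2]),
    runif(1, max(cfg$t_ds_range[1], 1e-6), min(cfg$t_ds_range[2], 1 - 1e-6)))
  if (constrained) par[-2] else par
}

#' Maximum-likelihood OU fit to one event's expression triples
#'
#' Maximises the joint log-likelihood of the `m` per-condition (D, S, L)
#' triples under a single shared parameter set, optionally constrained to the
#' redundant model `theta1 = theta2`.  The best of `n_starts` Nelder-Mead
#' runs (plus any starts supplied in `extra_starts`) is returned.
#'
#' @param triples An `m` x 3 matrix of expression triples (columns D, S, L).
#' @param constrained Fit the redundant model (`theta1 = theta2`)?
#' @param cfg An [lrt_config()].
#' @param seed Optional integer seed for the start draws.
#' @param extra_starts Optional list of transformed start vectors appended to
#'   the random multi-start set.
#' @return A list with `estimates` (named list: `theta1`, `theta2`, `alpha`,
#'   `sigma_sq`, `t_ds`), `loglik`, and `convergence` (0 = clean).
#' @export
fit_ou_ml <- function(triples, constrained = FALSE, cfg = lrt_config(),
                      seed = NULL, extra_starts = NULL) {
  if (is.vector(triples)) triples <- matrix(triples, ncol = 3L, byrow = TRUE)
  if (!is.numeric(triples) || ncol(triples) != 3L || any(!is.finite(triples))) {
    stop_invalid("`triples` must be a finite m x 3 matrix.")
  }
  starts <- with_seed(seed, lapply(seq_len(cfg$n_starts), function(i) {
    random_start(cfg, constrained)
  }))
  starts <- c(starts, extra_starts)
  best <- NULL
  failures <- character()
  for (s in starts) {
    fit <- tryCatch(
      optim(s, lrt_negloglik, e_mat = triples, constrained = constrained,
            method = "Nelder-Mead",
            control = list(reltol = cfg$reltol, maxit = cfg$maxit)),
      error = function(e) {
        failures <<- c(failures, conditionMessage(e))
        NULL
      })
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    abort("All optimisation starts failed.", class = "oudel_optim_failure",
          messages = unique(failures))
  }
  full <- if (constrained) c(best$par[1], best$par[1], best$par[2:4]) else best$par
  list(estimates = lrt_to_natural(full), loglik = -best$value,
       convergence = best$convergence, par = best$par)
}

#' Likelihood-ratio classification of one deletion event
#'
#' Fits the redundant (null) and unique (alternative) OU models, restarts the
#' alternative fit from the null solution so the models are properly nested,
#' and refers `2 * (ll_alt - ll_null)` (clipped at zero) to a chi-square
#' distribution with one degree of freedom.  The event is called "unique"
#' when `p < level`; `1 - p` serves as the ROC score for the unique class.
#'
#' @inheritParams fit_ou_ml
#' @return An object of class `oudel_lrt`: list with `null`, `alt` (fits as
#'   returned by [fit_ou_ml()]), `statistic`, `p_value`, `label`, `score`,
#'   and `m`.
#' @export
lrt_classify <- function(triples, cfg = lrt_config(), seed = NULL) {
  if (is.vector(triples)) triples <- matrix(triples, ncol = 3L, byrow = TRUE)
  if (isTRUE(cfg$per_condition)) {
    return(lrt_classify_per_condition(triples, cfg, seed))
  }
  null_fit <- fit_ou_ml(triples, constrained = TRUE, cfg = cfg,
                        seed = child_seed(seed, 1L))
  # alternative: random starts plus the null solution expanded to 5 params
  null_start <- list(c(null_fit$par[1], null_fit$par[1], null_fit$par[2:4]))
  alt_fit <- fit_ou_ml(triples, constrained = FALSE, cfg = cfg,
                       seed = child_seed(seed, 2L),
                       extra_starts = null_start)
  if (alt_fit$loglik < null_fit$loglik) {
    # optimiser noise; the null is a special case of the alternative
    alt_fit <- list(estimates = null_fit$estimates, loglik = null_fit$loglik,
                    convergence = null_fit$convergence, par = null_start[[1]])
  }
  statistic <- max(2 * (alt_fit$loglik - null_fit$loglik), 0)
  p <- pchisq(statistic, df = 1, lower.tail = FALSE)
  structure(list(null = null_fit, alt = alt_fit, statistic = statistic,
                 p_value = p,
                 label = if (p < cfg$level) "unique" else "redundant",
                 score = 1 - p, m = nrow(triples), cfg = cfg),
            class = "oudel_lrt")
}

# Sensitivity-analysis mode: independent five-parameter fits per condition;
# statistics add, degrees of freedom = m.
lrt_classify_per_condition <- function(triples, cfg, seed = NULL) {
  cfg1 <- cfg
  cfg1$per_condition <- FALSE
  fits <- lapply(seq_len(nrow(triples)), function(k) {
    lrt_classify(triples[k, , drop = FALSE], cfg1, child_seed(seed, 10L + k))
  })
  statistic <- sum(vapply(fits, `[[`, numeric(1), "statistic"))
  p <- pchisq(statistic, df = nrow(triples), lower.tail = FALSE)
  structure(list(condition_fits = fits, statistic = statistic, p_value = p,
                 label = if (p < cfg$level) "unique" else "redundant",
                 score = 1 - p, m = nrow(triples), cfg = cfg),
            class = "oudel_lrt")
}

#' @export
print.oudel_lrt <- function(x, ...) {
  cat(sprintf(
    "<oudel_lrt> statistic = %.4f, p = %.4g, label = %s (m = %d)\n",
    x$statistic, x$p_value, x$label, x$m))
  invisible(x)
}

#' Broadcast LRT parameter estimates into the regression-target layout
#'
#' The shared alternative-model estimates are replicated across the `m`
#' conditions as per-condition `(theta1, theta2, log10sv)` triples, matching
#' the layout predicted by the supervised regressors.
#'
#' @param fit An `oudel_lrt` object.
#' @param m Number of conditions (defaults to the number seen at fit time).
#' @return Named numeric vector of length `3 * m`.
#' @export
lrt_param_estimates <- function(fit, m = fit$m) {
  if (!inherits(fit, "oudel_lrt")) stop_invalid("`fit` must be an oudel_lrt.")
  if (!is.null(fit$condition_fits)) {
    est <- t(vapply(fit$condition_fits, function(f) {
      e <- f$alt$estimates
      c(e$theta1, e$theta2, stationary_variance_log10(e$sigma_sq, e$alpha))
    }, numeric(3)))
  } else {
    e <- fit$alt$estimates
    est <- matrix(c(e$theta1, e$theta2,
                    stationary_variance_log10(e$sigma_sq, e$alpha)),
                  m, 3L, byrow = TRUE)
  }
  out <- as.vector(t(est))
  names(out) <- target_names(nrow(est))
  out
}

#' Run the LRT classifier over a dataset of events
#'
#' @param data An `oudel_sim` object or data frame with feature columns in
#'   the [event_features()] layout (and optionally `event_id`).
#' @param cfg An [lrt_config()].
#' @param seed Optional integer seed.
#' @param progress Print a dot every 100 events.
#' @return A tibble with one row per event: `event_id`, `ll_null`, `ll_alt`,
#'   `statistic`, `p_value`, `score`, `label`, and the five shared
#'   alternative-model estimates.
#' @export
lrt_panel <- function(data, cfg = lrt_config(), seed = NULL,
                      progress = FALSE) {
  x <- feature_matrix(data)
  df <- if (inherits(data, "oudel_sim")) data$data else data
  ids <- if ("event_id" %in% names(df)) df$event_id else sprintf("ev%05d", seq_len(nrow(x)))
  rows <- lapply(seq_len(nrow(x)), function(i) {
    if (progress && i %% 100L == 0L) cat(".")
    fit <- lrt_classify(split_features(x[i, ]), cfg, child_seed(seed, i))
    e <- if (is.null(fit$condition_fits)) fit$alt$estimates else {
      list(theta1 = NA_real_, theta2 = NA_real_, alpha = NA_real_,
           sigma_sq = NA_real_, t_ds = NA_real_)
    }
    tibble(event_id = ids[i],
           ll_null = if (is.null(fit$null)) NA_real_ else fit$null$loglik,
           ll_alt = if (is.null(fit$alt)) NA_real_ else fit$alt$loglik,
           statistic = fit$statistic, p_value = fit$p_value,
           score = fit$score, label = fit$label,
           theta1 = e$theta1, theta2 = e$theta2, alpha = e$alpha,
           sigma_sq = e$sigma_sq, t_ds = e$t_ds)
  })
  if (progress) cat("\n")
  dplyr::bind_rows(rows)
}

#' @export
tidy.oudel_lrt <- function(x, ...) {
  if (!is.null(x$condition_fits)) {
    return(dplyr::bind_rows(lapply(seq_along(x$condition_fits), function(k) {
      out <- tidy.oudel_lrt(x$condition_fits[[k]])
      out$condition <- k
      out
    })))
  }
  est <- function(fit, model) {
    tibble(model = model, term = c("theta1", "theta2", "alpha", "sigma_sq", "t_ds"),
           estimate = unlist(fit$estimates))
  }
  dplyr::bind_rows(est(x$null, "redundant"), est(x$alt, "unique"))
}

#' @export
glance.oudel_lrt <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value, label = x$label,
         ll_null = if (is.null(x$null)) NA_real_ else x$null$loglik,
         ll_alt = if (is.null(x$alt)) NA_real_ else x$alt$loglik,
         m = x$m)
}
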