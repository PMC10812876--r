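# Labelled training/test data for the deletion-event predictors.
#
# Each simulated event draws OU parameters independently per condition across
# broad ranges (theta uniform, alpha and sigma_sq log-uniform), one D-S
# divergence time per event, samples the 3m expression values, and accepts
# the event only if every value falls inside per-condition expression bounds
# (rejection sampling against the range seen in empirical data).  Rejection
# redraws parameters and expression jointly.

#' Simulation configuration
#'
#' Bundles the generative settings for labelled deletion-event datasets.
#' Defaults follow the study conditions of the framework: six conditions,
#' expression optima uniform on \[0, 5\], `log10(alpha)` uniform on \[0, 3\],
#' `log10(sigma_sq)` uniform on \[-2, 3\], D-S divergence time uniform on
#' \[0, 1\], and per-condition acceptance bounds \[0, 5\] matching the optimum
#' range.
#'
#' @param n_events Number of events to simulate.
#' @param m Number of expression conditions (tissues, stages, ...).
#' @param theta_range Range of the uniform draw for expression optima.
#' @param log10_alpha_range Range of the uniform draw for `log10(alpha)`.
#' @param log10_sigma_sq_range Range of the uniform draw for
#'   `log10(sigma_sq)`.
#' @param t_ds_range Range of the uniform draw for the D-S divergence time.
#' @param class_proportions Named proportions for classes `redundant` and
#'   `unique`; must sum to 1.
#' @param bounds Acceptance interval for expression values: a length-2 vector
#'   applied to every condition, or an `m` x 2 matrix of per-condition
#'   bounds.
#' @param max_attempts Rejection-sampling cap per accepted event.
#' @param noise_sd Standard deviation of measurement noise added to finished
#'   feature tables (0 = none).
#' @param scenario `"standard"` (duplicates start at the ancestral optimum
#'   `theta2`) or `"theta0"` (the single-copy ancestor held its own optimum
#'   `theta0`, drawn per condition from `theta0_range`).
#' @param param_sharing `"condition"` draws a fresh `(theta1, theta2, alpha,
#'   sigma_sq)` set for every condition (the training protocol of the
#'   supervised predictors); `"event"` draws one set per event and treats the
#'   `m` conditions as independent replicates of it (the protocol under which
#'   the shared-parameter maximum-likelihood baseline is well specified).
#' @param theta0_range Range of the uniform draw for the ancestral optimum in
#'   the `"theta0"` scenario.
#' @return A list of class `oudel_sim_config`.
#' @export
sim_config <- function(n_events = 2000L,
                       m = 6L,
                       theta_range = c(0, 5),
                       log10_alpha_range = c(0, 3),
                       log10_sigma_sq_range = c(-2, 3),
                       t_ds_range = c(0, 1),
                       class_proportions = c(redundant = 0.5, unique = 0.5),
                       bounds = c(0, 5),
                       max_attempts = 1e5,
                       noise_sd = 0,
                       scenario = c("standard", "theta0"),
                       theta0_range = c(0, 5),
                       param_sharing = c("condition", "event")) {
  scenario <- match.arg(scenario)
  param_sharing <- match.arg(param_sharing)
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop_invalid("`m` must be a positive integer.")
  for (nm in c("theta_range", "log10_alpha_range", "log10_sigma_sq_range",
               "t_ds_range", "theta0_range")) {
    r <- get(nm)
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2]) {
      stop_invalid(sprintf("`%s` must be a well-ordered finite range.", nm))
    }
  }
  if (any(t_ds_range < 0) || any(t_ds_range > 1)) {
    stop_invalid("`t_ds_range` must lie within [0, 1].")
  }
  if (length(class_proportions) != 2L || any(class_proportions <= 0) ||
      abs(sum(class_proportions) - 1) > 1e-8) {
    stop_invalid("`class_proportions` must be two positive values summing to 1.")
  }
  if (is.null(names(class_proportions))) {
    names(class_proportions) <- c("redundant", "unique")
  }
  if (is.matrix(bounds)) {
    if (nrow(bounds) != m || ncol(bounds) != 2L) {
      stop_invalid("Matrix `bounds` must be m x 2.")
    }
  } else {
    if (length(bounds) != 2L) stop_invalid("`bounds` must have length 2.")
    bounds <- matrix(rep(bounds, each = m), m, 2L)
  }
  if (any(bounds[, 1] > bounds[, 2])) {
    stop_invalid("Each bounds row must satisfy min <= max.")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop_invalid("`noise_sd` must be >= 0.")
  }
  structure(list(
    n_events = as.integer(n_events), m = m, theta_range = theta_range,
    log10_alpha_range = log10_alpha_range,
    log10_sigma_sq_range = log10_sigma_sq_range, t_ds_range = t_ds_range,
    class_proportions = class_proportions, bounds = bounds,
    max_attempts = max_attempts, noise_sd = noise_sd, scenario = scenario,
    theta0_range = theta0_range, param_sharing = param_sharing
  ), class = "oudel_sim_config")
}

#' @export
print.oudel_sim_config <- function(x, ...) {
  cat("<oudel_sim_config>\n")
  cat(sprintf("  events: %d  conditions: %d  scenario: %s\n",
              x$n_events, x$m, x$scenario))
  cat(sprintf("  theta ~ U[%g, %g]; log10(alpha) ~ U[%g, %g]; log10(sigma_sq) ~ U[%g, %g]\n",
              x$theta_range[1], x$theta_range[2],
              x$log10_alpha_range[1], x$log10_alpha_range[2],
              x$log10_sigma_sq_range[1], x$log10_sigma_sq_range[2]))
  cat(sprintf("  class proportions: redundant %.2f / unique %.2f\n",
              x$class_proportions[1], x$class_proportions[2]))
  invisible(x)
}

#' Draw the generative OU parameters of one event
#'
#' Per condition: `theta1 ~ U(theta_range)`; `theta2 = theta1` for the
#' redundant class, otherwise an independent uniform draw;
#' `alpha = 10^U(log10_alpha_range)`; `sigma_sq = 10^U(log10_sigma_sq_range)`.
#' One divergence time `t_ds ~ U(t_ds_range)` is shared across the event's
#' conditions (there is a single gene tree per event).
#'
#' @param config An [sim_config()] object.
#' @param label `"redundant"` or `"unique"`.
#' @param seed Optional integer seed.
#' @return A list with elements `conditions` (a tibble with one row per
#'   condition: `theta1`, `theta2`, `alpha`, `sigma_sq`, and `theta0` in the
#'   theta0 scenario), `t_ds`, and `label`.
#' @export
draw_event_params <- function(config, label = c("redundant", "unique"),
                              seed = NULL) {
  label <- match.arg(label)
  with_seed(seed, {
    m <- config$m
    nd <- if (identical(config$param_sharing, "event")) 1L else m
    rep_m <- function(v) rep_len(v, m)
    theta1 <- rep_m(runif(nd, config$theta_range[1], config$theta_range[2]))
    theta2 <- if (label == "redundant") theta1 else {
      rep_m(runif(nd, config$theta_range[1], config$theta_range[2]))
    }
    cond <- tibble(
      condition = seq_len(m), theta1 = theta1, theta2 = theta2,
      alpha = rep_m(10^runif(nd, config$log10_alpha_range[1],
                             config$log10_alpha_range[2])),
      sigma_sq = rep_m(10^runif(nd, config$log10_sigma_sq_range[1],
                                config$log10_sigma_sq_range[2]))
    )
    if (config$scenario == "theta0") {
      cond$theta0 <- runif(m, config$theta0_range[1], config$theta0_range[2])
    }
    list(conditions = cond,
         t_ds = runif(1, config$t_ds_range[1], config$t_ds_range[2]),
         label = label)
  })
}

# Vectorised batch of candidate events: draws `n_cand` full events and their
# expression, returns everything flat; acceptance is decided by the caller.
draw_candidates <- function(config, label, n_cand) {
  m <- config$m
  nm <- n_cand * m
  if (identical(config$param_sharing, "event")) {
    # one parameter set per event, replicated across its m conditions
    expand <- function(v) rep(v, each = m)
    theta1 <- expand(runif(n_cand, config$theta_range[1], config$theta_range[2]))
    theta2 <- if (label == "redundant") theta1 else {
      expand(runif(n_cand, config$theta_range[1], config$theta_range[2]))
    }
    alpha <- expand(10^runif(n_cand, config$log10_alpha_range[1],
                             config$log10_alpha_range[2]))
    sigma_sq <- expand(10^runif(n_cand, config$log10_sigma_sq_range[1],
                                config$log10_sigma_sq_range[2]))
  } else {
    theta1 <- runif(nm, config$theta_range[1], config$theta_range[2])
    theta2 <- if (label == "redundant") theta1 else {
      runif(nm, config$theta_range[1], config$theta_range[2])
    }
    alpha <- 10^runif(nm, config$log10_alpha_range[1], config$log10_alpha_range[2])
    sigma_sq <- 10^runif(nm, config$log10_sigma_sq_range[1],
                         config$log10_sigma_sq_range[2])
  }
  t_ds_event <- runif(n_cand, config$t_ds_range[1], config$t_ds_range[2])
  t_ds <- rep(t_ds_event, each = m)

  if (config$scenario == "theta0") {
    theta0 <- runif(nm, config$theta0_range[1], config$theta0_range[2])
    mu <- ou_mean_theta0(theta0, theta1, theta2, alpha)
  } else {
    theta0 <- NULL
    w <- exp(-alpha * t_ds)
    mu_ds <- (1 - w) * theta1 + w * theta2
    mu <- cbind(mu_ds, mu_ds, theta2)
  }

  # closed-form Cholesky of the structured correlation matrix, scaled by the
  # stationary standard deviation; stable parameterisation of L32 avoids
  # 0/0 as t_ds -> 0
  sv <- sqrt(sigma_sq / (2 * alpha))
  r <- exp(-2 * alpha * t_ds)
  b <- exp(-2 * alpha)
  l22 <- sqrt(pmax(1 - r^2, 0))
  l32 <- b * sqrt(pmax((1 - r) / (1 + r), 0))
  l33 <- sqrt(pmax(1 - b^2 - l32^2, 0))
  z1 <- rnorm(nm); z2 <- rnorm(nm); z3 <- rnorm(nm)
  e_d <- mu[, 1L] + sv * z1
  e_s <- mu[, 2L] + sv * (r * z1 + l22 * z2)
  e_l <- mu[, 3L] + sv * (b * z1 + l32 * z2 + l33 * z3)

  lo <- rep(config$bounds[, 1L], times = n_cand)
  hi <- rep(config$bounds[, 2L], times = n_cand)
  ok_cond <- e_d >= lo & e_d <= hi & e_s >= lo & e_s <= hi &
    e_l >= lo & e_l <= hi
  accept <- as.logical(
    tapply(ok_cond, rep(seq_len(n_cand), each = m), all))

  list(theta1 = theta1, theta2 = theta2, alpha = alpha, sigma_sq = sigma_sq,
       theta0 = theta0, t_ds_event = t_ds_event,
       e_d = e_d, e_s = e_s, e_l = e_l, accept = accept)
}

# Accepted-event harvest for one class; errors when the per-event attempt
# budget is exhausted.
sim_class_events <- function(config, label, n_needed) {
  m <- config$m
  got <- 0L
  attempts <- 0
  chunks <- list()
  rate <- 0.5  # running acceptance-rate estimate for chunk sizing
  while (got < n_needed) {
    budget_left <- config$max_attempts * n_needed - attempts
    if (budget_left <= 0) {
      bad <- paste(sprintf("[%g, %g]", config$bounds[, 1], config$bounds[, 2]),
                   collapse = ", ")
      abort(sprintf(paste0(
        "Rejection sampling exhausted %g attempts for %d '%s' events; ",
        "acceptance bounds per condition: %s."),
        attempts, n_needed, label, bad),
        class = "oudel_rejection_exhausted")
    }
    n_cand <- min(max(ceiling((n_needed - got) / max(rate, 1e-3)), 64L),
                  200000L, budget_left)
    cand <- draw_candidates(config, label, n_cand)
    attempts <- attempts + n_cand
    rate <- max((got + sum(cand$accept)) / attempts, 1e-4)
    keep_ev <- which(cand$accept)
    if (got + length(keep_ev) > n_needed) {
      keep_ev <- keep_ev[seq_len(n_needed - got)]
    }
    if (length(keep_ev)) {
      keep_cond <- rep((keep_ev - 1L) * m, each = m) + seq_len(m)
      chunks[[length(chunks) + 1L]] <- list(
        theta1 = cand$theta1[keep_cond], theta2 = cand$theta2[keep_cond],
        alpha = cand$alpha[keep_cond], sigma_sq = cand$sigma_sq[keep_cond],
        theta0 = cand$theta0[keep_cond], t_ds = cand$t_ds_event[keep_ev],
        e_d = cand$e_d[keep_cond], e_s = cand$e_s[keep_cond],
        e_l = cand$e_l[keep_cond])
      got <- got + length(keep_ev)
    }
  }
  out <- list()
  for (f in c("theta1", "theta2", "alpha", "sigma_sq", "theta0", "t_ds",
              "e_d", "e_s", "e_l")) {
    out[[f]] <- unlist(lapply(chunks, `[[`, f), use.names = FALSE)
  }
  out$label <- label
  out$n <- as.integer(n_needed)
  out
}

#' Simulate one deletion event under rejection sampling
#'
#' Repeatedly draws event parameters and expression until all `3 * m` values
#' fall within the configured per-condition bounds; both parameters and
#' expression are redrawn on every attempt.
#'
#' @inheritParams draw_event_params
#' @return A list with `features` (named length-`3m` vector in the
#'   [event_features()] layout), `target` (named length-`3m` vector of
#'   per-condition `theta1`, `theta2`, `log10sv`), and `params` (as
#'   [draw_event_params()]).
#' @export
simulate_event <- function(config, label = c("redundant", "unique"),
                           seed = NULL) {
  label <- match.arg(label)
  ev <- with_seed(seed, sim_class_events(config, label, 1L))
  triples <- cbind(ev$e_d, ev$e_s, ev$e_l)
  target <- as.vector(t(cbind(ev$theta1, ev$theta2,
                              stationary_variance_log10(ev$sigma_sq, ev$alpha))))
  names(target) <- target_names(config$m)
  cond <- tibble(condition = seq_len(config$m), theta1 = ev$theta1,
                 theta2 = ev$theta2, alpha = ev$alpha, sigma_sq = ev$sigma_sq)
  if (!is.null(ev$theta0)) cond$theta0 <- ev$theta0
  list(features = event_features(triples), target = target,
       params = list(conditions = cond, t_ds = ev$t_ds, label = label))
}

#' Simulate a labelled deletion-event dataset
#'
#' Generates `n_events` events with class counts matching
#' `class_proportions` (largest-remainder rounding), shuffles the rows, and
#' returns features, labels, regression targets and the full generative truth
#' in one object.
#'
#' @inheritParams draw_event_params
#' @param config An [sim_config()] object (or arguments forwarded to it via
#'   `...`).
#' @param ... Overrides forwarded to [sim_config()] when `config` is `NULL`.
#' @return An object of class `oudel_sim`: a list with
#'   \describe{
#'     \item{data}{tibble with `event_id`, `class`, the `3m` feature columns
#'       `eD_k`/`eS_k`/`eL_k`, and the `3m` target columns `theta1_k`/
#'       `theta2_k`/`log10sv_k`;}
#'     \item{params}{long tibble of the generating parameters, one row per
#'       event x condition;}
#'     \item{config, seed}{provenance.}
#'   }
#' @examples
#' sim <- simulate_deletion_data(n_events = 20, seed = 1)
#' dplyr::count(sim$data, class)
#' @export
simulate_deletion_data <- function(config = NULL, seed = NULL, ...) {
  if (is.null(config)) config <- sim_config(...)
  if (!inherits(config, "oudel_sim_config")) {
    stop_invalid("`config` must come from sim_config().")
  }
  n <- config$n_events
  # largest-remainder apportionment of the two classes
  raw <- config$class_proportions * n
  n_red <- floor(raw[["redundant"]])
  n_uni <- floor(raw[["unique"]])
  left <- n - n_red - n_uni
  if (left > 0) {
    frac <- raw - floor(raw)
    extra <- order(frac, decreasing = TRUE)[seq_len(left)]
    for (i in extra) if (names(raw)[i] == "redundant") n_red <- n_red + 1L else n_uni <- n_uni + 1L
  }

  with_seed(seed, {
    parts <- Filter(function(p) p$n > 0L,
                    list(sim_class_events(config, "redundant", n_red),
                         sim_class_events(config, "unique", n_uni)))
    perm <- sample.int(n)
    build_sim_object(config, parts, perm, seed)
  })
}

build_sim_object <- function(config, parts, perm, seed) {
  m <- config$m
  n <- sum(vapply(parts, `[[`, integer(1), "n"))
  pull <- function(f) unlist(lapply(parts, `[[`, f), use.names = FALSE)
  theta1 <- pull("theta1"); theta2 <- pull("theta2")
  alpha <- pull("alpha"); sigma_sq <- pull("sigma_sq")
  theta0 <- pull("theta0")
  e_d <- pull("e_d"); e_s <- pull("e_s"); e_l <- pull("e_l")
  t_ds <- pull("t_ds")
  class_vec <- rep(vapply(parts, `[[`, character(1), "label"),
                   vapply(parts, `[[`, integer(1), "n"))

  # condition-major flattening: row k of `wide` interleaves (eD, eS, eL) and
  # (theta1, theta2, log10sv) per condition
  interleave <- function(a, b, c3) {
    out <- matrix(NA_real_, n, 3L * m)
    out[, seq(1L, 3L * m, by = 3L)] <- matrix(a, n, m, byrow = TRUE)
    out[, seq(2L, 3L * m, by = 3L)] <- matrix(b, n, m, byrow = TRUE)
    out[, seq(3L, 3L * m, by = 3L)] <- matrix(c3, n, m, byrow = TRUE)
    out
  }
  feats <- interleave(e_d, e_s, e_l)
  colnames(feats) <- feature_names(m)
  targs <- interleave(theta1, theta2,
                      stationary_variance_log10(sigma_sq, alpha))
  colnames(targs) <- target_names(m)

  if (config$noise_sd > 0) {
    feats <- feats + rnorm(length(feats), 0, config$noise_sd)
  }

  event_id <- sprintf("ev%05d", seq_len(n))
  data <- as_tibble(cbind(as.data.frame(feats), as.data.frame(targs)))
  data <- dplyr::bind_cols(tibble(event_id = event_id, class = class_vec), data)
  params <- tibble(
    event_id = rep(event_id, each = m),
    class = rep(class_vec, each = m),
    t_ds = rep(t_ds, each = m),
    condition = rep(seq_len(m), times = n),
    theta1 = theta1, theta2 = theta2, alpha = alpha, sigma_sq = sigma_sq)
  if (!is.null(theta0) && length(theta0)) params$theta0 <- theta0

  data <- data[perm, , drop = FALSE]
  structure(list(data = data, params = params, config = config, seed = seed),
            class = "oudel_sim")
}

#' @export
print.oudel_sim <- function(x, ...) {
  cat(sprintf("<oudel_sim> %d events, m = %d conditions (%s scenario)\n",
              nrow(x$data), x$config$m, x$config$scenario))
  print(dplyr::count(x$data, .data$class))
  invisible(x)
}

# Column accessors shared across modules -------------------------------------

sim_feature_cols <- function(data) {
  grep("^e[DSL]_\\d+$", names(data), value = TRUE)
}

sim_target_cols <- function(data) {
  grep("^(theta1|theta2|log10sv)_\\d+$", names(data), value = TRUE)
}

# Feature matrix in canonical layout from a sim object or plain data frame.
feature_matrix <- function(data) {
  if (inherits(data, "oudel_sim")) data <- data$data
  cols <- sim_feature_cols(data)
  if (!length(cols)) stop_invalid("No feature columns (eD_k/eS_k/eL_k) found.")
  m <- length(cols) / 3L
  as.matrix(data[, feature_names(m), drop = FALSE])
}

target_matrix <- function(data) {
  if (inherits(data, "oudel_sim")) data <- data$data
  cols <- sim_target_cols(data)
  if (!length(cols)) stop_invalid("No target columns (theta1_k/...) found.")
  m <- length(cols) / 3L
  as.matrix(data[, target_names(m), drop = FALSE])
}

#' Add measurement noise to a simulated dataset
#'
#' Adds independent `N(0, sd^2)` noise to every feature value, leaving labels
#' and regression targets untouched.  Used to emulate expression measured at
#' shallower sequencing depth.
#'
#' @param x An `oudel_sim` object or a data frame with feature columns.
#' @param sd Noise standard deviation (>= 0).
#' @param seed Optional integer seed.
#' @return An object of the same type as `x` with perturbed features.
#' @export
add_expression_noise <- function(x, sd, seed = NULL) {
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd < 0) {
    stop_invalid("`sd` must be a single non-negative number.")
  }
  data <- if (inherits(x, "oudel_sim")) x$data else x
  cols <- sim_feature_cols(data)
  if (sd > 0) {
    noise <- with_seed(seed, rnorm(nrow(data) * length(cols), 0, sd))
    data[cols] <- data[cols] + matrix(noise, nrow(data), length(cols))
  }
  if (inherits(x, "oudel_sim")) {
    x$data <- data
    x
  } else {
    data
  }
}

# TSV persistence -------------------------------------------------------------

fmt17 <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(col) sprintf("%.17g", col))
  df
}

#' Write / read a simulated dataset as tab-separated files
#'
#' Writes `<prefix>_features.tsv` (`event_id` + feature columns),
#' `<prefix>_labels.tsv` (`event_id`, `class`), `<prefix>_targets.tsv`
#' (`event_id` + target columns) and a `<prefix>_provenance.json` sidecar
#' holding the configuration and seed.  Numeric values are written with 17
#' significant digits so the round-trip is bit-exact.
#'
#' @param x An `oudel_sim` object.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_sim_dataset <- function(x, dir, prefix = "sim") {
  if (!inherits(x, "oudel_sim")) stop_invalid("`x` must be an oudel_sim.")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fcols <- sim_feature_cols(x$data)
  tcols <- sim_target_cols(x$data)
  paths <- file.path(dir, paste0(prefix, c("_features.tsv", "_labels.tsv",
                                           "_targets.tsv", "_provenance.json")))
  wr <- function(df, path) {
    write.table(fmt17(as.data.frame(df)), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wr(x$data[, c("event_id", fcols)], paths[1])
  write.table(as.data.frame(x$data[, c("event_id", "class")]), paths[2],
              sep = "\t", quote = FALSE, row.names = FALSE)
  wr(x$data[, c("event_id", tcols)], paths[3])
  cfg <- x$config
  cfg$bounds <- unclass(cfg$bounds)
  jsonlite::write_json(list(config = unclass(cfg), seed = x$seed), paths[4],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @rdname write_sim_dataset
#' @param dir Directory holding the files written by [write_sim_dataset()].
#' @export
read_sim_dataset <- function(dir, prefix = "sim") {
  paths <- file.path(dir, paste0(prefix, c("_features.tsv", "_labels.tsv",
                                           "_targets.tsv", "_provenance.json")))
  if (!all(file.exists(paths[1:3]))) {
    stop_invalid(sprintf("Dataset files with prefix '%s' not found in %s.",
                         prefix, dir))
  }
  feats <- as_tibble(read.delim(paths[1], check.names = FALSE))
  labs <- as_tibble(read.delim(paths[2], check.names = FALSE))
  targs <- as_tibble(read.delim(paths[3], check.names = FALSE))
  data <- dplyr::inner_join(labs, feats, by = "event_id")
  data <- dplyr::inner_join(data, targs, by = "event_id")
  prov <- if (file.exists(paths[4])) jsonlite::read_json(paths[4]) else NULL
  config <- NULL
  if (!is.null(prov)) {
    cf <- prov$config
    config <- sim_config(
      n_events = cf$n_events, m = cf$m,
      theta_range = unlist(cf$theta_range),
      log10_alpha_range = unlist(cf$log10_alpha_range),
      log10_sigma_sq_range = unlist(cf$log10_sigma_sq_range),
      t_ds_range = unlist(cf$t_ds_range),
      class_proportions = setNames(unlist(cf$class_proportions),
                                   c("redundant", "unique")),
      bounds = matrix(unlist(cf$bounds), ncol = 2L),
      max_attempts = cf$max_attempts, noise_sd = cf$noise_sd,
      scenario = cf$scenario, theta0_range = unlist(cf$theta0_range),
      param_sharing = cf$param_sharing %||% "condition")
  }
  structure(list(data = data, params = NULL, config = config,
                 seed = prov$seed), class = "oudel_sim")
}
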