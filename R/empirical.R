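# Applying trained predictors to empirical deletion-event expression tables
# and the downstream statistics: exact binomial tests on annotation
# proportions, rank tests on predicted parameters, and a back-simulation
# consistency check of predicted parameters against the observed expression.

#' Read an empirical deletion-event expression table
#'
#' Expects a tab-separated file with columns `event_id`, `lineage`,
#' `gene_D`, `gene_S`, `gene_L`, followed by the `3m` expression columns
#' `eD_1, eS_1, eL_1, ..., eD_m, eS_m, eL_m` (log-transformed normalised
#' expression, e.g. log quantile-normalised FPKM).
#'
#' @param path Path to the file.
#' @return A tibble validated for schema and finiteness.
#' @export
read_empirical_table <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("File not found: %s", path))
  df <- as_tibble(read.delim(path, check.names = FALSE))
  meta <- c("event_id", "lineage", "gene_D", "gene_S", "gene_L")
  missing_meta <- setdiff(meta, names(df))
  if (length(missing_meta)) {
    stop_invalid(sprintf("Missing required column(s): %s.",
                         paste(missing_meta, collapse = ", ")))
  }
  expr_cols <- sim_feature_cols(df)
  if (!length(expr_cols)) {
    stop_invalid("Expression columns eD_k/eS_k/eL_k missing or incomplete.")
  }
  m <- max(as.integer(sub("^e[DSL]_", "", expr_cols)))
  expected <- feature_names(m)
  missing_expr <- setdiff(expected, names(df))
  if (length(missing_expr)) {
    stop_invalid(sprintf("Missing expression column(s): %s.",
                         paste(missing_expr, collapse = ", ")))
  }
  X <- df[, expected]
  bad_col <- names(X)[!vapply(X, is.numeric, logical(1))]
  if (length(bad_col)) {
    stop_invalid(sprintf("Non-numeric expression column(s): %s.",
                         paste(bad_col, collapse = ", ")))
  }
  bad_row <- which(!complete.cases(X) | rowSums(!is.finite(as.matrix(X))) > 0)
  if (length(bad_row)) {
    stop_invalid(sprintf("Non-finite expression values in row(s): %s.",
                         paste(df$event_id[bad_row], collapse = ", ")))
  }
  df[, c(meta, expected)]
}

#' Write an empirical table (round-trips with [read_empirical_table()])
#' @param table A tibble in the empirical layout.
#' @param path Output path.
#' @export
write_empirical_table <- function(table, path) {
  write.table(fmt17(as.data.frame(table)), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Two-sided exact binomial test
#'
#' Exact binomial test of `x` successes in `n` trials against success
#' probability `p0`, two-sided by the point-probability summation convention
#' (all outcomes no more probable than the observed one contribute).
#'
#' @param x Observed successes.
#' @param n Trials.
#' @param p0 Null success probability.
#' @return The two-sided p-value.
#' @examples
#' exact_binomial_test(11, 46, 0.39)
#' @export
exact_binomial_test <- function(x, n, p0) {
  if (any(x < 0) || any(x > n) || p0 < 0 || p0 > 1) {
    stop_invalid("Need 0 <= x <= n and p0 in [0, 1].")
  }
  as.numeric(binom.test(x, n, p = p0)$p.value)
}

#' Exact binomial tests on user-supplied lineage/annotation proportions
#'
#' Convenience wrapper running one exact binomial test per row of a
#' specification table, e.g. comparing the proportion of lethal-phenotype
#' lost genes against a genome-wide proportion.
#'
#' @param specs A data frame with columns `x`, `n`, `p0` and optionally
#'   `test`.
#' @return `specs` with an added `p_value` column.
#' @export
lineage_proportion_tests <- function(specs) {
  if (!all(c("x", "n", "p0") %in% names(specs))) {
    stop_invalid("`specs` needs columns x, n, p0.")
  }
  specs <- as_tibble(specs)
  specs$p_value <- vapply(seq_len(nrow(specs)), function(i) {
    exact_binomial_test(specs$x[i], specs$n[i], specs$p0[i])
  }, numeric(1))
  specs
}

#' Classify empirical events and summarise predicted parameters
#'
#' Applies a trained classifier and regressor to an empirical table, pools
#' the per-condition parameter estimates, and runs the class-contrast rank
#' tests: a two-sample location test of `|theta1 - theta2|` between classes,
#' and a one-sample signed-rank test of `log10sv` against zero per class.
#'
#' @param classifier Classification `oudel_predictor`.
#' @param regressor Regression `oudel_predictor` with matching `m`.
#' @param table Tibble from [read_empirical_table()] (or an `oudel_sim` for
#'   simulated panels).
#' @return A list with
#'   \describe{
#'     \item{events}{per-event tibble: `event_id`, `label`, `p_unique`, and
#'       the 3m parameter estimates;}
#'     \item{estimates}{long tibble of per-condition estimates with
#'       `abs_dtheta` and `log10sv`;}
#'     \item{tests}{tibble of the rank-test results.}
#'   }
#' @export
class_and_param_summary <- function(classifier, regressor, table) {
  if (classifier$m != regressor$m) {
    stop_invalid("Classifier and regressor disagree on the number of conditions.")
  }
  df <- if (inherits(table, "oudel_sim")) table$data else table
  prob <- predict(classifier, df, type = "prob")[, "unique"]
  label <- CLASS_LEVELS[(prob >= 0.5) + 1L]
  params <- predict(regressor, df, type = "params")
  ids <- if ("event_id" %in% names(df)) df$event_id else sprintf("ev%05d", seq_along(prob))
  events <- dplyr::bind_cols(
    tibble(event_id = ids, label = label, p_unique = prob),
    as_tibble(as.data.frame(params)))

  m <- regressor$m
  long <- tibble(
    event_id = rep(ids, each = m),
    label = rep(label, each = m),
    condition = rep(seq_len(m), times = length(ids)),
    theta1 = as.vector(t(params[, seq(1, 3 * m, by = 3), drop = FALSE])),
    theta2 = as.vector(t(params[, seq(2, 3 * m, by = 3), drop = FALSE])),
    log10sv = as.vector(t(params[, seq(3, 3 * m, by = 3), drop = FALSE])))
  long$abs_dtheta <- abs(long$theta1 - long$theta2)

  tests <- list()
  if (length(unique(label)) == 2L) {
    wt <- wilcox.test(abs_dtheta ~ label, data = long, exact = FALSE)
    tests[[1]] <- tibble(
      test = "abs_dtheta_unique_vs_redundant",
      statistic = unname(wt$statistic), p_value = wt$p.value)
  }
  for (cl in intersect(CLASS_LEVELS, unique(label))) {
    v <- long$log10sv[long$label == cl]
    st <- wilcox.test(v, mu = 0, exact = FALSE)
    tests[[length(tests) + 1L]] <- tibble(
      test = paste0("log10sv_vs_zero_", cl),
      statistic = unname(st$statistic), p_value = st$p.value)
  }
  list(events = events, estimates = long, tests = dplyr::bind_rows(tests))
}

#' Back-simulation consistency check of empirical predictions
#'
#' For each event, the predicted stationary variance pins only the ratio
#' `sigma_sq / (2 * alpha)`, so `log10(alpha)` is drawn uniformly on
#' \[0, 3\] `n_draws` times, `sigma_sq = 2 * alpha * 10^log10sv` recovered,
#' and expression re-simulated with the event's predicted optima (divergence
#' time drawn uniformly per draw).  Simulated and observed expression are
#' compared per gene role by a two-sample rank test, with and without
#' removing values below the low-expression threshold
#' `log10(2)` (i.e. FPKM < 1 on a log10(1 + FPKM) scale).
#'
#' @param events Per-event predictions (the `events` element of
#'   [class_and_param_summary()]).
#' @param table The empirical table the predictions came from.
#' @param n_draws Simulated draws per event.
#' @param log10_alpha_range Range of the uniform `log10(alpha)` draw.
#' @param threshold Low-expression filter threshold on the expression scale.
#' @param seed Optional integer seed.
#' @return A list with `panel` (long tibble of simulated values: `event_id`,
#'   `draw`, `condition`, `role`, `value`, plus `alpha`, `sigma_sq`),
#'   `comparisons` (per-role rank tests, filtered and unfiltered), and
#'   `n_observations` (events x draws).
#' @export
back_simulate_check <- function(events, table, n_draws = 200L,
                                log10_alpha_range = c(0, 3),
                                threshold = log10(2), seed = NULL) {
  if (!all(c("event_id", "p_unique") %in% names(events))) {
    stop_invalid("`events` must come from class_and_param_summary().")
  }
  df <- if (inherits(table, "oudel_sim")) table$data else table
  pcols <- grep("^(theta1|theta2|log10sv)_\\d+$", names(events), value = TRUE)
  if (!length(pcols)) stop_invalid("`events` carries no parameter estimates.")
  m <- length(pcols) / 3L
  emp <- feature_matrix(df)

  with_seed(seed, {
    rows <- vector("list", nrow(events))
    for (i in seq_len(nrow(events))) {
      th1 <- as.numeric(events[i, paste0("theta1_", seq_len(m))])
      th2 <- as.numeric(events[i, paste0("theta2_", seq_len(m))])
      lsv <- as.numeric(events[i, paste0("log10sv_", seq_len(m))])
      la <- runif(n_draws, log10_alpha_range[1], log10_alpha_range[2])
      alpha <- 10^la
      t_ds <- runif(n_draws)
      # per condition x draw
      alpha_f <- rep(alpha, times = m)
      sv_f <- 10^rep(lsv, each = n_draws)
      sigma_sq_f <- 2 * alpha_f * sv_f
      t_ds_f <- rep(t_ds, times = m)
      th1_f <- rep(th1, each = n_draws)
      th2_f <- rep(th2, each = n_draws)
      w <- exp(-alpha_f * t_ds_f)
      mu_ds <- (1 - w) * th1_f + w * th2_f
      sd_st <- sqrt(sv_f)
      r <- exp(-2 * alpha_f * t_ds_f)
      b <- exp(-2 * alpha_f)
      l22 <- sqrt(pmax(1 - r^2, 0))
      l32 <- b * sqrt(pmax((1 - r) / (1 + r), 0))
      l33 <- sqrt(pmax(1 - b^2 - l32^2, 0))
      nmf <- n_draws * m
      z1 <- rnorm(nmf); z2 <- rnorm(nmf); z3 <- rnorm(nmf)
      rows[[i]] <- tibble(
        event_id = events$event_id[i],
        draw = rep(seq_len(n_draws), times = m),
        condition = rep(seq_len(m), each = n_draws),
        alpha = alpha_f, sigma_sq = sigma_sq_f,
        e_D = mu_ds + sd_st * z1,
        e_S = mu_ds + sd_st * (r * z1 + l22 * z2),
        e_L = th2_f + sd_st * (b * z1 + l32 * z2 + l33 * z3))
    }
    panel <- dplyr::bind_rows(rows)
    panel_long <- tidyr::pivot_longer(panel, c("e_D", "e_S", "e_L"),
                                      names_to = "role", values_to = "value")
    panel_long$role <- sub("^e_", "", panel_long$role)

    emp_long <- tibble(
      role = rep(rep(GENE_ROLES, times = m), each = nrow(emp)),
      value = as.vector(emp))

    cmp <- list()
    for (filt in c(FALSE, TRUE)) {
      for (role in GENE_ROLES) {
        sim_v <- panel_long$value[panel_long$role == role]
        emp_v <- emp_long$value[emp_long$role == role]
        if (filt) {
          sim_v <- sim_v[sim_v >= threshold]
          emp_v <- emp_v[emp_v >= threshold]
        }
        wt <- wilcox.test(sim_v, emp_v, exact = FALSE)
        cmp[[length(cmp) + 1L]] <- tibble(
          role = role, filtered = filt,
          n_sim = length(sim_v), n_emp = length(emp_v),
          statistic = unname(wt$statistic), p_value = wt$p.value)
      }
    }
    list(panel = panel_long,
         comparisons = dplyr::bind_rows(cmp),
         n_observations = nrow(events) * n_draws)
  })
}
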