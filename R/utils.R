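#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm runif optim predict pchisq binom.test wilcox.test
#'   median quantile sd var complete.cases setNames
#' @importFrom utils head modifyList read.delim write.table
NULL

# error constructors ---------------------------------------------------------

stop_invalid <- function(msg, ...) {
  abort(msg, class = "oudel_invalid_input", ...)
}

stop_numerical <- function(msg, ...) {
  abort(msg, class = "oudel_numerical", ...)
}

check_scalar_finite <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(sprintf("`%s` must be a single finite numeric value.", name))
  }
  invisible(x)
}

check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop_invalid(sprintf("`%s` must be strictly positive and finite.", name))
  }
  invisible(x)
}

# seed handling: every stochastic entry point takes an optional integer seed
# and restores the caller's RNG state on exit.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_invalid("`seed` must be a single integer.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive distinct child seeds from one master seed (kept below 2^31)
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 101 + as.numeric(k) * 7919) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
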