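#' @keywords internal
#' @useDynLib pulseguard, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

# Input validation helpers shared across modules. Error classes are stable so
# callers (and the CLI) can condition on them.

pg_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "pulseguard_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    pg_stop("pg_config_error", "`%s` must be a single finite number", name)
  }
  if (integer && x != round(x)) {
    pg_stop("pg_config_error", "`%s` must be an integer, got %s", name, x)
  }
  if (x < lower || x > upper) {
    pg_stop("pg_config_error", "`%s` must be in [%s, %s], got %s",
            name, lower, upper, x)
  }
  invisible(x)
}

check_range_pair <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)) || x[1] > x[2]) {
    pg_stop("pg_config_error",
            "`%s` must be a (min, max) pair with min <= max", name)
  }
  invisible(x)
}

# Deterministic sub-seed derivation: one root seed spawns independent stream
# seeds so per-subject records are order-independent. Values stay < 2^31.
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  sample.int(.Machine$integer.max - 1L, n)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
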