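#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not disturb the global random stream.
#' With `seed = NULL` the expression runs against the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_carollia <- function(..., call. = FALSE) {
  stop(..., call. = call.)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_carollia(sprintf("`%s` must be a single finite number", name))
  }
  if (x < lower || x > upper) {
    stop_carollia(sprintf("`%s` must be in [%g, %g]", name, lower, upper))
  }
  invisible(x)
}

#' Derive a stream of child seeds from one master seed
#'
#' Deterministic arithmetic (no RNG use), keeping each child below 2^31.
#' @keywords internal
#' @noRd
child_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  ((as.double(seed) * 48271 + 1000003 * seq_len(n)) %% 2147483629) + 1
}
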