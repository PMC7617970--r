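# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the R generator with `seed`, evaluates `expr`, and restores the
#' caller's RNG state so that library code never perturbs user-level
#' randomness. If `seed` is NULL the expression runs on the current stream.
#'
#' @param seed integer seed or NULL.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_rng <- function(seed, expr) {
  if (!is.null(seed)) {
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = genv)
      } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

#' Deterministic sub-stream seed
#'
#' Fans one master seed out to named sub-streams so that independent
#' operations (and iterations within an operation) draw from independent but
#' fully reproducible streams. Values stay below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param stream character stream label.
#' @param index optional iteration index within the stream.
#' @return an integer seed.
#' @export
#' @examples
#' sub_seed(7, "partition", 3)
sub_seed <- function(seed, stream, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  chars <- utf8ToInt(as.character(stream))
  h <- sum(chars * seq_along(chars)) %% 65521
  val <- (abs(as.numeric(seed)) * 48271 + h * 7919 + as.numeric(index) * 104729) %%
    2147483587
  as.integer(val) + 1L
}

# Validate a probability-like scalar/vector.
check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

check_positive_count <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 1) || any(x != floor(x))) {
    stop(sprintf("`%s` must be a positive integer", name), call. = FALSE)
  }
  invisible(x)
}

# Dense-or-sparse friendly accessors used throughout.
mat_values <- function(x) {
  if (methods::is(x, "sparseMatrix")) x@x else as.vector(x)
}
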