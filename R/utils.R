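# internal helpers

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
# seed = NULL leaves the global RNG stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage sub-seed; stays within 32-bit integer range.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + stage * 1000003) %% 2147483647)
}

stop_if_not_finite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop(sprintf("'%s' must be finite numeric", what), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
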