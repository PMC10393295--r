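# internal helpers shared across modules

# evaluate `expr` under a temporary RNG state seeded with `seed`;
# NULL seed leaves the global RNG alone
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive a stream of child seeds from a master seed (kept below 2^31)
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_lamcsd <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "lamcsd_error")))
}

invalid_argument <- function(msg) stop_lamcsd(msg, "lamcsd_invalid_argument")
degenerate_pattern <- function(msg) stop_lamcsd(msg, "lamcsd_degenerate_pattern")
numerical_failure <- function(msg) stop_lamcsd(msg, "lamcsd_numerical_failure")

is_strictly_monotone <- function(x) {
  d <- diff(x)
  all(d > 0) || all(d < 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
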