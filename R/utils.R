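#' @importFrom rlang abort warn .data
#' @importFrom stats rbeta rbinom rnorm runif sd var quantile pchisq pt pnorm
#'   setNames coef
#' @importFrom utils head tail
NULL

# Deterministic 31-bit seed mixer: derives independent sub-seeds from a global
# seed plus stream labels (client index, round, ...). Plain integer arithmetic
# mod the Mersenne prime 2^31 - 1 keeps every derived seed a valid R seed.
mix_seed <- function(seed, ...) {
  m <- 2147483647
  h <- as.double(seed %% m)
  for (x in c(...)) {
    h <- (h * 48271 + as.double(x) + 11) %% m
  }
  as.integer(h)
}

# Evaluate an expression under a local RNG state; global RNG untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
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
  set.seed(seed)
  expr
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be an integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
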