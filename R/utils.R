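`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with a local RNG state seeded from `seed`, restoring the
# caller's state afterwards. All stochastic code in the package funnels
# through this so that one integer seed reproduces a run exactly.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# error with a package-specific condition class so callers can catch
# distinct failure modes
stopTyped <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "ecmscreen_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Geometric mean
#'
#' @param x strictly positive numeric vector.
#' @return `exp(mean(log(x)))`.
#' @export
geometricMean <- function(x) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x)) || any(x <= 0))
    stop("geometricMean() requires a strictly positive numeric vector")
  exp(mean(log(x)))
}

# is x a whole-number-valued numeric matrix?
isCountMatrix <- function(x) {
  is.matrix(x) && is.numeric(x) && all(is.finite(x)) &&
    all(x == floor(x)) && all(x >= 0)
}
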