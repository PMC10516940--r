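#' @importFrom stats rnorm rexp rbinom rpois optimize quantile qnorm dist
#'   hclust cutree setNames
#' @importFrom methods new validObject is slot
#' @importFrom utils head tail read.delim write.table packageVersion
NULL

## Row-wise numerically stable softmax.
softmaxRows <- function(x) {
  stopifnot(is.matrix(x))
  if (nrow(x) == 0L) return(x)
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the caller's RNG state so
#' that seeded package operations never perturb the global random stream.
#'
#' @param seed Single integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single non-missing integer")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a child seed from a root seed
#'
#' Deterministic stream splitting: one root seed per run, one child stream per
#' module or grid point. Uses a Lehmer step modulo the Mersenne prime 2^31 - 1,
#' so derived seeds always fit a 32-bit integer.
#'
#' @param seed Root integer seed.
#' @param stream Non-negative integer stream index.
#' @return A single integer seed.
#' @export
childSeed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, length(stream) == 1L, stream >= 0)
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + stream + 1) %% 2147483647)
}

## Internal: validate a probability-like scalar.
checkFraction <- function(x, name, lower = 0, upper = 1,
                          openLower = FALSE, openUpper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single number", name))
  }
  lo <- if (openLower) x > lower else x >= lower
  hi <- if (openUpper) x < upper else x <= upper
  if (!lo || !hi) {
    stop(sprintf("'%s' = %g is outside %s%g, %g%s", name, x,
                 if (openLower) "(" else "[", lower, upper,
                 if (openUpper) ")" else "]"))
  }
  invisible(x)
}
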