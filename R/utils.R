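#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded generators are
#' pure functions of `(arguments, seed)` and never perturb the caller's
#' random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
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
  expr
}

#' Range-normalize a vector to the interval [1, 100]
#'
#' The normalization used for every centrality entering the IVI composite:
#' `1 + 99 * (x - min) / (max - min)`.  A constant vector (max == min)
#' maps to all ones, the convention for degenerate (e.g. regular) graphs.
#'
#' @param x Numeric vector.
#' @return Numeric vector in `[1, 100]`; `numeric(0)` stays empty.
#' @export
#' @examples
#' range_normalize(c(0, 5, 10))  # 1, 50.5, 100
#' range_normalize(c(3, 3, 3))   # all 1
range_normalize <- function(x) {
  if (length(x) == 0L) return(numeric(0))
  rng <- range(x)
  if (!all(is.finite(rng))) stop("non-finite values in range_normalize")
  if (rng[1] == rng[2]) return(rep(1, length(x)))
  1 + 99 * (x - rng[1]) / (rng[2] - rng[1])
}

# shared stop helper: consistent "stage: message" errors
stop2 <- function(...) stop(paste0(...), call. = FALSE)
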