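#' @useDynLib ocuprost, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median kmeans lsfit quantile rnorm runif sd setNames optim dnorm rbinom
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so seeded helpers do not disturb
#' the caller's RNG stream.
#' @param seed integer seed
#' @param code expression to evaluate
#' @return value of \code{code}
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

abort_ocuprost <- function(msg, class) {
  stop(structure(class = c(class, "ocuprost_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# clamp to [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
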