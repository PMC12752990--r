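#' @useDynLib dmrpredict, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats prcomp kmeans p.adjust pchisq phyper glm binomial
#'   plogis qlogis rnorm rbeta rbinom rnbinom runif predict coef var sd
#'   quantile setNames as.formula optim
#' @importFrom utils read.delim write.table head
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs code under the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of child seeds from a master seed, keeping them < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

# logit-scale effect injection, clipped so beta-binomial draws stay valid
clip01 <- function(p, lo = 0.01, hi = 0.99) pmin(pmax(p, lo), hi)
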