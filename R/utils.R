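#' @useDynLib microstatr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rgamma runif sd var fft kmeans lm coef median
#'   pnorm pwilcox predict quantile complete.cases binomial glm setNames
#' @importFrom utils head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Run-length encode an integer state sequence: data.frame(state, length).
run_lengths <- function(s) {
  r <- rle(as.integer(s))
  data.frame(state = r$values, length = r$lengths)
}

# Deterministic per-subject / per-fold seed derivation that stays inside
# 32-bit integer range.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed)
  for (k in idx) s <- (s * 69069 + k * 9973 + 1) %% 2147483647
  as.integer(s)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)
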