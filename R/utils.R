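#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm rpois rgamma rnbinom rlnorm runif rmultinom
#'   rbeta cor sd quantile median dist cmdscale model.matrix setNames
#'   aggregate rbinom pnorm coef vcov logLik as.formula
#' @importFrom utils head read.csv write.csv
NULL

# Evaluate `expr` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a stream of child seeds from one master seed (all < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Weighted pool-adjacent-violators algorithm
#'
#' Least-squares monotone (non-decreasing) regression of `y` with weights
#' `w`, used by the NMDS inner loop for the isotonic fit of configuration
#' distances on the dissimilarity rank order.
#'
#' @param y numeric vector, already in the order the fit must be monotone in.
#' @param w positive weights, same length as `y`.
#' @return fitted values, non-decreasing, same length as `y`.
#' @export
pava <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  if (n == 0L) return(numeric(0))
  stopifnot(length(w) == n, all(w > 0))
  # blocks stored as (value, weight, size); merge while decreasing
  val <- numeric(n); wt <- numeric(n); sz <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    k <- k + 1L
    val[k] <- y[i]; wt[k] <- w[i]; sz[k] <- 1L
    while (k > 1L && val[k - 1L] > val[k]) {
      v <- (val[k - 1L] * wt[k - 1L] + val[k] * wt[k]) / (wt[k - 1L] + wt[k])
      wt[k - 1L] <- wt[k - 1L] + wt[k]
      sz[k - 1L] <- sz[k - 1L] + sz[k]
      val[k - 1L] <- v
      k <- k - 1L
    }
  }
  rep.int(val[seq_len(k)], sz[seq_len(k)])
}

# Sample skewness (method-of-moments); NA for constant input.
skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0 || n < 3) return(NA_real_)
  mean((x - m)^3) / s2^1.5
}

# round to the resolution of a tipping-bucket gauge
round_half_mm <- function(x) round(x * 2) / 2

`%||%` <- function(a, b) if (is.null(a)) b else a
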