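#' Spearman collinearity screen
#'
#' Pairwise Spearman rank correlations (average ranks for ties,
#' pairwise-complete observations) between candidate environmental
#' covariates, flagging pairs with absolute correlation above `threshold`.
#' Constant variables have undefined correlations; these are recorded as
#' missing and the variable itself is flagged.
#'
#' @param data data.frame holding the covariates.
#' @param vars covariate names (default: all numeric columns).
#' @param threshold flag threshold on |r_s| (strict inequality; default 0.7).
#' @return object of class `screen_result`: the correlation matrix,
#'   flagged pairs, and after [prune_covariates()] the dropped/retained
#'   sets.
#' @export
spearman_screen <- function(data, vars = NULL, threshold = 0.7) {
  if (is.null(vars))
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
  stopifnot(all(vars %in% names(data)), length(vars) >= 2L)
  X <- data[vars]
  n_ok <- vapply(vars, function(v) sum(!is.na(X[[v]])), numeric(1))
  if (any(n_ok < 3L))
    stop("need at least 3 complete observations per variable", call. = FALSE)
  R <- suppressWarnings(
    cor(X, method = "spearman", use = "pairwise.complete.obs"))
  constant <- vars[vapply(vars, function(v)
    sd(X[[v]], na.rm = TRUE) == 0, logical(1))]
  diag(R) <- 1
  flagged <- which(abs(R) > threshold & upper.tri(R), arr.ind = TRUE)
  pairs <- data.frame(
    var1 = vars[flagged[, 1]], var2 = vars[flagged[, 2]],
    r_s = R[flagged])
  pairs <- pairs[order(-abs(pairs$r_s), pairs$var1, pairs$var2), ]
  rownames(pairs) <- NULL
  structure(list(correlations = R, flagged = pairs, threshold = threshold,
                 constant = constant, data = X, vars = vars),
            class = "screen_result")
}

# preference score: longer gradient first, then the more even distribution
# (smaller absolute skewness), then name (reverse-alphabetical so that
# lexicographically earlier names win ties deterministically).
covariate_preference <- function(x) {
  rng <- diff(range(x, na.rm = TRUE))
  sk <- skewness(x)
  c(range = rng, neg_abs_skew = if (is.na(sk)) -Inf else -abs(sk))
}

#' Prune collinear covariates
#'
#' Iteratively resolves the flagged pair with the largest |r_s| by
#' dropping its lower-preference member, until no retained pair exceeds
#' the threshold. Preference ranks variables by gradient length (range),
#' then by the more symmetric distribution (smaller |skewness|), then by
#' name -- a deterministic operationalization that is independent of
#' column order. Pairs at exactly the threshold are retained (strict
#' inequality).
#'
#' @param screen a `screen_result` from [spearman_screen()].
#' @return the `screen_result` with `dropped` (data.frame of variable,
#'   reason) and `retained` (character vector) filled in.
#' @export
prune_covariates <- function(screen) {
  stopifnot(inherits(screen, "screen_result"))
  R <- abs(screen$correlations)
  diag(R) <- 0
  alive <- screen$vars
  dropped <- data.frame(variable = character(0), reason = character(0))
  drop_var <- function(v, reason) {
    alive <<- setdiff(alive, v)
    dropped <<- rbind(dropped, data.frame(variable = v, reason = reason))
  }
  for (v in intersect(screen$constant, alive))
    drop_var(v, "constant (correlation undefined)")
  repeat {
    sub <- R[alive, alive, drop = FALSE]
    sub[is.na(sub)] <- 0
    if (all(sub <= screen$threshold)) break
    ij <- which(sub == max(sub), arr.ind = TRUE)
    # deterministic pair choice under exact ties
    cand <- data.frame(a = alive[ij[, 1]], b = alive[ij[, 2]])
    cand <- cand[cand$a != cand$b, ]
    swap <- cand$a > cand$b
    tmp <- cand$a[swap]; cand$a[swap] <- cand$b[swap]; cand$b[swap] <- tmp
    cand <- unique(cand)
    cand <- cand[order(cand$a, cand$b), ][1, ]
    pa <- covariate_preference(screen$data[[cand$a]])
    pb <- covariate_preference(screen$data[[cand$b]])
    loser <- if (pa["range"] != pb["range"]) {
      if (pa["range"] < pb["range"]) cand$a else cand$b
    } else if (pa["neg_abs_skew"] != pb["neg_abs_skew"]) {
      if (pa["neg_abs_skew"] < pb["neg_abs_skew"]) cand$a else cand$b
    } else {
      max(cand$a, cand$b)  # later name loses
    }
    winner <- setdiff(c(cand$a, cand$b), loser)
    drop_var(loser, sprintf("|r_s| = %.3f with %s",
                            R[cand$a, cand$b], winner))
  }
  screen$dropped <- dropped
  screen$retained <- sort(alive)
  screen
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("Spearman screen of %d covariates (threshold |r_s| > %.2f)\n",
              length(x$vars), x$threshold))
  cat(sprintf("  flagged pairs: %d\n", nrow(x$flagged)))
  if (!is.null(x$retained)) {
    cat("  retained:", paste(x$retained, collapse = ", "), "\n")
    if (nrow(x$dropped))
      cat("  dropped: ", paste(x$dropped$variable, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Reference retained covariate set
#'
#' The environmental covariates the shipped example configuration carries
#' forward after the collinearity screen of the field study the generator
#' emulates: seasonal rainfall, total plant cover, gravel and cobble (sand,
#' boulder, large boulder, plant species number and herb/grass cover
#' excluded). Asserted as configuration, not recomputed from data.
#'
#' @return character vector of covariate names.
#' @export
reference_covariates <- function() {
  c("seasonal_rainfall", "plant_cover", "gravel", "cobble")
}
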