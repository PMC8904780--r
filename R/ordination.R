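#' Normalize taxon columns to unit sum of squares
#'
#' Divides each taxon column by its Euclidean norm so that every column's
#' margin sum of squares equals one, removing magnitude differences
#' between abundant and scarce taxa before dissimilarity calculation.
#' Row (site) scaling is available via `margin = "sites"`.
#'
#' @param M site-by-taxa matrix, nonnegative.
#' @param margin `"taxa"` (columns, default) or `"sites"` (rows).
#' @return matrix of the same shape.
#' @export
normalize_columns <- function(M, margin = c("taxa", "sites")) {
  margin <- match.arg(margin)
  M <- as.matrix(M)
  if (margin == "sites") return(t(normalize_columns(t(M), "taxa")))
  norms <- sqrt(colSums(M^2))
  if (any(norms == 0)) {
    bad <- colnames(M)[norms == 0] %||% which(norms == 0)
    stop(sprintf("all-zero column(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  sweep(M, 2, norms, "/")
}

#' Bray--Curtis dissimilarity matrix
#'
#' d(i, j) = sum_k |x_ik - x_jk| / sum_k (x_ik + x_jk): 0 for identical
#' sites, 1 for sites with disjoint taxon support.
#'
#' @param M site-by-taxa matrix, nonnegative, no all-zero row.
#' @return symmetric dissimilarity matrix with zero diagonal, entries in
#'   [0, 1], dimnames taken from the row names of `M`.
#' @export
bray_curtis <- function(M) {
  M <- as.matrix(M)
  if (any(M < 0)) stop("negative abundances", call. = FALSE)
  if (any(rowSums(M) == 0))
    stop("all-zero row(s): Bray-Curtis undefined for empty sites",
         call. = FALSE)
  n <- nrow(M)
  rs <- rowSums(M)
  # sum of pairwise minima via one matrix product per taxon is O(n^2 p);
  # vectorize with |x - y| = x + y - 2 min(x, y)
  D <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    num <- colSums(abs(t(M[j, , drop = FALSE]) - M[i, ]))
    den <- rs[i] + rs[j]
    D[i, j] <- D[j, i] <- num / den
  }
  D
}

procrustes_cor <- function(X, Y) {
  X <- scale(X, scale = FALSE); Y <- scale(Y, scale = FALSE)
  X <- X / sqrt(sum(X^2)); Y <- Y / sqrt(sum(Y^2))
  sv <- svd(crossprod(X, Y))
  sum(sv$d)  # in [0, 1]; 1 = identical up to rotation/scale
}

nmds_stress <- function(dvec, dhat) sqrt(sum((dvec - dhat)^2) / sum(dvec^2))

# isotonic fit of configuration distances on the dissimilarity order,
# ties in the dissimilarities averaged within blocks. Equivalent to
# weighted PAVA on the block means (see pava()); stats::isoreg on the
# block-averaged vector is used for speed.
monotone_fit <- function(dvec, ord, block) {
  d_sorted <- dvec[ord]
  bm <- rowsum(d_sorted, block) / tabulate(block)
  dhat_sorted <- stats::isoreg(bm[block, 1L])$yf
  dhat <- numeric(length(dvec))
  dhat[ord] <- dhat_sorted
  dhat
}

#' Non-metric multidimensional scaling
#'
#' Minimizes Kruskal stress-1, sqrt(sum (d - dhat)^2 / sum d^2), where d
#' are configuration Euclidean distances and dhat their isotonic
#' (monotone) regression on the rank order of the input dissimilarities.
#' Alternates the pool-adjacent-violators fit with Guttman-transform
#' configuration updates; iterations that fail to decrease stress are
#' rejected, so stress is non-increasing. The best of `n_restarts` starts
#' is returned (first start: principal-coordinates configuration; the
#' rest random); the fit is declared convergent when at least two
#' restarts' solutions agree to Procrustes correlation >= 0.999.
#'
#' @param D dissimilarity matrix (or `dist`).
#' @param k target dimension (default 2).
#' @param n_restarts number of starts (default 20).
#' @param max_iter iteration cap per start.
#' @param tol stop when the stress decrease falls below this.
#' @param seed RNG seed for the random restarts.
#' @return object of class `nmds_result`: `scores` (n x k, centered),
#'   `stress`, `n_restarts`, `converged`, `restart_stress`.
#' @export
nmds <- function(D, k = 2L, n_restarts = 20L, max_iter = 200L,
                 tol = 1e-7, seed = 1L) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 4L) stop("need at least 4 sites for NMDS", call. = FALSE)
  Dvec <- D[lower.tri(D)]
  ord <- order(Dvec)
  block <- match(Dvec[ord], unique(Dvec[ord]))  # tie blocks
  ij <- which(lower.tri(D), arr.ind = TRUE)

  run_start <- function(X) {
    X <- scale(X, scale = FALSE)
    dvec <- as.numeric(dist(X))
    dhat <- monotone_fit(dvec, ord, block)
    s <- nmds_stress(dvec, dhat)
    for (it in seq_len(max_iter)) {
      # Guttman transform for the current monotone fit
      Bv <- ifelse(dvec > 0, dhat / dvec, 0)
      B <- matrix(0, n, n)
      B[cbind(ij[, 1], ij[, 2])] <- -Bv
      B[cbind(ij[, 2], ij[, 1])] <- -Bv
      diag(B) <- -rowSums(B)
      Xn <- B %*% X / n
      dvec_n <- as.numeric(dist(Xn))
      dhat_n <- monotone_fit(dvec_n, ord, block)
      s_n <- nmds_stress(dvec_n, dhat_n)
      if (s_n > s) break  # reject non-improving update
      improved <- s - s_n
      X <- Xn; dvec <- dvec_n; dhat <- dhat_n; s <- s_n
      if (improved < tol) break
    }
    list(scores = scale(X, scale = FALSE), stress = s)
  }

  starts <- with_seed(seed, {
    inits <- vector("list", n_restarts)
    pc <- suppressWarnings(cmdscale(D, k = k))
    if (ncol(pc) < k) pc <- cbind(pc, matrix(0, n, k - ncol(pc)))
    inits[[1L]] <- pc
    for (r in seq_len(n_restarts - 1L))
      inits[[r + 1L]] <- matrix(rnorm(n * k), n, k) * mean(Dvec)
    lapply(inits, run_start)
  })

  stresses <- vapply(starts, `[[`, numeric(1), "stress")
  best <- which.min(stresses)
  sol <- starts[[best]]
  converged <- FALSE
  for (r in seq_len(n_restarts)) {
    if (r != best && abs(stresses[r] - sol$stress) < 1e-3 &&
        procrustes_cor(starts[[r]]$scores, sol$scores) >= 0.999) {
      converged <- TRUE
      break
    }
  }
  if (!converged && n_restarts > 1L)
    warning("no two NMDS restarts converged to the same solution")
  rownames(sol$scores) <- rownames(D)
  colnames(sol$scores) <- paste0("NMDS", seq_len(k))
  structure(list(scores = sol$scores, stress = sol$stress,
                 n_restarts = n_restarts, converged = converged,
                 restart_stress = stresses),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS: %d sites, stress = %.4f, %d restarts, %s\n",
              nrow(x$scores), x$stress, x$n_restarts,
              if (x$converged) "convergent" else "no convergent pair"))
  invisible(x)
}

#' Fit an environmental vector onto an ordination
#'
#' Least-squares regression of the centered variable on the site scores;
#' r-squared is 1 - RSS/TSS, the arrow direction is the normalized
#' coefficient vector, and significance comes from permuting the
#' variable's values across sites: P = (1 + #{r2_perm >= r2}) / (1 +
#' n_perm).
#'
#' @param scores site scores (n x k) from [nmds()].
#' @param x environmental variable, length n, non-constant.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed.
#' @return list with `r2`, `direction` (unit vector), `p_value`, `n_perm`.
#' @export
envfit_vector <- function(scores, x, n_perm = 1000L, seed = 1L) {
  scores <- as.matrix(scores)
  stopifnot(length(x) == nrow(scores))
  if (sd(x) == 0) stop("constant environmental variable", call. = FALSE)
  Xc <- scale(scores, scale = FALSE)
  qrX <- qr(Xc)
  r2_of <- function(v) {
    vc <- v - mean(v)
    fit <- qr.fitted(qrX, vc)
    sum(fit^2) / sum(vc^2)
  }
  r2 <- r2_of(x)
  beta <- qr.coef(qrX, x - mean(x))
  direction <- beta / sqrt(sum(beta^2))
  perm_r2 <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    r2_of(sample(x)), numeric(1)))
  p <- (1 + sum(perm_r2 >= r2)) / (1 + n_perm)
  list(r2 = r2, direction = as.numeric(direction), p_value = p,
       n_perm = n_perm)
}

#' Fit several environmental vectors
#'
#' @param scores site scores.
#' @param env data.frame of variables (columns fitted one at a time).
#' @param n_perm,seed passed to [envfit_vector()]; each variable uses an
#'   independent child seed.
#' @return data.frame with one row per variable: `r2`, the direction
#'   cosines and the permutation P.
#' @export
envfit_table <- function(scores, env, n_perm = 1000L, seed = 1L) {
  seeds <- derive_seeds(seed, ncol(env))
  rows <- lapply(seq_along(env), function(i) {
    f <- envfit_vector(scores, env[[i]], n_perm = n_perm, seed = seeds[i])
    data.frame(variable = names(env)[i], r2 = f$r2,
               dir1 = f$direction[1], dir2 = f$direction[2],
               p_value = f$p_value)
  })
  do.call(rbind, rows)
}

#' Permutational multivariate analysis of variance (sequential SS)
#'
#' Partitions a dissimilarity matrix by the McArdle--Anderson approach:
#' with A = -D^2/2 and G = JAJ (J the centering operator), each term
#' added in order contributes SS = tr((H_j - H_{j-1}) G), pseudo-F =
#' (SS/df) / (SS_res/df_res), and significance comes from jointly
#' permuting the rows and columns of D. Sequential (Type-I) sums of
#' squares are order-dependent; the term order is the order of `terms`.
#'
#' @param D dissimilarity matrix.
#' @param data data.frame holding the model variables (rows match `D`).
#' @param terms character vector of term names, added in this order.
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @return data.frame of class `permanova_table`: one row per term plus
#'   `Residual` and `Total`, with `df`, `SS`, `R2`, `F`, `p_value`.
#' @export
permanova <- function(D, data, terms, n_perm = 999L, seed = 1L) {
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(nrow(data) == n, all(terms %in% names(data)))
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J

  X <- matrix(1, n, 1)
  hats <- list()
  dfs <- integer(length(terms))
  for (i in seq_along(terms)) {
    v <- data[[terms[i]]]
    cols <- if (is.factor(v) || is.character(v)) {
      model.matrix(~ f, data.frame(f = factor(v)))[, -1, drop = FALSE]
    } else matrix(as.numeric(v), ncol = 1)
    Xi <- cbind(X, cols)
    q_prev <- qr(X); q_new <- qr(Xi)
    dfs[i] <- q_new$rank - q_prev$rank
    if (dfs[i] == 0L)
      stop(sprintf("term '%s' is aliased with earlier terms", terms[i]),
           call. = FALSE)
    X <- Xi
    hats[[i]] <- list(prev = q_prev, new = q_new)
  }
  q_full <- qr(X)
  df_res <- n - q_full$rank
  hat_of <- function(q) {
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    tcrossprod(Q)
  }
  Hd <- lapply(hats, function(h) hat_of(h$new) - hat_of(h$prev))
  H_full <- hat_of(q_full)
  R_full <- diag(n) - H_full

  ss_stats <- function(Gp) {
    ss <- vapply(Hd, function(H) sum(H * Gp), numeric(1))
    ss_res <- sum(R_full * Gp)
    Fs <- (ss / dfs) / (ss_res / df_res)
    list(ss = ss, ss_res = ss_res, F = Fs)
  }
  obs <- ss_stats(G)
  ss_total <- sum(diag(G))

  F_perm <- with_seed(seed, {
    out <- matrix(NA_real_, n_perm, length(terms))
    for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      out[b, ] <- ss_stats(G[p, p])$F
    }
    out
  })
  pvals <- vapply(seq_along(terms), function(i)
    (1 + sum(F_perm[, i] >= obs$F[i])) / (1 + n_perm), numeric(1))

  tab <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(dfs, df_res, n - 1L),
    SS = c(obs$ss, obs$ss_res, ss_total),
    R2 = c(obs$ss, obs$ss_res, ss_total) / ss_total,
    F = c(obs$F, NA, NA),
    p_value = c(pvals, NA, NA))
  class(tab) <- c("permanova_table", "data.frame")
  tab
}
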