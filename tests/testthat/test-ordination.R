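test_that("column normalization gives unit sum of squares per taxon", {
  M <- rbind(c(3, 1), c(4, 1))
  N <- normalize_columns(M)
  expect_equal(N[, 1], c(0.6, 0.8))
  expect_equal(colSums(N^2), c(1, 1), tolerance = 1e-12)
  expect_equal(normalize_columns(N), N)  # idempotent
  set.seed(1)
  R <- matrix(rexp(60), 10)
  expect_equal(unname(colSums(normalize_columns(R)^2)), rep(1, 6),
               tolerance = 1e-12)
  Z <- cbind(R, 0); colnames(Z) <- c(paste0("t", 1:6), "empty")
  expect_error(normalize_columns(Z), "empty")
})

test_that("Bray-Curtis matches its definition and the naive oracle", {
  expect_equal(bray_curtis(rbind(c(6, 2), c(2, 2)))[1, 2], 1 / 3)
  expect_equal(bray_curtis(rbind(c(1, 2), c(1, 2)))[1, 2], 0)
  expect_equal(bray_curtis(rbind(c(5, 0), c(0, 3)))[1, 2], 1)
  set.seed(7)
  for (i in 1:5) {
    M <- matrix(rpois(50, 3), 10, 5)
    M[rowSums(M) == 0, 1] <- 1
    D <- bray_curtis(M)
    expect_lt(max(abs(D - bray_oracle(M))), 1e-12)
    expect_lt(max(abs(D - as.matrix(vegan::vegdist(M, "bray")))), 1e-12)
    expect_true(all(D >= 0 & D <= 1))
  }
  expect_error(bray_curtis(rbind(c(0, 0), c(1, 2))), "all-zero")
})

test_that("NMDS recovers exactly embeddable configurations with near-zero stress", {
  set.seed(3)
  X <- matrix(rnorm(20), 10, 2)
  D <- as.matrix(dist(X))
  fit <- suppressWarnings(nmds(D, n_restarts = 5, seed = 1))
  expect_lte(fit$stress, 0.001)
  expect_equal(unname(colMeans(fit$scores)), c(0, 0), tolerance = 1e-8)
  # geometric oracle: a unit square comes back as a square
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  fsq <- suppressWarnings(nmds(as.matrix(dist(sq)), n_restarts = 8,
                               seed = 2))
  expect_lte(fsq$stress, 0.001)
  expect_gte(aridpulse:::procrustes_cor(fsq$scores, sq), 0.999)
})

test_that("NMDS depends only on dissimilarity ranks", {
  set.seed(4)
  X <- matrix(rnorm(24), 12, 2)
  D <- as.matrix(dist(X)) + 0.05
  diag(D) <- 0
  s1 <- nmds(D, n_restarts = 10, seed = 5)$stress
  s2 <- nmds(D^2, n_restarts = 10, seed = 5)$stress
  expect_lt(abs(s1 - s2), 1e-3)
})

test_that("NMDS stress never beats its PCoA start by accident of bookkeeping", {
  # the returned stress is the best over restarts, so it cannot exceed
  # the stress of the PCoA-initialized run alone
  set.seed(5)
  M <- matrix(rpois(80, 4), 16, 5)
  D <- bray_curtis(M + 1)
  many <- nmds(D, n_restarts = 10, seed = 1)
  one <- suppressWarnings(nmds(D, n_restarts = 1, seed = 1))
  expect_lte(many$stress, one$stress + 1e-12)
})

test_that("weighted PAVA is monotone, mean-preserving and matches isoreg", {
  set.seed(6)
  y <- rnorm(40)
  f <- pava(y)
  expect_true(all(diff(f) >= -1e-12))
  expect_equal(mean(f), mean(y))
  expect_equal(f, isoreg(y)$yf, tolerance = 1e-12)
  w <- runif(40, 0.5, 2)
  fw <- pava(y, w)
  expect_true(all(diff(fw) >= -1e-12))
  expect_equal(sum(fw * w), sum(y * w))
})

test_that("envfit recovers perfect and closed-form alignments", {
  set.seed(8)
  scores <- scale(matrix(rnorm(60), 30, 2), scale = FALSE)
  f1 <- envfit_vector(scores, scores[, 1], n_perm = 999, seed = 1)
  expect_equal(f1$r2, 1, tolerance = 1e-12)
  expect_equal(f1$p_value, 1 / 1000)
  f12 <- envfit_vector(scores, scores[, 1] + scores[, 2], n_perm = 99,
                       seed = 1)
  expect_equal(abs(f12$direction), rep(1 / sqrt(2), 2), tolerance = 1e-9)
  expect_error(envfit_vector(scores, rep(1, 30), n_perm = 99), "constant")
})

test_that("envfit r2 is invariant to rotation of the score axes", {
  set.seed(9)
  scores <- scale(matrix(rnorm(50), 25, 2), scale = FALSE)
  v <- rnorm(25)
  th <- 0.7
  Rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  f1 <- envfit_vector(scores, v, n_perm = 49, seed = 2)
  f2 <- envfit_vector(scores %*% Rot, v, n_perm = 49, seed = 2)
  expect_equal(f1$r2, f2$r2, tolerance = 1e-9)
})

test_that("envfit permutation p-values are calibrated under the null", {
  set.seed(10)
  n_rep <- 400
  p <- vapply(seq_len(n_rep), function(i) {
    scores <- matrix(rnorm(40), 20, 2)
    envfit_vector(scores, rnorm(20), n_perm = 199, seed = i)$p_value
  }, numeric(1))
  rej <- mean(p <= 0.05)
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("PERMANOVA reproduces classical ANOVA in the Euclidean univariate case", {
  set.seed(11)
  y <- rnorm(24)
  g <- factor(rep(letters[1:3], each = 8))
  D <- as.matrix(dist(y))
  tab <- permanova(D, data.frame(g = g), "g", n_perm = 49, seed = 1)
  f_classic <- anova(lm(y ~ g))[["F value"]][1]
  expect_equal(tab$F[1], f_classic, tolerance = 1e-9)
  expect_equal(sum(tab$R2[1:2]), 1, tolerance = 1e-9)
  # SS_total equals the trace of the Gower-centered matrix by construction
  expect_equal(tab$SS[3], sum(tab$SS[1:2]), tolerance = 1e-9)
})

test_that("PERMANOVA sequential SS agree with the reference implementation", {
  set.seed(12)
  M <- matrix(rpois(100, 5), 20, 5)
  d <- data.frame(x = rnorm(20), g = factor(rep(1:2, 10)))
  D <- bray_curtis(M + 1)
  tab <- permanova(D, d, c("x", "g"), n_perm = 99, seed = 1)
  ref <- vegan::adonis2(as.dist(D) ~ x + g, data = d, permutations = 99,
                        by = "terms")
  expect_equal(tab$SS[1:3], ref$SumOfSqs[1:3], tolerance = 1e-9)
  expect_equal(tab$F[1:2], ref$F[1:2], tolerance = 1e-9)
})

test_that("PERMANOVA p-values match exhaustive enumeration at n = 6", {
  set.seed(13)
  y <- matrix(rnorm(18), 6, 3)
  grp <- factor(rep(c("a", "b"), each = 3))
  D <- as.matrix(dist(y))
  f_obs <- pseudo_f_oracle(D, grp)
  perms <- all_perms(6)
  f_all <- apply(perms, 1, function(p) pseudo_f_oracle(D[p, p], grp))
  # permutations preserving the partition tie with F_obs to rounding;
  # bracket the exact p-value by strict and tie-inclusive counts
  p_hi <- mean(f_all >= f_obs - 1e-9)
  p_lo <- mean(f_all > f_obs + 1e-9)
  tab <- permanova(D, data.frame(grp = grp), "grp", n_perm = 999,
                   seed = 3)
  expect_equal(tab$F[1], f_obs, tolerance = 1e-9)
  se <- sqrt(p_hi * (1 - p_hi) / 999)
  expect_gt(tab$p_value[1], p_lo - 2 * se)
  expect_lt(tab$p_value[1], p_hi + 2 * se + 1 / 1000)
})

test_that("identical groups of identical sites contribute zero SS", {
  M <- rbind(c(1, 2), c(3, 1), c(1, 2), c(3, 1))
  D <- bray_curtis(M)
  tab <- suppressWarnings(
    permanova(D, data.frame(g = factor(c(1, 1, 2, 2))), "g",
              n_perm = 19, seed = 1))
  expect_equal(tab$SS[1], 0, tolerance = 1e-12)
  expect_error(
    permanova(D, data.frame(g = factor(c(1, 1, 2, 2)),
                            g2 = factor(c(1, 1, 2, 2))), c("g", "g2"),
              n_perm = 19, seed = 1),
    "aliased")
})
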