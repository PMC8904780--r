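# Shared fixtures, all built in code.

# constant daily rainfall over given years
flat_rain <- function(years, mm = 1) {
  dates <- seq(as.Date(sprintf("%d-01-01", min(years) - 1)),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  data.frame(date = dates, mm = rep(mm, length(dates)))
}

# a small hand-made trap table: two plots, one year, two rounds
tiny_traps <- function() {
  expand.grid(plot = c("A", "B"), year = 2015L, round = 1:2,
              taxon = c("Cicadina", "Collembola"),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE) |>
    (\(d) {
      d$start_date <- as.Date("2015-03-05") + (d$round - 1L) * 15L
      d$count <- c(3L, 1L, 4L, 2L, 5L, 0L, 6L, 7L)
      d[c("plot", "year", "round", "start_date", "taxon", "count")]
    })()
}

tiny_taxa <- function() {
  data.frame(taxon = c("Cicadina", "Collembola"),
             trophic_group = c("herbivores", "detritivores"),
             ground_dwelling = TRUE)
}

tiny_veg <- function() {
  data.frame(plot = rep(c("A", "B"), each = 2), year = 2015L,
             round = rep(1:2, 2),
             total_cover = c(10, 24, 5, 3), herb_cover = c(2, 6, 1, 1),
             grass_cover = c(7, 15, 3, 2), n_species = c(3L, 5L, 2L, 2L))
}

tiny_soil <- function() {
  data.frame(plot = c("A", "B"), sand = c(60, 50), gravel = c(25, 30),
             cobble = c(10, 12), boulder = c(4, 6),
             large_boulder = c(1, 2))
}

# small, fast study for integration-style tests
small_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_plots = 10L, years = 2013:2015,
             dropout_rate = 0, ...)
}

# simulate an NB random-intercept dataset with known parameters
sim_nb_panel <- function(n_groups = 30, n_per = 12, beta0 = 2,
                         beta1 = 0.5, sigma = 0.5, theta = 2,
                         seed = 1) {
  set.seed(seed)
  g <- factor(rep(seq_len(n_groups), each = n_per))
  x <- rnorm(n_groups * n_per)
  b <- rnorm(n_groups, 0, sigma)[as.integer(g)]
  mu <- exp(beta0 + beta1 * x + b)
  data.frame(y = rnbinom(length(mu), mu = mu, size = theta),
             x = x, plot = g)
}

# naive double-loop Bray-Curtis, the independent oracle
bray_oracle <- function(M) {
  n <- nrow(M)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- sum(abs(M[i, ] - M[j, ])) / sum(M[i, ] + M[j, ])
  D
}

# one-factor distance-based pseudo-F, the independent PERMANOVA oracle
# (group-sum formulation, no hat matrices)
pseudo_f_oracle <- function(D, grp) {
  n <- nrow(D)
  a <- length(unique(grp))
  d2 <- D^2
  ss_total <- sum(d2[lower.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(grp)) {
    idx <- which(grp == g)
    sub <- d2[idx, idx]
    ss_within <- ss_within + sum(sub[lower.tri(sub)]) / length(idx)
  }
  ss_between <- ss_total - ss_within
  (ss_between / (a - 1)) / (ss_within / (n - a))
}

# Gauss-Hermite nodes/weights (Golub-Welsch) for integrals against exp(-x^2)
gh_rule <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}

# independent adaptive Gauss-Hermite marginal log-likelihood for the NB
# random-intercept model, evaluated at given parameters
agq_loglik <- function(y, eta, sigma, theta, group, nodes = 9) {
  rule <- gh_rule(nodes)
  total <- 0
  for (g in unique(group)) {
    idx <- group == g
    gfun <- function(u)
      sum(dnbinom(y[idx], mu = exp(eta[idx] + u), size = theta,
                  log = TRUE)) + dnorm(u, 0, sigma, log = TRUE)
    uhat <- optimize(gfun, c(-8, 8) * max(sigma, 0.2),
                     maximum = TRUE)$maximum
    h <- 1e-4
    curv <- -(gfun(uhat + h) - 2 * gfun(uhat) + gfun(uhat - h)) / h^2
    tau <- 1 / sqrt(max(curv, 1e-8))
    u <- uhat + sqrt(2) * tau * rule$x
    gv <- vapply(u, gfun, numeric(1))
    m <- max(gv)
    total <- total +
      m + log(sqrt(2) * tau * sum(rule$w * exp(rule$x^2 + gv - m)))
  }
  total
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    block <- cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))
    out <- rbind(out, block)
  }
  out
}
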