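#' Configuration for the synthetic arid-savannah study generator
#'
#' Bundles every knob of the synthetic study: design constants (plots,
#' years, trapping rounds), the rainfall climate (seasonal mean and
#' coefficient of variation of the February--March total), the causal
#' structure (per-group critical-window lags, rainfall and trophic link
#' coefficients), the stochastic components (negative-binomial dispersion
#' per group, plot random-intercept SD, shared year-level SD) and the data
#' imperfections real panels show (plot-year dropout, rare taxa, one
#' non-ground-dwelling taxon).
#'
#' Counts for trophic group g at plot p, year y, round r are drawn
#' NB(exp(eta), theta_g) with
#' eta = alpha_g + gamma_g * W + sum(link * latent parent) + b_p + u_y,
#' where W is the standardized 7-day rainfall sum ending `lag_g` days
#' before the trap start, b_p ~ N(0, sigma_plot^2) and u_y ~ N(0,
#' sigma_year^2). Ants have no critical window; they respond to the
#' standardized seasonal (Feb--Mar) total instead.
#'
#' @param seed integer master seed; fixed seed gives byte-identical output.
#' @param n_plots number of 2 m x 2 m plots (default 30).
#' @param years study years (default 2013:2018).
#' @param rounds_per_year trapping rounds per year, at least 14 days apart.
#' @param seasonal_mean_mm across-year mean of the Feb--Mar rainfall total.
#' @param seasonal_cv coefficient of variation of the seasonal total
#'   (log-normal across years); 0 makes every year's total equal the mean.
#' @param group_lags named integer vector of critical-window offsets in
#'   days (window ends `lag` days before trapping starts); `NA` for ants.
#' @param group_effects named numeric vector of log-scale coefficients for
#'   the rainfall and bottom-up links (per SD of the driver).
#' @param alpha named numeric vector of per-round log-scale intercepts.
#' @param theta named numeric vector of NB dispersion per group
#'   (Var = mu + mu^2/theta).
#' @param sigma_plot SD of the plot random intercept.
#' @param sigma_year SD of the shared year-level deviate (per group).
#' @param dropout_rate probability a plot-year is lost; at least 15 plots
#'   are always retained per year.
#' @param rare_taxon_count number of extra taxa with expected study-wide
#'   totals below 50 individuals.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_plots = 30L,
                       years = 2013:2018,
                       rounds_per_year = 2L,
                       seasonal_mean_mm = 56,
                       seasonal_cv = 1.0,
                       group_lags = c(plants = 8L, herbivores = 15L,
                                      omnivores = 24L, predators = 15L,
                                      detritivores = 15L, ants = NA_integer_),
                       group_effects = c(
                         rain_plants = 1.0, rain_herbivores = 1.1,
                         rain_omnivores = 0.9, rain_predators = 0.35,
                         rain_detritivores = 1.3,
                         gravel_plants = -0.5,
                         plants_herbivores = 0.45,
                         plants_omnivores = 0.25,
                         herbivores_omnivores = 0.3,
                         herbivores_predators = 0.25,
                         omnivores_predators = 0.2,
                         detritivores_predators = 0.2,
                         herbivores_ants = 0.2,
                         season_ants = -0.2),
                       alpha = c(herbivores = 2.2, omnivores = 2.2,
                                 predators = 1.5, detritivores = 1.5,
                                 ants = 3.7),
                       theta = c(herbivores = 1.5, omnivores = 1.5,
                                 predators = 2, detritivores = 1.2,
                                 ants = 2.5),
                       sigma_plot = 0.4,
                       sigma_year = 0.45,
                       dropout_rate = 0.1,
                       rare_taxon_count = 3L) {
  cfg <- list(seed = as.integer(seed), n_plots = as.integer(n_plots),
              years = as.integer(years),
              rounds_per_year = as.integer(rounds_per_year),
              seasonal_mean_mm = seasonal_mean_mm,
              seasonal_cv = seasonal_cv,
              group_lags = group_lags, group_effects = group_effects,
              alpha = alpha, theta = theta,
              sigma_plot = sigma_plot, sigma_year = sigma_year,
              dropout_rate = dropout_rate,
              rare_taxon_count = as.integer(rare_taxon_count))
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (length(cfg$years) == 0L)
    stop("configuration error: 'years' must be non-empty", call. = FALSE)
  if (cfg$n_plots < 2L)
    stop("configuration error: need at least 2 plots", call. = FALSE)
  lags <- cfg$group_lags[!is.na(cfg$group_lags)]
  if (any(lags < 0L | lags > 30L))
    stop("configuration error: all lags must lie in [0, 30] days",
         call. = FALSE)
  if (cfg$seasonal_mean_mm <= 0 || cfg$seasonal_cv < 0)
    stop("configuration error: seasonal rainfall parameters must be positive",
         call. = FALSE)
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1)
    stop("configuration error: dropout_rate must be in [0, 1)", call. = FALSE)
  if (cfg$sigma_plot < 0 || cfg$sigma_year < 0)
    stop("configuration error: variance components must be nonnegative",
         call. = FALSE)
  invisible(cfg)
}

#' A fully nulled configuration for calibration studies
#'
#' All rainfall, soil and trophic-link coefficients are zero and the shared
#' year-level deviate is switched off, so counts carry no signal beyond the
#' plot random intercept and NB noise. Used to check that downstream tests
#' reject at their nominal rate.
#'
#' @inheritParams sim_config
#' @param ... further arguments passed to [sim_config()].
#' @export
null_config <- function(seed = 1L, ...) {
  cfg <- sim_config(seed = seed, ...)
  cfg$group_effects[] <- 0
  cfg$sigma_year <- 0
  cfg
}

trophic_groups <- function() {
  c("herbivores", "omnivores", "predators", "detritivores", "ants")
}

# day-of-year of a Date within its rain season, as distance to March 1
days_to_mar1 <- function(dates, year) {
  as.numeric(dates - as.Date(sprintf("%d-03-01", year)))
}

#' Generate a daily rainfall series
#'
#' Produces one record per calendar day from 1 October of the year before
#' the first study year through 31 December of the last study year.
#' Per-year February--March totals are drawn log-normally with mean
#' `seasonal_mean_mm` and coefficient of variation `seasonal_cv`, then
#' disaggregated into gamma-magnitude events on days weighted towards the
#' seasonal peak around 1 March; shoulder-season rain (October--January,
#' April) is generated the same way so annual totals sit near 2.35 times
#' the seasonal total. Daily amounts are recorded at 0.5 mm resolution
#' while preserving the drawn seasonal total exactly (to 0.5 mm).
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `date` (Date, strictly increasing,
#'   contiguous) and `mm` (nonnegative, multiples of 0.5).
#' @export
gen_rainfall <- function(config) {
  validate_config(config)
  with_seed(derive_seeds(config$seed, 6L)[1L], {
    years <- config$years
    start <- as.Date(sprintf("%d-10-01", min(years) - 1L))
    end <- as.Date(sprintf("%d-12-31", max(years)))
    dates <- seq(start, end, by = "day")
    mm <- numeric(length(dates))

    draw_total <- function(mean_mm, cv) {
      if (cv < 1e-12) return(mean_mm)
      sdlog <- sqrt(log(1 + cv^2))
      rlnorm(1, meanlog = log(mean_mm) - sdlog^2 / 2, sdlog = sdlog)
    }
    # scale event magnitudes to an exact half-mm total
    place <- function(days, target) {
      x <- rgamma(length(days), shape = 0.7, rate = 1)
      target <- round_half_mm(target)
      if (target <= 0) return(invisible(NULL))
      x <- x / sum(x) * target
      xr <- round_half_mm(x)
      xr[which.max(xr)] <- xr[which.max(xr)] + (target - sum(xr))
      xr <- pmax(xr, 0)
      idx <- match(days, dates)
      for (i in seq_along(idx)) mm[idx[i]] <<- mm[idx[i]] + xr[i]
      invisible(NULL)
    }

    for (y in years) {
      total <- draw_total(config$seasonal_mean_mm, config$seasonal_cv)
      season <- seq(as.Date(sprintf("%d-02-01", y)),
                    as.Date(sprintf("%d-03-31", y)), by = "day")
      w <- exp(-0.5 * (days_to_mar1(season, y) / 18)^2)
      n_ev <- 3L + rpois(1, 8)
      days <- sample(season, n_ev, replace = TRUE, prob = w)
      place(unique(days), total)

      shoulder <- c(seq(as.Date(sprintf("%d-10-01", y - 1L)),
                        as.Date(sprintf("%d-01-31", y)), by = "day"),
                    seq(as.Date(sprintf("%d-04-01", y)),
                        as.Date(sprintf("%d-04-30", y)), by = "day"))
      ws <- exp(-0.5 * (pmin(abs(days_to_mar1(shoulder, y)), 200) / 55)^2)
      n_sh <- 4L + rpois(1, 9)
      days <- sample(shoulder, n_sh, replace = TRUE, prob = ws)
      place(unique(days), 1.35 * total)
    }
    data.frame(date = dates, mm = mm)
  })
}

#' Generate plot soil-surface textures
#'
#' Five surface-material fractions per plot (sand, gravel, cobble, boulder,
#' large boulder), summing to 100 percent, with sand dominant -- drawn from
#' a Dirichlet with decreasing concentration across the size gradations.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `plot`, `sand`, `gravel`, `cobble`,
#'   `boulder`, `large_boulder` (percent).
#' @export
gen_plots <- function(config) {
  validate_config(config)
  with_seed(derive_seeds(config$seed, 6L)[2L], {
    shapes <- c(sand = 24, gravel = 12, cobble = 6, boulder = 3,
                large_boulder = 1.5)
    g <- matrix(rgamma(config$n_plots * 5L, shape = rep(shapes,
                each = config$n_plots)), ncol = 5L)
    frac <- g / rowSums(g) * 100
    colnames(frac) <- names(shapes)
    data.frame(plot = sprintf("P%02d", seq_len(config$n_plots)), frac)
  })
}

group_taxa <- function() {
  list(
    herbivores = c(Cicadina = 0.6, Caelifera = 0.3, Sternorrhyncha = 0.1),
    omnivores = c(Coleoptera = 0.5, Ensifera = 0.2, Heteroptera = 0.15,
                  Blattodea = 0.1, Psocoptera = 0.05),
    predators = c(Araneae = 0.4, Acarina = 0.35, Scorpiones = 0.1,
                  Chilopoda = 0.1, Pseudoscorpiones = 0.05),
    detritivores = c(Collembola = 1),
    ants = c(Formicidae = 1))
}

rare_taxon_pool <- function() {
  data.frame(
    taxon = c("Solifugae", "Zygentoma", "Embioptera", "Dermaptera",
              "Thysanoptera"),
    trophic_group = c("predators", "detritivores", "herbivores",
                      "omnivores", "herbivores"))
}

#' Generate a complete synthetic study dataset
#'
#' Draws daily rainfall, plot soil textures, per-round vegetation surveys
#' and pitfall-trap counts for every retained plot-year, wired by the
#' bottom-up causal structure in the configuration (rainfall -> plants ->
#' herbivores -> omnivores/predators, rainfall -> detritivores, seasonal
#' rainfall -> ants). Trophic links act on latent expected abundances, not
#' realized counts, so the cascade stays acyclic. Group counts are split
#' multinomially into member taxa; rare taxa (expected study total < 50)
#' and one non-ground-dwelling taxon (Diptera) are added so the filtering
#' rules have something to remove.
#'
#' @param config a [sim_config()].
#' @return a list of class `sim_study` with elements `rainfall`, `soil`,
#'   `veg`, `traps`, `taxa` (data.frames matching the CSV schemas) and
#'   `truth` (the generating lags, coefficients and variance components).
#' @export
gen_study <- function(config) {
  validate_config(config)
  rain <- gen_rainfall(config)
  soil <- gen_plots(config)
  seeds <- derive_seeds(config$seed, 6L)

  with_seed(seeds[3L], {
    years <- config$years
    n_plots <- config$n_plots
    plots <- soil$plot
    groups <- trophic_groups()

    # field campaign dates, shared across plots
    rounds <- do.call(rbind, lapply(years, function(y) {
      r1 <- as.Date(sprintf("%d-03-01", y)) + sample(0:9, 1)
      starts <- r1
      for (r in seq_len(config$rounds_per_year - 1L))
        starts <- c(starts, starts[length(starts)] + 14L + sample(0:6, 1))
      data.frame(year = y, round = seq_len(config$rounds_per_year),
                 start_date = starts)
    }))

    # plot-year dropout, at least 15 plots retained per year
    keep <- expand.grid(plot = plots, year = years,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    min_keep <- min(15L, n_plots)
    repeat {
      keep$kept <- rbinom(nrow(keep), 1L, 1 - config$dropout_rate) == 1L
      n_per_year <- tapply(keep$kept, keep$year, sum)
      if (all(n_per_year >= min_keep)) break
    }

    grid <- merge(keep[keep$kept, c("plot", "year")], rounds, by = "year")
    grid <- grid[order(grid$plot, grid$year, grid$round), ]
    rownames(grid) <- NULL

    # windowed rainfall drivers (standardized over campaign dates)
    zscale <- function(x) {
      s <- sd(x)
      if (!is.finite(s) || s == 0) return(rep(0, length(x)))
      (x - mean(x)) / s
    }
    wdriver <- function(lag) {
      w <- vapply(grid$start_date, function(t0)
        window_sum(rain, t0, width = 7L, offset = lag), numeric(1))
      zscale(w)
    }
    eff <- config$group_effects
    lag <- config$group_lags
    W <- list(plants = wdriver(lag[["plants"]]),
              herbivores = wdriver(lag[["herbivores"]]),
              omnivores = wdriver(lag[["omnivores"]]),
              predators = wdriver(lag[["predators"]]),
              detritivores = wdriver(lag[["detritivores"]]))
    seas <- vapply(grid$year, function(y) seasonal_rainfall(rain, y),
                   numeric(1))
    seas_z <- zscale(seas)
    gravel_z <- zscale(soil$gravel)[match(grid$plot, soil$plot)]

    re_plot <- function() {
      b <- rnorm(n_plots, 0, config$sigma_plot)
      b[match(grid$plot, plots)]
    }
    re_year <- function() {
      u <- rnorm(length(years), 0, config$sigma_year)
      u[match(grid$year, years)]
    }

    # plants: latent log-cover scale; the 0.45 survey-level SD reproduces
    # the large within-year cross-plot cover spread of sparse savannah
    # vegetation (order tenfold between plots in a wet year)
    L_P <- eff[["rain_plants"]] * W$plants + eff[["gravel_plants"]] * gravel_z +
      re_plot() + re_year() + rnorm(nrow(grid), 0, 0.45)
    cover <- pmin(50, pmax(0.1, exp(1.4 + 1.0 * L_P)))
    P_z <- zscale(L_P)

    eta_H <- config$alpha[["herbivores"]] + eff[["rain_herbivores"]] * W$herbivores +
      eff[["plants_herbivores"]] * P_z + re_plot() + re_year()
    H_z <- zscale(eta_H)
    eta_D <- config$alpha[["detritivores"]] + eff[["rain_detritivores"]] * W$detritivores +
      re_plot() + re_year()
    D_z <- zscale(eta_D)
    eta_O <- config$alpha[["omnivores"]] + eff[["rain_omnivores"]] * W$omnivores +
      eff[["plants_omnivores"]] * P_z + eff[["herbivores_omnivores"]] * H_z +
      re_plot() + re_year()
    O_z <- zscale(eta_O)
    eta_Pr <- config$alpha[["predators"]] + eff[["rain_predators"]] * W$predators +
      eff[["herbivores_predators"]] * H_z + eff[["omnivores_predators"]] * O_z +
      eff[["detritivores_predators"]] * D_z + re_plot() + re_year()
    eta_A <- config$alpha[["ants"]] + eff[["season_ants"]] * seas_z +
      eff[["herbivores_ants"]] * H_z + re_plot() + re_year()

    etas <- list(herbivores = eta_H, omnivores = eta_O, predators = eta_Pr,
                 detritivores = eta_D, ants = eta_A)
    counts <- lapply(groups, function(g)
      rnbinom(nrow(grid), mu = exp(etas[[g]]), size = config$theta[[g]]))
    names(counts) <- groups

    # split each group's count into member taxa
    taxa_split <- group_taxa()
    trap_list <- list()
    for (g in groups) {
      props <- taxa_split[[g]]
      if (length(props) == 1L) {
        tc <- matrix(counts[[g]], ncol = 1L,
                     dimnames = list(NULL, names(props)))
      } else {
        tc <- t(vapply(counts[[g]], function(n)
          drop(rmultinom(1, n, props)), numeric(length(props))))
        colnames(tc) <- names(props)
      }
      for (tx in colnames(tc))
        trap_list[[tx]] <- data.frame(grid[c("plot", "year", "round",
                                             "start_date")],
                                      taxon = tx, count = tc[, tx])
    }

    # rare taxa (expected study total well below 50) + a flying taxon
    pool <- rare_taxon_pool()
    n_rare <- min(config$rare_taxon_count, nrow(pool))
    rare <- pool[seq_len(n_rare), , drop = FALSE]
    for (i in seq_len(n_rare)) {
      lam <- 25 / nrow(grid)
      trap_list[[rare$taxon[i]]] <-
        data.frame(grid[c("plot", "year", "round", "start_date")],
                   taxon = rare$taxon[i],
                   count = rpois(nrow(grid), lam))
    }
    trap_list[["Diptera"]] <-
      data.frame(grid[c("plot", "year", "round", "start_date")],
                 taxon = "Diptera",
                 count = rnbinom(nrow(grid), mu = 3, size = 2))

    traps <- do.call(rbind, trap_list)
    traps <- traps[order(traps$plot, traps$year, traps$round, traps$taxon), ]
    rownames(traps) <- NULL

    taxa <- rbind(
      do.call(rbind, lapply(groups, function(g)
        data.frame(taxon = names(taxa_split[[g]]), trophic_group = g,
                   ground_dwelling = TRUE))),
      if (n_rare > 0L)
        data.frame(taxon = rare$taxon, trophic_group = rare$trophic_group,
                   ground_dwelling = TRUE),
      data.frame(taxon = "Diptera", trophic_group = "omnivores",
                 ground_dwelling = FALSE))
    rownames(taxa) <- NULL

    grass_frac <- rbeta(nrow(grid), 6, 2)
    veg <- data.frame(grid[c("plot", "year", "round")],
                      total_cover = round(cover, 1),
                      herb_cover = round(cover * (1 - grass_frac) * 0.95, 1),
                      grass_cover = round(cover * grass_frac * 0.95, 1),
                      n_species = 1L + rpois(nrow(grid),
                                             2 + 1.5 * log1p(cover)))

    truth <- list(true_lags = config$group_lags,
                  true_coefficients = config$group_effects,
                  true_sigma_plot = config$sigma_plot,
                  true_sigma_year = config$sigma_year,
                  true_theta = config$theta)

    structure(list(rainfall = rain, soil = soil, veg = veg, traps = traps,
                   taxa = taxa, truth = truth, config = config),
              class = "sim_study")
  })
}

#' @export
print.sim_study <- function(x, ...) {
  cat("Synthetic arid-savannah pitfall study\n")
  cat(sprintf("  %d plots x %d years, %d trap rows, %d taxa\n",
              x$config$n_plots, length(x$config$years), nrow(x$traps),
              nrow(x$taxa)))
  invisible(x)
}
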