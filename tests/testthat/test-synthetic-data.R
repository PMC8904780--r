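test_that("the generator is deterministic under a fixed seed", {
  s1 <- gen_study(sim_config(seed = 42))
  s2 <- gen_study(sim_config(seed = 42))
  expect_identical(s1$rainfall, s2$rainfall)
  expect_identical(s1$traps, s2$traps)
  expect_identical(s1$veg, s2$veg)
  d1 <- file.path(tempdir(), "study_a"); d2 <- file.path(tempdir(), "study_b")
  write_study(s1, d1); write_study(s2, d2)
  for (f in list.files(d1))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  s3 <- gen_study(sim_config(seed = 43))
  expect_false(identical(s1$traps$count, s3$traps$count))
})

test_that("rainfall series is contiguous, nonnegative, half-mm and seasonal", {
  rain <- gen_rainfall(sim_config(seed = 3))
  expect_true(all(diff(rain$date) == 1))
  expect_true(all(rain$mm >= 0))
  expect_true(all(rain$mm * 2 == round(rain$mm * 2)))
  # bulk of rain in the Oct-Apr season, peak around Feb-Mar
  mon <- as.integer(format(rain$date, "%m"))
  expect_equal(sum(rain$mm[mon %in% 5:9]), 0)
  expect_gt(sum(rain$mm[mon %in% 2:3]), sum(rain$mm[mon %in% c(10, 11)]))
})

test_that("degenerate seasonal dispersion pins every year at the mean", {
  cfg <- sim_config(seed = 5, seasonal_cv = 0)
  rain <- gen_rainfall(cfg)
  for (y in cfg$years)
    expect_lt(abs(seasonal_rainfall(rain, y) - 56) / 56, 0.01)
})

test_that("seasonal totals are centered on the configured mean", {
  # scaled-down Monte Carlo: 6 series x 40 years = 240 replicate years
  totals <- unlist(lapply(1:6, function(s) {
    cfg <- sim_config(seed = s, years = 1981:2020)
    rain <- gen_rainfall(cfg)
    vapply(cfg$years, function(y) seasonal_rainfall(rain, y), numeric(1))
  }))
  se <- sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - 56), 2 * se)
})

test_that("empty year list is a configuration error", {
  expect_error(sim_config(years = integer(0)), "configuration")
  expect_error(sim_config(group_lags = c(plants = 40L, herbivores = 15L,
                                         omnivores = 24L, predators = 15L,
                                         detritivores = 15L,
                                         ants = NA_integer_)),
               "lags")
})

test_that("soil fractions close to 100 with sand-dominated ordering", {
  for (seed in c(1, 9)) {
    soil <- gen_plots(sim_config(seed = seed))
    expect_equal(nrow(soil), 30L)
    expect_equal(rowSums(soil[, -1]), rep(100, 30), tolerance = 1e-9)
    expect_gt(median(soil$sand), median(soil$gravel))
    expect_gt(median(soil$gravel), median(soil$cobble))
  }
})

test_that("study counts are integer, trap dates in Mar-early Apr, panels unbalanced within bounds", {
  st <- gen_study(sim_config(seed = 1))
  expect_true(all(st$traps$count >= 0))
  expect_true(all(st$traps$count == round(st$traps$count)))
  mon <- as.integer(format(st$traps$start_date, "%m"))
  day <- as.integer(format(st$traps$start_date, "%d"))
  expect_true(all(mon == 3 | (mon == 4 & day <= 10)))
  # both rounds of a plot-year at least 14 days apart
  key <- paste(st$traps$plot, st$traps$year)
  gap <- tapply(as.integer(st$traps$start_date), key,
                function(d) diff(range(d)))
  expect_true(all(gap >= 14))
  n_per_year <- tapply(st$traps$plot, st$traps$year,
                       function(p) length(unique(p)))
  expect_true(all(n_per_year >= 15 & n_per_year <= 30))
})

test_that("group counts are overdispersed when theta is small", {
  st <- gen_study(sim_config(seed = 2))
  rt <- rounds_table(st$traps, st$taxa)
  for (g in c("herbivores", "omnivores", "predators", "detritivores",
              "ants"))
    expect_gt(var(rt[[g]]), mean(rt[[g]]))
})

test_that("rare and flying taxa exist for the filters to remove", {
  st <- gen_study(sim_config(seed = 1))
  totals <- tapply(st$traps$count, st$traps$taxon, sum)
  rare <- names(totals)[totals < 50]
  expect_gte(length(rare), 1L)
  expect_false(all(st$taxa$ground_dwelling))
  expect_identical(sort(unique(st$traps$taxon)), sort(st$taxa$taxon))
})

test_that("a fully nulled generator yields year-exchangeable counts", {
  # Kruskal-Wallis across years should reject at about its nominal level
  n_seeds <- 60
  ok <- vapply(seq_len(n_seeds), function(s) {
    st <- gen_study(null_config(seed = 1000 + s, sigma_plot = 0,
                                n_plots = 10L))
    rt <- rounds_table(st$traps, st$taxa)
    p <- kruskal.test(rt$herbivores, factor(rt$year))$p.value
    p > 0.01
  }, logical(1))
  expect_gte(mean(ok), 0.95 - 2 * sqrt(0.05 * 0.95 / n_seeds))
})

test_that("the truth record echoes the generating configuration", {
  cfg <- sim_config(seed = 4, sigma_plot = 0.3)
  st <- gen_study(cfg)
  expect_identical(st$truth$true_lags, cfg$group_lags)
  expect_identical(st$truth$true_coefficients, cfg$group_effects)
  expect_identical(st$truth$true_sigma_plot, 0.3)
})
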