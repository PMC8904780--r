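test_that("the cascade design encodes the bottom-up wiring exactly", {
  d <- cascade_design()
  expect_identical(d$plants, c("seasonal_rainfall", "gravel", "cobble"))
  expect_false("plants" %in% d$predators)      # predators: no plants
  expect_false("omnivores" %in% d$ants)        # no top-down leakage
  expect_true(all(c("herbivores", "omnivores", "detritivores") %in%
                    d$predators))
  expect_identical(d$herbivores, d$detritivores)
})

test_that("NT cells carry no estimate and tested sets match the design", {
  st <- gen_study(small_config(seed = 1))
  ret <- filter_taxa(st$traps, st$taxa)
  rec <- aggregate_records(st$traps, st$veg, st$soil, st$rainfall,
                           st$taxa, ret)
  cs <- fit_cascade(rec)
  d <- cascade_design()
  for (resp in names(d)) {
    sub <- cs[cs$response == resp, ]
    expect_setequal(sub$covariate[!sub$nt], d[[resp]])
    expect_true(all(is.na(sub$estimate[sub$nt])))
    fit <- attr(cs, "fits")[[resp]]
    expect_identical(setdiff(fit$fixed, "year_cov"),
                     paste0("cov_", d[[resp]]))
  }
  tab <- render_cascade_table(cs)
  expect_equal(tab["plants", "predators"], "NT")
  expect_equal(tab["omnivores", "plants"], "NT")
})

test_that("cell formatting follows the star convention", {
  expect_equal(aridpulse:::format_cascade_cell(3.61, 4e-04, FALSE),
               "3.61***")
  expect_equal(aridpulse:::format_cascade_cell(-5.76, 0.0005, FALSE),
               "-5.76***")
  expect_equal(aridpulse:::format_cascade_cell(2.40, 0.004, FALSE),
               "2.40**")
  expect_equal(aridpulse:::format_cascade_cell(1.98, 0.03, FALSE),
               "1.98*")
  expect_equal(aridpulse:::format_cascade_cell(1.2, 0.2, FALSE), "n.s")
  expect_equal(aridpulse:::format_cascade_cell(NA, NA, TRUE), "NT")
})

test_that("row order of the records does not change the estimates", {
  st <- gen_study(small_config(seed = 2))
  ret <- filter_taxa(st$traps, st$taxa)
  rec <- aggregate_records(st$traps, st$veg, st$soil, st$rainfall,
                           st$taxa, ret)
  cs1 <- fit_cascade(rec)
  set.seed(1)
  cs2 <- fit_cascade(rec[sample(nrow(rec)), ])
  expect_equal(cs1$estimate, cs2$estimate, tolerance = 1e-6)
})

test_that("the planted plants-to-herbivores link is detected above chance", {
  # Annual-resolution attribution of the plant link is confounded when
  # the plant (8 d) and herbivore (15 d) rainfall windows decorrelate
  # across the six years by chance, so single realizations can even go
  # negative -- the same mechanism that lets a field study print a
  # negative seasonal-rainfall cell next to a positive plants cell.
  # Across seeds the estimate distribution must be centred positive and
  # detected far above the 2.5% chance rate for positive-significant
  # cells under a true null.
  res <- vapply(1:10, function(s) {
    st <- gen_study(sim_config(seed = 100 + s))
    ret <- filter_taxa(st$traps, st$taxa)
    rec <- aggregate_records(st$traps, st$veg, st$soil, st$rainfall,
                             st$taxa, ret)
    cs <- fit_cascade(rec)
    cell <- cs[cs$response == "herbivores" & cs$covariate == "plants", ]
    c(est = cell$estimate,
      hit = as.numeric(cell$estimate > 0 && cell$p_value < 0.05))
  }, numeric(2))
  expect_gt(median(res["est", ]), 0)
  # P(>=3 hits in 10 | null) ~ 2e-3 at the 2.5% per-seed chance rate
  expect_gte(sum(res["hit", ]), 3)
})

test_that("the cascade attributes the link correctly once pulse timing is controlled", {
  # oracle check, possible only in simulation: adding the herbivore's
  # true lag-15 rainfall window as a control removes the confounding
  # and the plants cell is positive
  est <- p <- numeric(6)
  for (s in 1:6) {
    st <- gen_study(sim_config(seed = 100 + s))
    ret <- filter_taxa(st$traps, st$taxa)
    rec <- aggregate_records(st$traps, st$veg, st$soil, st$rainfall,
                             st$taxa, ret)
    rounds <- rounds_table(st$traps, st$taxa, ret)
    rounds$W15 <- window_sum(st$rainfall, rounds$start_date, 7, 15)
    agg <- aggregate(list(W15 = rounds$W15),
                     by = list(plot = rounds$plot, year = rounds$year),
                     FUN = mean)
    d <- merge(rec, agg, by = c("plot", "year"))
    d$year_cov <- d$year - mean(d$year)
    for (v in c("seasonal_rainfall", "gravel", "cobble", "W15"))
      d[[paste0("cov_", v)]] <- as.numeric(scale(d[[v]]))
    d$cov_plants <- as.numeric(scale(log1p(d$plant_cover)))
    fit <- fit_nb_glmm("herbivores",
                       c("cov_seasonal_rainfall", "cov_gravel",
                         "cov_cobble", "cov_plants", "cov_W15",
                         "year_cov"), d)
    est[s] <- fit$beta[["cov_plants"]]
    p[s] <- fit$p_value[["cov_plants"]]
  }
  expect_gte(sum(est > 0 & p < 0.05), 5)
})
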