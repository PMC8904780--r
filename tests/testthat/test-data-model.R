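test_that("seasonal rainfall sums Feb 1 through Mar 31 inclusive", {
  expect_equal(seasonal_rainfall(flat_rain(2015), 2015), 59)  # 28 + 31
  expect_equal(seasonal_rainfall(flat_rain(2016), 2016), 60)  # leap year
  expect_equal(seasonal_rainfall(flat_rain(2015, mm = 0), 2015), 0)
})

test_that("rainfall gaps are reported by name", {
  rain <- flat_rain(2015)
  expect_error(seasonal_rainfall(rain[-100, ], 2015), "gap")
  short <- rain[rain$date >= as.Date("2015-03-01"), ]
  expect_error(seasonal_rainfall(short, 2015), "Feb-Mar 2015")
})

test_that("taxon filter applies the strict <50 rule and the ground-dwelling flag", {
  traps <- tiny_traps()
  taxa <- tiny_taxa()
  # Cicadina total 18, Collembola 10 with min_total 50 -> both out
  expect_identical(filter_taxa(traps, taxa), character(0))
  # boundary: 49 excluded, exactly 50 retained
  t2 <- traps
  t2$count[t2$taxon == "Cicadina"] <- c(20L, 20L, 4L, 5L)   # total 49
  t2$count[t2$taxon == "Collembola"] <- c(20L, 20L, 5L, 5L) # total 50
  expect_identical(filter_taxa(t2, taxa), "Collembola")
  # a huge non-ground-dwelling taxon is still excluded
  t3 <- rbind(t2, data.frame(plot = "A", year = 2015L, round = 1L,
                             start_date = as.Date("2015-03-05"),
                             taxon = "Diptera", count = 10000L))
  taxa3 <- rbind(taxa, data.frame(taxon = "Diptera",
                                  trophic_group = "omnivores",
                                  ground_dwelling = FALSE))
  expect_identical(filter_taxa(t3, taxa3), "Collembola")
  expect_identical(filter_taxa(traps[0, ], taxa), character(0))
  expect_error(filter_taxa(t3, taxa), "Diptera")
})

test_that("aggregation sums counts over rounds and takes max vegetation", {
  rec <- aggregate_records(tiny_traps(), tiny_veg(), tiny_soil(),
                           flat_rain(2015), tiny_taxa(),
                           retained = c("Cicadina", "Collembola"))
  a <- rec[rec$plot == "A", ]
  expect_equal(a$herbivores, 3L + 4L)
  expect_equal(a$taxon_Collembola, 5L + 6L)
  expect_equal(a$plant_cover, 24)
  expect_equal(a$n_rounds, 2L)
  expect_equal(a$seasonal_rainfall, 59)
  expect_equal(a$gravel, 25)
  # single-round plot-year keeps a record with n_rounds = 1
  tr1 <- tiny_traps()
  tr1 <- tr1[!(tr1$plot == "B" & tr1$round == 2), ]
  rec1 <- aggregate_records(tr1, tiny_veg(), tiny_soil(), flat_rain(2015),
                            tiny_taxa(), c("Cicadina", "Collembola"))
  expect_equal(rec1$n_rounds[rec1$plot == "B"], 1L)
})

test_that("orphan vegetation surveys warn and missing cover is flagged", {
  veg <- rbind(tiny_veg(),
               data.frame(plot = "C", year = 2015L, round = 1L,
                          total_cover = 9, herb_cover = 1, grass_cover = 7,
                          n_species = 2L))
  expect_warning(
    aggregate_records(tiny_traps(), veg, tiny_soil(), flat_rain(2015),
                      tiny_taxa(), c("Cicadina", "Collembola")),
    "without trap events")
  veg_missing <- tiny_veg()[tiny_veg()$plot != "B", ]
  expect_warning(
    rec <- aggregate_records(tiny_traps(), veg_missing, tiny_soil(),
                             flat_rain(2015), tiny_taxa(),
                             c("Cicadina", "Collembola")),
    "NA")
  expect_true(is.na(rec$plant_cover[rec$plot == "B"]))
})

test_that("site-taxa matrix has the expected shape and drops empty sites", {
  st <- gen_study(small_config(seed = 2))
  ret <- filter_taxa(st$traps, st$taxa)
  rec <- aggregate_records(st$traps, st$veg, st$soil, st$rainfall,
                           st$taxa, ret)
  M <- build_matrix(rec)
  expect_lte(nrow(M), nrow(rec))
  expect_equal(ncol(M), length(ret))
  # conservation: matrix total equals retained individuals in the traps
  tr <- st$traps[st$traps$taxon %in% ret, ]
  expect_equal(sum(M), sum(tr$count))
  expect_true(all(M >= 0))
  # degenerate inputs
  rec0 <- rec[1:2, ]
  expect_error(build_matrix(rec0), "at least 3")
  recz <- rec
  taxcols <- grep("^taxon_", names(recz))
  recz[1, taxcols] <- 0L
  expect_warning(Mz <- build_matrix(recz), "empty site")
  expect_equal(nrow(Mz), nrow(recz) - 1L)
})

test_that("CSV schemas round-trip exactly and validate on read", {
  st <- gen_study(small_config(seed = 3))
  dir <- file.path(tempdir(), "roundtrip")
  write_study(st, dir)
  back <- read_study(dir)
  expect_equal(back$rainfall, st$rainfall)
  expect_equal(back$traps, st$traps)
  expect_equal(back$veg, st$veg)
  expect_equal(back$soil, st$soil)
  expect_equal(back$taxa, st$taxa)
  # header and type validation
  bad <- st$traps; names(bad)[6] <- "n"
  f <- tempfile(fileext = ".csv"); write.csv(bad, f, row.names = FALSE)
  expect_error(read_study_csv(f, "traps"), "missing column")
  bad2 <- st$traps; bad2$count <- as.character(bad2$count)
  bad2$count[3] <- "many"
  write.csv(bad2, f, row.names = FALSE)
  expect_error(read_study_csv(f, "traps"), "row 3")
  expect_error(read_study_csv(file.path(dir, "nope.csv"), "traps"),
               "not found")
})
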