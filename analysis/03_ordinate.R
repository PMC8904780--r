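#!/usr/bin/env Rscript
# Community ordination: column-normalized site-taxa matrix, Bray-Curtis
# dissimilarity, 2-D NMDS (20 restarts), envfit with 1000 permutations,
# and sequential-SS PERMANOVA over rainfall, plant cover, soil and year.
# Reads results/data/ and results/plotyears.csv; writes NMDS scores,
# envfit table and PERMANOVA table under results/.

library(aridpulse)

study <- read_study("results/data")
retained_taxa <- filter_taxa(study$traps, study$taxa)
records <- aggregate_records(study$traps, study$veg, study$soil,
                             study$rainfall, study$taxa, retained_taxa)

M <- build_matrix(records)
idx <- match(rownames(M), paste(records$plot, records$year, sep = "_"))
env <- records[idx, ]
env$year_f <- factor(env$year)

D <- bray_curtis(normalize_columns(M))
ord <- nmds(D, k = 2, n_restarts = 20, seed = 101)
print(ord)
write.csv(data.frame(site = rownames(ord$scores), ord$scores),
          "results/nmds_scores.csv", row.names = FALSE)

ef <- envfit_table(ord$scores, env[reference_covariates()],
                   n_perm = 1000, seed = 102)
cat("\nEnvironmental vectors fitted onto the ordination:\n")
print(transform(ef, r2 = round(r2, 3)))
write.csv(ef, "results/envfit.csv", row.names = FALSE)

pt <- permanova(D, env, c(reference_covariates(), "year_f"),
                n_perm = 999, seed = 103)
cat("\nPERMANOVA (sequential SS):\n")
print(as.data.frame(pt))
write.csv(as.data.frame(pt), "results/permanova.csv", row.names = FALSE)

r2_env <- sum(pt$R2[pt$term %in% c("seasonal_rainfall", "plant_cover")])
r2_year <- pt$R2[pt$term == "year_f"]
cat(sprintf(paste0("\nRainfall + plant cover explain %.0f%% of community",
                   " variance; inter-annual term %.0f%%\n"),
            100 * r2_env, 100 * r2_year))
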