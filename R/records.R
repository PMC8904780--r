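check_rainfall_series <- function(series) {
  stopifnot(is.data.frame(series), all(c("date", "mm") %in% names(series)))
  d <- as.integer(diff(series$date))
  if (any(d != 1L)) {
    i <- which(d != 1L)[1]
    stop(sprintf("rainfall series has a gap: %s to %s",
                 series$date[i], series$date[i + 1L]), call. = FALSE)
  }
  if (any(series$mm < 0))
    stop("rainfall series has negative amounts", call. = FALSE)
  invisible(series)
}

#' Seasonal (February--March) rainfall total
#'
#' Sum of daily rainfall from 1 February through 31 March of `year`
#' inclusive -- the main-growing-season total used as the seasonal
#' covariate throughout the analysis.
#'
#' @param series daily rainfall data.frame (`date`, `mm`), contiguous.
#' @param year calendar year.
#' @return total rainfall in mm.
#' @export
seasonal_rainfall <- function(series, year) {
  check_rainfall_series(series)
  from <- as.Date(sprintf("%d-02-01", year))
  to <- as.Date(sprintf("%d-03-31", year))
  want <- seq(from, to, by = "day")
  missing <- want[!want %in% series$date]
  if (length(missing))
    stop(sprintf("rainfall series misses %d day(s) in Feb-Mar %d (first: %s)",
                 length(missing), year, missing[1]), call. = FALSE)
  sum(series$mm[series$date >= from & series$date <= to])
}

#' Taxon retention filter
#'
#' Retains taxa that are predominantly ground-dwelling and whose summed
#' activity density over the whole study reaches `min_total` individuals.
#' Exclusion is strict: a study total of `min_total - 1` drops the taxon,
#' exactly `min_total` keeps it.
#'
#' @param traps long-format trap counts (`plot`, `year`, `round`,
#'   `start_date`, `taxon`, `count`).
#' @param taxa taxon metadata (`taxon`, `trophic_group`, `ground_dwelling`).
#' @param min_total minimum study-wide total (default 50).
#' @return character vector of retained taxon names.
#' @export
filter_taxa <- function(traps, taxa, min_total = 50L) {
  if (nrow(traps) == 0L) return(character(0))
  unknown <- setdiff(unique(traps$taxon), taxa$taxon)
  if (length(unknown))
    stop(sprintf("taxon without metadata: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  totals <- tapply(traps$count, traps$taxon, sum)
  ground <- taxa$taxon[taxa$ground_dwelling]
  keep <- names(totals)[totals >= min_total & names(totals) %in% ground]
  sort(keep)
}

group_of <- function(taxa) setNames(taxa$trophic_group, taxa$taxon)

#' Per-round counts by trophic group and taxon
#'
#' The modelling table for the moving-window scan: one row per plot, year
#' and trapping round, with the trap start date, the summed activity
#' density of each trophic group (over retained taxa) and each retained
#' taxon's count.
#'
#' @param traps long-format trap counts.
#' @param taxa taxon metadata.
#' @param retained retained taxon names, e.g. from [filter_taxa()].
#' @return data.frame with columns `plot`, `year`, `round`, `start_date`,
#'   one column per trophic group and one per retained taxon.
#' @export
rounds_table <- function(traps, taxa, retained = filter_taxa(traps, taxa)) {
  tr <- traps[traps$taxon %in% retained, , drop = FALSE]
  key <- interaction(tr$plot, tr$year, tr$round, drop = TRUE)
  base <- tr[!duplicated(key), c("plot", "year", "round", "start_date")]
  base <- base[order(base$plot, base$year, base$round), ]
  rownames(base) <- NULL
  bkey <- paste(base$plot, base$year, base$round)
  tkey <- paste(tr$plot, tr$year, tr$round)
  grp <- group_of(taxa)
  for (g in unique(grp[retained])) {
    members <- retained[grp[retained] == g]
    sub <- tr[tr$taxon %in% members, ]
    s <- tapply(sub$count, paste(sub$plot, sub$year, sub$round), sum)
    base[[g]] <- as.integer(ifelse(is.na(s[bkey]), 0L, s[bkey]))
  }
  for (tx in retained) {
    sub <- tr[tr$taxon == tx, ]
    s <- tapply(sub$count, paste(sub$plot, sub$year, sub$round), sum)
    base[[tx]] <- as.integer(ifelse(is.na(s[bkey]), 0L, s[bkey]))
  }
  base
}

#' Aggregate to analysis-ready plot-year records
#'
#' One record per plot-year with at least one trapping round: taxon and
#' trophic-group activity densities summed over rounds (removing
#' intra-seasonal variability), vegetation parameters taken as the
#' per-plot-year maximum over surveys, soil texture joined by plot and the
#' seasonal (Feb--Mar) rainfall joined by year.
#'
#' @param traps long-format trap counts.
#' @param veg per-round vegetation surveys.
#' @param soil plot soil textures.
#' @param rainfall daily rainfall series.
#' @param taxa taxon metadata.
#' @param retained retained taxon names.
#' @return data.frame of plot-year records; taxon densities are in columns
#'   prefixed `"taxon_"`, trophic-group densities in columns named after
#'   the group.
#' @export
aggregate_records <- function(traps, veg, soil, rainfall, taxa,
                              retained = filter_taxa(traps, taxa)) {
  rt <- rounds_table(traps, taxa, retained)
  groups <- unique(group_of(taxa)[retained])
  agg <- aggregate(rt[c(groups, retained)],
                   by = list(plot = rt$plot, year = rt$year), FUN = sum)
  nr <- aggregate(list(n_rounds = rt$round),
                  by = list(plot = rt$plot, year = rt$year),
                  FUN = length)
  rec <- merge(agg, nr, by = c("plot", "year"))

  vkey <- paste(veg$plot, veg$year)
  rkey <- paste(rec$plot, rec$year)
  orphan_veg <- setdiff(unique(vkey), rkey)
  if (length(orphan_veg))
    warning(sprintf("%d vegetation survey plot-year(s) without trap events",
                    length(orphan_veg)))
  vmax <- aggregate(veg[c("total_cover", "herb_cover", "grass_cover",
                          "n_species")],
                    by = list(plot = veg$plot, year = veg$year), FUN = max)
  names(vmax)[names(vmax) == "total_cover"] <- "plant_cover"
  rec <- merge(rec, vmax, by = c("plot", "year"), all.x = TRUE)
  if (anyNA(rec$plant_cover))
    warning("plot-year(s) without vegetation survey: cover set to NA")

  rec <- merge(rec, soil, by = "plot")
  seas <- vapply(sort(unique(rec$year)),
                 function(y) seasonal_rainfall(rainfall, y), numeric(1))
  rec$seasonal_rainfall <- seas[match(rec$year, sort(unique(rec$year)))]
  names(rec)[names(rec) %in% retained] <- paste0("taxon_", retained)
  rec <- rec[order(rec$plot, rec$year), ]
  rownames(rec) <- NULL
  rec
}

#' Build the site-by-taxa matrix
#'
#' Dense matrix of activity densities with plot-years as rows (named
#' `plot_year`) and retained taxa as columns. All-zero rows are dropped
#' with a warning because Bray--Curtis dissimilarity is undefined for
#' empty sites.
#'
#' @param records plot-year records from [aggregate_records()].
#' @return numeric matrix (sites x taxa).
#' @export
build_matrix <- function(records) {
  taxcols <- grep("^taxon_", names(records), value = TRUE)
  if (nrow(records) < 3L)
    stop("need at least 3 plot-year records for ordination", call. = FALSE)
  if (length(taxcols) < 2L)
    stop("need at least 2 retained taxa", call. = FALSE)
  M <- as.matrix(records[taxcols])
  colnames(M) <- sub("^taxon_", "", taxcols)
  rownames(M) <- paste(records$plot, records$year, sep = "_")
  zero <- rowSums(M) == 0
  if (any(zero)) {
    warning(sprintf("dropping %d empty site(s): %s", sum(zero),
                    paste(rownames(M)[zero], collapse = ", ")))
    M <- M[!zero, , drop = FALSE]
  }
  M
}
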