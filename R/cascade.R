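#' Bottom-up trophic-cascade model design
#'
#' Which covariates are tested for each response under the classical
#' bottom-up wiring: every model tests seasonal rainfall and soil texture
#' (gravel, cobble); herbivores and detritivores additionally test plant
#' cover; omnivores test plant cover plus herbivore and detritivore
#' activity density; predators test herbivore, omnivore and detritivore
#' activity density (no plants); ants test plant cover plus herbivore and
#' detritivore activity density. Covariates absent from a model are "not
#' tested" (NT) -- top-down links are deliberately excluded.
#'
#' @return named list: response -> character vector of tested covariates.
#' @export
cascade_design <- function() {
  soil <- c("seasonal_rainfall", "gravel", "cobble")
  list(
    plants = soil,
    herbivores = c(soil, "plants"),
    omnivores = c(soil, "plants", "herbivores", "detritivores"),
    predators = c(soil, "herbivores", "omnivores", "detritivores"),
    detritivores = c(soil, "plants"),
    ants = c(soil, "plants", "herbivores", "detritivores"))
}

cascade_covariate_order <- function() {
  c("seasonal_rainfall", "gravel", "cobble", "plants", "herbivores",
    "omnivores", "detritivores")
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "")))
}

#' Fit the trophic-cascade GLMM suite
#'
#' One NB mixed model per response (plot random intercept, year as a
#' centered numeric covariate), with each response's covariate set taken
#' from the bottom-up design. Plant cover enters as a response via the
#' x10-rounded count scale and as a covariate on its raw percent scale;
#' activity-density covariates are log(x+1)-transformed; all covariates
#' are z-scored before fitting (so estimates are comparable across
#' covariates) unless `standardize = FALSE`.
#'
#' @param records plot-year records from [aggregate_records()].
#' @param design model wiring, default [cascade_design()].
#' @param standardize z-score covariates before fitting (default TRUE).
#' @param engine model engine, see [fit_nb_glmm()].
#' @param cover_scale multiplier for the plant-cover response (default 10).
#' @return object of class `cascade_summary`: long data.frame with one
#'   row per response x covariate cell (`estimate`, `se`, `z`, `p_value`,
#'   `stars`, `nt`, `converged`), plus the fits as an attribute.
#' @export
fit_cascade <- function(records, design = cascade_design(),
                        standardize = TRUE, engine = "glmmTMB",
                        cover_scale = 10) {
  d <- records
  d$plants_response <- as.integer(round(d$plant_cover * cover_scale))
  d$year_cov <- d$year - mean(d$year)
  # covariate columns on the modelling scale
  cov_col <- function(v) {
    x <- switch(v,
      plants = d$plant_cover,
      herbivores = log1p(d$herbivores),
      omnivores = log1p(d$omnivores),
      detritivores = log1p(d$detritivores),
      d[[v]])
    if (standardize) as.numeric(scale(x)) else x
  }
  covs <- cascade_covariate_order()
  for (v in covs) d[[paste0("cov_", v)]] <- cov_col(v)

  fits <- list()
  rows <- list()
  for (resp in names(design)) {
    tested <- design[[resp]]
    stopifnot(all(tested %in% covs))
    fixed <- c(paste0("cov_", tested), "year_cov")
    resp_col <- if (resp == "plants") "plants_response" else resp
    fit <- fit_nb_glmm(resp_col, fixed, d, group = "plot", engine = engine)
    fits[[resp]] <- fit
    for (v in covs) {
      nt <- !(v %in% tested)
      if (nt) {
        rows[[length(rows) + 1L]] <- data.frame(
          response = resp, covariate = v, estimate = NA_real_,
          se = NA_real_, z = NA_real_, p_value = NA_real_,
          stars = "", nt = TRUE, converged = fit$converged)
      } else {
        cn <- paste0("cov_", v)
        rows[[length(rows) + 1L]] <- data.frame(
          response = resp, covariate = v,
          estimate = fit$beta[[cn]], se = fit$se[[cn]], z = fit$z[[cn]],
          p_value = fit$p_value[[cn]],
          stars = significance_stars(fit$p_value[[cn]]),
          nt = FALSE, converged = fit$converged)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  attr(out, "standardize") <- standardize
  class(out) <- c("cascade_summary", "data.frame")
  out
}

format_cascade_cell <- function(estimate, p_value, nt) {
  if (nt) return("NT")
  if (is.na(p_value) || p_value >= 0.05) return("n.s")
  sprintf("%.2f%s", estimate, significance_stars(p_value))
}

#' Render the cascade summary as a starred table
#'
#' Rows are covariates (seasonal rainfall, gravel, cobble, plants,
#' herbivores, omnivores, detritivores), columns responses. Cells show
#' the signed estimate with significance stars (* P < 0.05, ** P < 0.01,
#' *** P < 0.001), "n.s" for non-significant tested covariates, and "NT"
#' for covariates not tested in that model.
#'
#' @param summary a `cascade_summary` from [fit_cascade()].
#' @return character matrix (covariates x responses).
#' @export
render_cascade_table <- function(summary) {
  covs <- cascade_covariate_order()
  resps <- unique(summary$response)
  out <- matrix("", length(covs), length(resps),
                dimnames = list(covs, resps))
  for (i in seq_len(nrow(summary))) {
    r <- summary[i, ]
    out[r$covariate, r$response] <-
      format_cascade_cell(r$estimate, r$p_value, r$nt)
  }
  out
}

#' @export
print.cascade_summary <- function(x, ...) {
  cat("Bottom-up trophic-cascade GLMM suite",
      if (attr(x, "standardize")) "(standardized covariates)" else "",
      "\n")
  print(render_cascade_table(x), quote = FALSE)
  invisible(x)
}
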