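#' Windowed rainfall sum before a trapping date
#'
#' Sum of daily rainfall over the `width` days ending `offset` days
#' before the trap start `t0`, i.e. days t0 - offset - width through
#' t0 - offset - 1 inclusive. Offset 0 means the window ends the day
#' before trapping starts; rain falling during the trapping period is
#' never counted.
#'
#' @param series daily rainfall data.frame (`date`, `mm`), contiguous.
#' @param t0 trap start date(s) (Date), recycled against nothing --
#'   vectorized over `t0`.
#' @param width window width in days (>= 1).
#' @param offset whole days between window end and trap start (>= 0).
#' @return numeric vector of rainfall sums (mm), one per `t0`.
#' @export
window_sum <- function(series, t0, width, offset) {
  stopifnot(width >= 1L, offset >= 0L)
  check_rainfall_series(series)
  t0 <- as.Date(t0)
  first_needed <- min(t0) - offset - width
  last_needed <- max(t0) - offset - 1
  if (first_needed < min(series$date) || last_needed > max(series$date)) {
    want <- seq(first_needed, last_needed, by = "day")
    missing <- want[!want %in% series$date]
    stop(sprintf("rainfall history insufficient: missing %s .. %s",
                 min(missing), max(missing)), call. = FALSE)
  }
  cum <- c(0, cumsum(series$mm))
  idx <- function(d) as.integer(d - series$date[1]) + 1L
  # sum over [t0 - offset - width, t0 - offset - 1]
  cum[idx(t0 - offset)] - cum[idx(t0 - offset - width)]
}

#' Moving-window critical-rainfall-window scan
#'
#' For every combination of window width and offset, builds the windowed
#' rainfall covariate per trapping round and fits the NB mixed model
#' `response ~ windowed_rain + year + (1 | plot)`, recording the
#' deviance-based adjusted R-squared against an intercept-only null.
#' The offset at which R-squared peaks locates the critical window: the
#' period before trapping during which rainfall best explains the
#' response. Each sampling round is a separate observation to keep the
#' temporal resolution at its maximum.
#'
#' @param rounds per-round table from [rounds_table()] (one row per plot,
#'   year and round, with `start_date` and the response column).
#' @param rainfall daily rainfall series.
#' @param response name of the count column to model.
#' @param widths window widths in days (default `c(7, 14, 30)`).
#' @param offsets window offsets in days (default `0:30`).
#' @param year_as `"factor"` (default) or `"numeric"` (centered). The
#'   windowed covariate varies within year (two rounds), so a year
#'   factor is identifiable here and absorbs inter-annual variation
#'   completely; the cascade models use numeric year instead because
#'   seasonal rainfall is constant within a year.
#' @param group random-intercept grouping column.
#' @param engine model engine, see [fit_nb_glmm()].
#' @return data.frame of class `scan_profile`: one row per (width,
#'   offset) with `r2_adj`, `r2`, `beta_rain`, `z_rain`, `converged`.
#' @export
scan_windows <- function(rounds, rainfall, response,
                         widths = c(7L, 14L, 30L), offsets = 0:30,
                         year_as = c("numeric", "factor"),
                         group = "plot", engine = "glmmTMB") {
  year_as <- match.arg(year_as)
  stopifnot(response %in% names(rounds), "start_date" %in% names(rounds))
  d <- rounds
  d$year_cov <- if (year_as == "factor") factor(d$year)
                else d$year - mean(d$year)
  null_fit <- fit_nb_glmm(response, character(0), d, group = group,
                          engine = engine)
  cells <- expand.grid(offset = offsets, width = widths,
                       KEEP.OUT.ATTRS = FALSE)[, c("width", "offset")]
  res <- lapply(seq_len(nrow(cells)), function(i) {
    w <- cells$width[i]; k <- cells$offset[i]
    d$rain_w <- window_sum(rainfall, d$start_date, w, k)
    if (sd(d$rain_w) == 0)
      return(data.frame(width = w, offset = k, r2_adj = NA_real_,
                        r2 = NA_real_, beta_rain = NA_real_,
                        z_rain = NA_real_, converged = FALSE))
    fit <- tryCatch(
      fit_nb_glmm(response, c("rain_w", "year_cov"), d, group = group,
                  engine = engine),
      error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(width = w, offset = k, r2_adj = NA_real_,
                        r2 = NA_real_, beta_rain = NA_real_,
                        z_rain = NA_real_, converged = FALSE))
    r2 <- adjusted_r2(fit, null_fit)
    data.frame(width = w, offset = k, r2_adj = r2$r2_adj, r2 = r2$r2,
               beta_rain = fit$beta[["rain_w"]],
               z_rain = fit$z[["rain_w"]], converged = fit$converged)
  })
  out <- do.call(rbind, res)
  if (!any(out$converged))
    stop("no window model converged", call. = FALSE)
  attr(out, "response") <- response
  class(out) <- c("scan_profile", "data.frame")
  out
}

#' Summarize a scan profile
#'
#' Per width: the offset with maximal adjusted R-squared among converged
#' cells (the critical window) and the plateau -- the maximal contiguous
#' run of offsets, containing the argmax, whose R-squared stays at or
#' above `plateau_frac` of the width's maximum.
#'
#' @param profile a `scan_profile`.
#' @param plateau_frac plateau threshold as a fraction of the per-width
#'   maximum (default 0.95).
#' @return data.frame with one row per width: `argmax_offset`, `max_r2_adj`,
#'   `plateau_from`, `plateau_to`.
#' @export
scan_summary <- function(profile, plateau_frac = 0.95) {
  sp <- split(as.data.frame(profile), profile$width)
  rows <- lapply(sp, function(p) {
    ok <- p$converged & !is.na(p$r2_adj)
    if (!any(ok))
      return(data.frame(width = p$width[1], argmax_offset = NA_integer_,
                        max_r2_adj = NA_real_, plateau_from = NA_integer_,
                        plateau_to = NA_integer_))
    pc <- p[ok, ]
    best <- which.max(pc$r2_adj)
    thr <- plateau_frac * pc$r2_adj[best]
    above <- pc$r2_adj >= thr
    lo <- best; while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
    hi <- best; while (hi < nrow(pc) && above[hi + 1L]) hi <- hi + 1L
    data.frame(width = p$width[1], argmax_offset = pc$offset[best],
               max_r2_adj = pc$r2_adj[best],
               plateau_from = pc$offset[lo], plateau_to = pc$offset[hi])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank window widths by explanatory power
#'
#' Per response, orders the scanned widths by their maximal adjusted
#' R-squared; exact ties prefer the smaller width.
#'
#' @param profiles a single `scan_profile` or a named list of them.
#' @param plateau_frac passed to [scan_summary()].
#' @return data.frame with one row per response: `best_width`, per-width
#'   maxima in columns `max_r2_w<width>`.
#' @export
compare_widths <- function(profiles, plateau_frac = 0.95) {
  if (inherits(profiles, "scan_profile"))
    profiles <- setNames(list(profiles),
                         attr(profiles, "response") %||% "response")
  rows <- lapply(names(profiles), function(nm) {
    s <- scan_summary(profiles[[nm]], plateau_frac)
    s <- s[order(s$width), ]
    best <- s$width[order(-s$max_r2_adj, s$width)][1]
    out <- data.frame(response = nm, best_width = best)
    for (i in seq_len(nrow(s)))
      out[[sprintf("max_r2_w%d", s$width[i])]] <- s$max_r2_adj[i]
    out
  })
  do.call(rbind, rows)
}

#' Attach a per-round plant-cover response
#'
#' Plant cover is scanned with the same NB machinery as the arthropod
#' groups; since the NB family needs counts, per-round cover (%) is
#' multiplied by `scale` and rounded to integer (0.1% -> 1 at the
#' default scale of 10).
#'
#' @param rounds per-round table.
#' @param veg per-round vegetation surveys.
#' @param scale multiplier before rounding (default 10).
#' @return `rounds` with an added integer `plants` column.
#' @export
add_cover_response <- function(rounds, veg, scale = 10) {
  key_r <- paste(rounds$plot, rounds$year, rounds$round)
  key_v <- paste(veg$plot, veg$year, veg$round)
  cov <- veg$total_cover[match(key_r, key_v)]
  if (anyNA(cov))
    warning("rounds without vegetation survey: plants response set to NA")
  rounds$plants <- as.integer(round(cov * scale))
  rounds
}
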