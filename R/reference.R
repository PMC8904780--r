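#' Published seasonal-rainfall summary of the emulated field study
#'
#' The per-year February--March rainfall totals (mm) and plot-year sample
#' sizes reported for the six-year Namibian arid-savannah pitfall study
#' that the synthetic generator emulates, together with the printed
#' across-year summary (mean 56.0 mm, SE 24.5 mm, N = 157). Used for
#' internal-consistency arithmetic, not re-estimated from data.
#'
#' @return data.frame with columns `year`, `seasonal_rainfall`, `n`.
#' @export
reference_seasonal_rainfall <- function() {
  data.frame(
    year = 2013:2018,
    seasonal_rainfall = c(30.5, 161.5, 4.0, 48.0, 85.8, 6.0),
    n = c(28L, 29L, 20L, 25L, 27L, 28L))
}

#' Published trophic-group catch totals of the emulated field study
#'
#' Study-wide numbers of ground-dwelling individuals per trophic group,
#' and the printed study total of 36227 individuals.
#'
#' @return named integer vector with a `total` attribute.
#' @export
reference_group_totals <- function() {
  structure(c(herbivores = 5536L, omnivores = 6141L, predators = 1790L,
              detritivores = 3621L, ants = 19139L),
            total = 36227L)
}

#' Summary arithmetic for a vector of seasonal totals
#'
#' Mean, standard error (sd / sqrt(n)), minimum and maximum -- the
#' statistics a study report prints for its per-year seasonal rainfall.
#'
#' @param x numeric vector of seasonal totals.
#' @return list with `mean`, `se`, `min`, `max`, `n`.
#' @export
seasonal_summary <- function(x) {
  list(mean = mean(x), se = sd(x) / sqrt(length(x)),
       min = min(x), max = max(x), n = length(x))
}
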