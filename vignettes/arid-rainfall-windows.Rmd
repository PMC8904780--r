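---
title: "Rainfall pulses, critical windows and bottom-up cascades: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rainfall pulses, critical windows and bottom-up cascades: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aridpulse)
```

## The scientific problem

In arid savannahs, rainfall arrives as erratic pulses concentrated in a
short growing season (here February--March, around a long-term seasonal
mean near 56 mm but spanning roughly 4--160 mm between years). Both the
*amount* of seasonal rain and its *timing* relative to sampling shape
plant cover and the activity density of ground-dwelling arthropods
(counts per pitfall trap per round -- a joint measure of abundance and
movement, not absolute abundance). `aridpulse` implements the full
analysis chain for such a study: data rules, a collinearity screen,
community ordination with permutation tests, a moving-window
critical-rainfall-window scan built on negative-binomial (NB) mixed
models, and a bottom-up trophic-cascade model suite -- together with a
seeded generator that simulates the whole study design with known
ground truth, so every stage is testable without field data.

## The synthetic study and what it emulates

The generator reproduces the design of a six-year Namibian
arid-savannah pitfall study: 30 plots of 2 m x 2 m, sampled in two
rounds per year (first round in early March, second at least 14 days
later), daily rainfall at 0.5 mm resolution, plot-level soil-surface
texture (sand, gravel, cobble, boulder, large boulder summing to
100%), per-round vegetation surveys, and counts for taxa classified
into herbivores, omnivores, predators, detritivores (springtails) and
ants.

Counts for trophic group $g$ at plot $p$, year $y$, round $r$ follow

$$y \sim \mathrm{NB}(\mu,\theta_g), \qquad
  \log \mu = \alpha_g + \gamma_g W_{g}(t_0) + \textstyle\sum_k
  \lambda_k Z_k + b_p + u_y,$$

where $W_g(t_0)$ is the standardized 7-day rainfall sum ending
$\mathrm{lag}_g$ days before the trap start $t_0$, the $Z_k$ are
standardized *latent* parent states (plants for herbivores; plants and
herbivores for omnivores; herbivores, omnivores and detritivores for
predators; herbivores for ants), $b_p \sim N(0, \sigma_{\mathrm{plot}}^2)$
and $u_y \sim N(0, \sigma_{\mathrm{year}}^2)$. Links operate on latent
expected abundances, not realized counts, keeping the cascade acyclic
and separating process noise from observation noise. Ants carry no
critical window; they respond (negatively, by default) to the seasonal
total itself. Plant cover is a continuous 0.1--50% response to
short-lag (8-day) rainfall and to gravel (negatively), and enters the
NB machinery as a count after multiplying by 10 and rounding.

Default conditions, chosen once to match the emulated study's reported
setting: seasonal mean 56 mm with log-normal between-year CV 1.0
(reproducing totals spanning single digits to >150 mm); lags plants 8,
herbivores/predators/detritivores 15, omnivores 24 days; rainfall
coefficients (per SD of the windowed sum) calibrated to the
inter-annual amplitudes the emulated study prints -- its herbivore
year-means span ~25-fold, detritivores ~100-fold, omnivores ~14-fold
but predators only ~3.6-fold, giving defaults of 1.1, 1.3, 0.9 and
0.35 respectively (plants 1.0);
$\sigma_{\mathrm{plot}} = 0.4$, $\sigma_{\mathrm{year}} = 0.45$ (the
study attributes roughly a fifth of community variance to inter-annual
variation); NB $\theta$ between 1.2 and 2.5; 10% plot-year dropout
(bounded so at least 15 plots remain per year, matching reported
per-year sample sizes of 20--29); three rare taxa with expected study
totals below 50; and one non-ground-dwelling taxon (Diptera) so the
filtering rules have work to do. Daily rainfall is disaggregated from
the drawn seasonal total into gamma-magnitude events on days weighted
toward a 1 March peak; amounts are recorded at 0.5 mm resolution while
preserving each seasonal total exactly, so degenerate configurations
(CV 0) reproduce the mean to well under 1%.

What the generator does *not* emulate: spatial structure among plots,
temperature, trap-failure mechanisms beyond whole-plot-year dropout,
within-round temporal autocorrelation, and taxon-level responses that
differ from their group's. Passing tests therefore demonstrate that the
pipeline recovers known signals under the study's design and noise
levels -- not that any particular field dataset satisfies the model.

## Data rules

Taxa are retained when predominantly ground-dwelling **and** their
study-wide total reaches 50 individuals (strictly fewer than 50
excludes; exactly 50 retains); totals are computed before any
aggregation, over the whole study. Activity densities are summed per
plot-year to remove intra-seasonal variability; vegetation parameters
take the per-plot-year maximum over surveys; seasonal rainfall is the
Feb 1--Mar 31 sum (the study says "between February and March" without
day bounds; whole calendar months are used). Empty sites (all-zero
rows) are dropped from the site-taxa matrix with a warning rather than
erroring, since severe drought years plausibly yield near-empty traps.

## Collinearity screen

Spearman rank correlations (ties averaged, pairwise-complete) flag
covariate pairs with $|r_s| > 0.7$ (strict). The flagged pair with the
largest $|r_s|$ is resolved by dropping the member with the lower
preference, iterating until no pair exceeds the threshold. The field
criterion "longer gradient length and better data distribution" is
qualitative; it is operationalized deterministically as: larger range
first, then smaller absolute skewness, then alphabetical name. This
makes the retained set invariant to column order. The covariate set
carried downstream (seasonal rainfall, plant cover, gravel, cobble) is
shipped as configuration via `reference_covariates()`, not recomputed,
because the emulated study's full correlation table is not available.

## Ordination

Taxon columns are scaled to unit sum of squares (the study's wording
mixes "means of each column" with "margin sum of squares equal to
one"; the latter is implemented, with row scaling behind a flag).
Bray--Curtis dissimilarity feeds a 2-D NMDS minimizing Kruskal
stress-1; the inner loop alternates isotonic regression (weighted PAVA
on tie-block-averaged distances, computed via `stats::isoreg`) with
Guttman-transform updates, rejecting non-improving steps so stress is
non-increasing. Twenty restarts are used (first from principal
coordinates, the rest random); convergence is declared when two
restarts agree to Procrustes correlation at least 0.999. Environmental
vectors are fitted by least squares on the score axes with
significance from 1000 permutations of the variable; PERMANOVA uses
the Gower-centered inner-product matrix with sequential (Type-I) sums
of squares via hat matrices and joint row/column permutation of the
dissimilarity matrix (999 permutations by default; the study does not
state its count). All permutation p-values use the add-one convention,
so they are never exactly zero. Term order matters for sequential SS;
the default enters rainfall, plant cover, gravel, cobble and then year
(as a factor), and is configurable and logged. Including year at all
is a design choice here: the emulated study reports a large
inter-annual share of community variance, and placing year last
attributes to it only variance unexplained by the continuous drivers.

## NB mixed models and adjusted R²

Models are fitted by maximum marginal likelihood through `glmmTMB`
(Laplace approximation; default) or `lme4::glmer.nb` (adaptive
Gauss--Hermite quadrature, node count configurable), behind one
interface (`fit_nb_glmm`) that reports estimates, Wald $z$ and $P$,
NB dispersion $\theta$ (Var $= \mu + \mu^2/\theta$), the plot-level
SD, log-likelihood and convergence flags. The explained-variation
measure is a deviance ratio evaluated at population-level fitted means
(random effect at zero), $R^2 = 1 - D_{\mathrm{full}}/D_{\mathrm{null}}$
with the full model's $\hat\theta$ used for both, and the Ezekiel
small-sample adjustment
$R^2_{\mathrm{adj}} = 1 - (1 - R^2)(n-1)/(n-p-1)$. The emulated
study's R² package formula is not public; any monotone-equivalent
definition yields the same window argmax, which is the quantity the
scan interprets, so numeric equality with published R² values is not
claimed. The scan's null model is intercept-only (year excluded), so
year's share is a constant offset across cells and does not move the
argmax; a partial-R² mode would change only the level of the profile.

## The moving-window scan

`window_sum(series, t0, w, k)` sums rainfall over the $w$ days ending
$k$ days before the trap start: days $t_0-k-w, \dots, t_0-k-1$. Offset
0 therefore ends the day before trapping; rain during the (roofed)
trapping week is never counted, since the question is antecedent
rainfall. Each sampling round is one observation (maximal temporal
resolution). For every width in {7, 14, 30} and offset 0--30 the model
`count ~ windowed_rain + year + (1 | plot)` is fitted and its adjusted
R² profiled. Year enters as a centered numeric covariate by default; a
factor coding is available (identifiable in the scan because the
windowed covariate varies between the two rounds of a year) and
absorbs inter-annual noise completely, but it also discards all
between-year information about the rain--response relationship, which
with six years and two rounds is most of it; the argmax offset locates the critical window, and the
plateau is the maximal contiguous run of offsets holding at least 95%
of the width's peak R² (threshold configurable -- the emulated study
reports ranges without defining them). Non-convergent cells stay in
the output flagged, excluded from argmax and plateau. Width comparison
ranks widths by peak R², preferring the smaller width on exact ties.
The "window position" axis indexes the window's near edge; with a
7-day causal window in the generator, the argmax sits at the true lag.

## The trophic-cascade suite

Six NB mixed models (plants, herbivores, omnivores, predators,
detritivores, ants) share the scan's structure (plot random intercept,
year as centered numeric -- a year factor would alias seasonal
rainfall, which is constant within year). Tested covariates follow the
bottom-up wiring; all other cells are "NT" (not tested), and top-down
links are deliberately absent. Covariates are z-scored before fitting
so estimates are comparable across rows of the summary table
(raw-scale mode by flag); activity-density covariates are
log(x+1)-transformed first to tame skew. Because the emulated study
does not state its covariate scaling, published coefficient magnitudes
are not numerical targets. Cells are rendered as `estimate` plus stars
(* $P<0.05$, ** $P<0.01$, *** $P<0.001$), `n.s`, or `NT`.

## Numerical choices and degenerate inputs

* Permutation p-values: $(1 + \#\{\text{stat}_\pi \ge
  \text{stat}\})/(1 + n_\pi)$.
* NMDS ties: distances averaged within tie blocks of the
  dissimilarities before PAVA; restart RNG derives from one master
  seed.
* Constant covariates: undefined Spearman correlations are recorded as
  missing and the variable dropped with reason "constant".
* Constant envfit variables and all-zero matrix columns raise errors
  naming the offender; all-zero matrix *rows* are dropped with a
  warning.
* `fit_nb_glmm` refuses non-integer or negative responses,
  rank-deficient designs and fewer than 10 observations; $\theta$
  above $10^4$ is flagged as the Poisson limit.
* Null calibration uses `null_config()`, which zeroes all effect
  coefficients *and* the shared year-level SD: with year-level noise
  present, a year-constant covariate under a plot-only random effect
  is pseudoreplicated and its Wald test anticonservative -- a
  misspecification issue, deliberately excluded from the calibration
  of the significance machinery itself. For the envfit calibration the
  plot random intercept is likewise set to zero, because site
  exchangeability -- the permutation test's own null hypothesis --
  fails when sites from the same plot share an intercept.

## Problem sizes used by the test and acceptance suites

Simulation checks run at the study's scale (30 plots x 6 years x 2
rounds) where the property under test concerns that scale: 20 seeds
for critical-window recovery (with the 7-day vs 30-day width contrast
measured on 6 of them), 200 replicates of 30 x 12 panels for
variance-component recovery, 40 null studies pooling 29 Wald tests
each for cascade calibration. Cheaper properties use reduced sizes
chosen once: 240 replicate years for the seasonal-mean check, 30
three-year, 10-plot null studies for envfit calibration, 400
small-sample replicates for the envfit permutation null. Exhaustive
enumeration (720 permutations at $n = 6$) anchors the PERMANOVA
p-value, and naive double-loop Bray--Curtis, classical ANOVA on
univariate Euclidean data, plain NB regression at $\sigma = 0$ and
exactly embeddable 2-D configurations anchor the rest.

## Attribution limits of annual-resolution cascade models

A property worth knowing before interpreting any single cascade table:
with six years, the correlation between the plant (8-day-lag) and
herbivore (15-day-lag) rainfall windows across years is itself a
six-point statistic and occasionally lands strongly negative by
chance. The bottom-up design carries no covariate for pulse timing, so
in such realizations the annual-scale plants cell absorbs part of the
herbivore's direct pulse response with a flipped sign, even though the
generative link is positive -- re-fitting with the true lag-15 window
added as a control (possible only in simulation) restores the positive
cell. The cascade tests therefore check that the estimate distribution
across seeds is centred positive and detected far above chance, and
that attribution is correct once pulse timing is controlled, rather
than demanding near-certain detection in every realization. Field
tables with opposite-signed seasonal-rainfall and plant-cover cells
for the same response are consistent with this mechanism. The
moving-window scan, which models pulse timing explicitly, does not
share the problem.

## Known limitations

The NB engine delegates optimization to glmmTMB/lme4 and inherits
their convergence behaviour on near-boundary variance components
(flags are propagated, and consumers exclude non-converged cells).
Sequential-SS PERMANOVA is order-dependent by construction. The scan
assumes a single rainfall series for all plots (one gauge), matching
the emulated design but not multi-station studies. The generator's
dominant-taxon split within groups is multinomial with fixed
proportions, so taxon-level scans mirror their group's window rather
than expressing taxon-specific lags.
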