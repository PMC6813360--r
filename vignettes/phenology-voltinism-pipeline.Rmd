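---
title: "Flight curves, voltinism and population trends: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flight curves, voltinism and population trends: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

lepiphen re-creates, end to end, the kind of analysis used to ask whether
climate-driven phenology advances help or harm insect populations depending
on their voltinism (number of generations per year) and habitat breadth:
seasonal flight curves fitted to standardized count data give each
population an annual emergence date and abundance index; atlas records give
each species an annual distribution size and northern range margin; 20-year
trends in these quantities are then related to one another with interaction
mixed models. Because the national monitoring datasets that motivate this
design are available only on request, the package is driven by a
synthetic-data generator that emulates their statistical structure with
known ground truth, so every stage can be validated by parameter recovery
rather than by fixture files.

This vignette records the models, the parameters that matter, and the
design decisions taken where the design was genuinely open.

## The seasonal flight curve model

For one population (a species at one site) in one year, observed counts
$y_i$ at recording events on days $d_i$ are modelled as

$$y_i \sim \mathrm{Poisson}(\mu(d_i)), \qquad
  \log \mu(d) = f(d),$$

where $f$ is a penalized cubic regression spline with 20 basis functions
and its smoothness chosen by REML (`mgcv::gam(count ~ s(doy, k = 20,
bs = "cr"), family = poisson, method = "REML")`). Counts of zero are
included; they carry most of the information about the flight season's
edges. Predictions are made on every integer day of the recording window
(days 91–272 for transects, 1–365 for traps).

A fitted curve is screened before use:

* **`jan1_gt1`** — predicted abundance on 1 January above 1 individual per
  event. For transect windows, which start on 1 April, the spline is
  extrapolated to day 1; this is an interpretation (the rule is usually
  stated for whole-year data) and is flagged as such.
* **`no_peak`** — no day's prediction exceeds both neighbours at a
  qualifying height anywhere in the window.
* **`peak_on_boundary`** — the first qualifying maximum sits on the
  window's first or last day (one-sided maxima at the edges count as
  boundary peaks). Curves like this belong to populations already flying
  when recording starts or still flying when it ends, so the peak day
  cannot be estimated. Note the two failure labels partition the failures:
  a flat, near-zero curve is `no_peak`; a monotone curve is
  `peak_on_boundary`.
* **`fit_error`** — the spline could not be fitted (for example fewer
  events than basis coefficients).

A local maximum qualifies as a *generation peak* when its height reaches
`plausibility_fraction` (default 0.05) of the curve's maximum **and** an
absolute floor `min_peak_height` (default 0.05 expected individuals per
event). The relative rule is a surrogate for the published decision trees
for "most plausible" peaks, which are not reproduced here; it is a single
documented knob, not asserted to be the original authors' rule. The
absolute floor exists because an all-zero fit is numerically a field of
10^-16^-scale wiggles that the relative rule alone would promote to peaks.
Plateaus of equal predicted values count once, at the plateau's last day;
equal-height competing peaks resolve to the earliest day.

The **phenology** of a population-year is the day of the first qualifying
peak. The **intergenerational abundance ratio** (multivoltine species only)
divides the summed predicted daily abundance after the inter-brood trough
(the minimum strictly between the first two qualifying peaks) by the sum up
to and including the trough. Larger values therefore mean proportionally
larger later generations; the orientation is chosen so that "earlier first
peak, larger ratio" is the expected direction of the brood-size mechanism.

## The selection cascade

All thresholds sit in `analysis_options()` and default to the uniform
criteria the design is built around:

| level | rule |
|---|---|
| population-year | ≥ 10 recording events, focal species positive on ≥ 3 |
| population | curves fitted in ≥ 15 of the 20 study years, plus ≥ 1 pre-period (1980–1990) year |
| species | ≥ 3 such populations, jointly covering all 20 study years |
| hectad | any-species records in both halves of the study period; median annual % of regional richness ≥ 25 |
| species (distribution) | ≥ 20 occupied heavy hectads; mean recorded elevation ≤ 200 m |
| margin subset | range margin > 100 km south of the northern limit |

Interpretations taken (each has a config switch or documented rationale):
the pre-period rule counts years with a *successfully fitted* curve
(`pre_period_mode = "recorded"` relaxes this to any recorded year); the
regional richness of a hectad excludes the hectad's own records and uses
its 100 nearest neighbouring hectads by centroid distance, ties broken by
(northing, easting); study years in which a hectad's region has no records
contribute 0% rather than being dropped; the northern limit is a northing
in km (the synthetic grid has no geodesy), defaulting to the northernmost
recorded hectad.

## Annual metrics and trends

Per population-year: phenology day; abundance index = total individuals /
number of recording events; the intergenerational ratio; and spring GDD5 =
$\sum_{\text{1 Mar–31 May}} \max(0, T_d - 5)$ on daily mean temperatures.
All years are treated as 365 days long, with 29 February sharing day 59
with 28 February, so the GDD5 window is always 92 days and day 60 is
always 1 March. Per species-year: distribution = 100 × occupied / recorded
heavy hectads (the year-specific denominator absorbs recording growth);
range margin = mean northing of the ten most northerly occupied hectads,
including all ties with the tenth.

Species-level 20-year trends in phenology and abundance are year slopes of
Gaussian mixed models with a random site intercept (`lme4::lmer`);
log abundance is used (natural log), and the phenology slope's sign is
reversed so that positive = advance. Distribution and margin trends are
ordinary regressions on the single national series. Population-level
trends are ordinary regressions. A species with one site degenerates to
the ordinary regression, and a failed mixed fit falls back to it with a
warning.

## Inference layer

All model comparisons use maximum likelihood (REML would make nested fixed
effects incomparable); likelihood-ratio statistics are referred to
$\chi^2_1$ since every focal term costs one parameter with two-level
factors. Interspecific models regress one species-level trend on another
with a random taxon-group intercept; the focal two- or three-way
interaction with voltinism (and habitat class) is tested by LRT, and
non-significant interactions are simplified stepwise (three-way, then
two-way, then main effect, each retained iff LRT p < α or AIC improves).
When an interaction is retained the data are split and the slope tested per
voltinism × class cell; cells below `min_cell_n = 4` species are reported
descriptively but not tested. Marginal R² is the fixed-effect prediction
variance over the total (fixed + random + residual).

The phenology-attributable component of abundance change is the
fixed-effects prediction of the phenology→abundance model evaluated at each
species' covariates, and feeds second-stage distribution/margin models.
Intraspecific models repeat the phenology→abundance test on
population-level trends with a species random intercept, plus independent
per-species ordinary regressions with two-tailed slope tests at α = 0.05 —
under independence, 2.5% of species are expected to show a significant
positive slope by chance. Annual-response models use crossed random
intercepts for species and year; abundance and ratio responses are
log-transformed; the ratio model is defined for multivoltine species only.

## The synthetic-data generator

Defaults are the study conditions the pipeline assumes; all are
`sim_config()` fields.

* **Temperatures**: per site, a sinusoidal annual cycle (mean 9 °C,
  amplitude 7.5 °C, coldest in mid-January), site offsets (s.d. 1.5 °C),
  a linear warming trend of 0.025 °C/yr (≈ 0.5 °C over the 20-year study
  window), and AR(1) daily noise (s.d. 2 °C, ρ = 0.7). These put spring
  GDD5 near 380 with a between-year trend of ≈ 2 units/yr.
* **Emergence**: baseline peak day per species (multivoltines 125–150,
  univoltine butterflies 155–185, univoltine moths 160–220), advanced by
  0.05 days per GDD5 unit above the long-run mean, plus Gaussian noise
  (s.d. 5 days). With the default warming this injects a mean advance of
  ≈ 0.1 days/yr (≈ 1 day/decade), the magnitude reported for British
  Lepidoptera.
* **Population dynamics**: log population scale = site effect (s.d. 0.4) +
  species trend (s.d. 0.03 log units/yr) + noise (s.d. 0.2) + a carry-over
  of ±0.01 log units per day of earlier emergence the previous year
  (positive for multivoltines, negative for univoltines).
* **Broods**: Gaussian activity curves (s.d. 10 and 12 days, 70 days
  apart); the second brood's size is multiplied by
  $\exp(0.04 \times \text{days earlier})$, so early years have relatively
  large second generations.
* **Counts**: Poisson draws of the brood-mixture rate at each recording
  event; weekly transects for butterflies, all-year traps (default
  7-day interval) for moths.
* **Atlas**: a 24 × 24 hectad grid (10-km cells, 230 km of northing).
  Species' northern range intercepts are uniform over the grid (so both
  southern, margin-subset species and near-limit species exist), local
  abundance falls off logistically (8-km scale) at the range edge, margins
  drift at 40 km per log-unit of abundance trend, and a species is
  recorded in a hectad-year when local abundance exceeds 0.2 *and* a
  Bernoulli recorder visit occurs (hectad efforts 0.9 / 0.5 / 0.05 with
  probabilities 0.7 / 0.2 / 0.1, which creates the well- and
  poorly-recorded contrast the effort filters need).

All randomness flows from one root seed through named substreams, so the
same configuration reproduces byte-identical tables and the pipeline's
outputs hash identically across runs.

`simulate_species_trends()` generates the species-level trend layer
directly for power and calibration studies of the inference stage:
phenology advances N(0.3, 0.8²) days/yr for multivoltines and N(0.15,
0.3²) for univoltines, abundance change = coupling × advance + N(0, 0.03²)
with coupling +0.03 (multivoltine), −0.09 (univoltine specialist) and 0
(univoltine generalist), and distribution/margin changes mediated by
abundance (40 %/yr and 80 km/yr per log-unit, residual s.d. 1 and 2). The
multivoltine coupling and the margin coupling were set by design
calculations targeting the detection properties the test-bed is required
to have — the voltinism interaction detectable in well over 80% of
130-species datasets (measured power ≈ 91%) and the mediated margin effect
in ≈ 98% — while staying within one standard error of the field estimates
they mirror. Univoltine-specialist declines use the published point
magnitude directly.

## What the generator does and does not emulate

It reproduces the *statistical* structure the pipeline assumes: uni- and
bimodal seasonal curves, emergence tracking spring warmth, log-linear
trends with site heterogeneity, carry-over coupling, effort-biased atlas
detection, and the two recording calendars. It does **not** emulate
spatially explicit dispersal, real British geography or geodesy, weather
reanalysis, observer-level variation in detection within a visit,
phylogenetic correlation between species, or migrant influxes. Passing
recovery tests therefore shows the pipeline's estimators are consistent
under the assumed data-generating process — not that real recording-scheme
data satisfy that process.

## Numerical choices and degenerate inputs

* Peak qualification: `plausibility_fraction` 0.05 of the curve maximum
  with an absolute floor of 0.05; both documented knobs.
* Tie-breaks: plateau peaks at the plateau's last day; equal competing
  peaks to the earliest day; equal trough minima to the earliest day;
  neighbour-distance ties in the hectad filter by (northing, easting).
* Curves failing anywhere in fitting or screening are *recorded*, never
  raised; the failure taxonomy is part of the output.
* A zero abundance index inside the selected set is impossible by
  construction (three positive events are required), so the trend layer
  treats one as a pipeline bug and errors rather than adding an offset.
* Mixed fits that are singular are accepted (the LRT remains valid); mixed
  fits that fail outright fall back to ordinary regression with a warning.
* Problem sizes used by the packaged tests and the acceptance script were
  chosen as the smallest that leave the statistical properties
  comfortably powered: 12 species × 6 sites × 35 years for full-pipeline
  recovery (≈ 1,250 curve fits), 1000 × 30 for the significance null,
  50 and 200 replicates for power and calibration of the inference layer,
  and a 6 × 6 configuration for byte-level determinism.

## Known limitations

The published decision trees for "most plausible" peak and trough are not
public; the relative-height rule is a surrogate and population-years near
the qualification threshold can be classified differently than the
original procedure would. The 1 January rule for transect curves relies on
spline extrapolation far outside the data window. The generator's
detection model is binary at the hectad-year level, so distribution
denominators are cleaner than in real atlas data. Phylogenetic
non-independence is out of scope; the interaction models treat species as
exchangeable within taxon group.
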