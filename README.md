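# lepiphen

Climate warming shifts the seasonal timing (phenology) of insect
life-cycles, but whether emerging earlier helps or harms a population
depends on its life history. Species with multiple reproductive cycles per
year (multivoltine) can convert a longer season into a larger second
generation; species locked into one annual generation (univoltine) cannot,
and habitat specialists may even pay a cost. lepiphen is an R pipeline for
testing exactly this chain of hypotheses on standardized monitoring and
atlas data for Lepidoptera: it estimates per-population flight curves and
emergence dates, per-species abundance, distribution and range-margin
trends, and then asks — with interaction mixed models — whether phenology
advances predict abundance trends differently by voltinism and habitat
class, and whether abundance in turn predicts range expansion.

Because the motivating national datasets (butterfly transects, light-trap
networks, hectad-scale atlases) are restricted-access, the package includes
a first-class synthetic-data generator that emulates their statistical
structure with known ground truth. Every stage of the pipeline is validated
by recovering injected parameters, not by fixtures.

## The core models

**Flight curves.** For one population-year with counts $y_i$ on days
$d_i$:

$$y_i \sim \text{Poisson}(\mu(d_i)), \quad \log \mu(d) = f(d),$$

with $f$ a penalized cubic regression spline (20 basis functions,
REML-selected smoothness; `mgcv`). The first-generation emergence date is
the first qualifying local maximum of the predicted daily curve; for
bimodal curves, the intergenerational abundance ratio is
$\sum_{d > t}\hat\mu(d) \big/ \sum_{d \le t}\hat\mu(d)$ around the
inter-brood trough $t$.

**Annual metrics.** Abundance index = individuals per recording event;
spring thermal forcing GDD5 $= \sum_{\text{1 Mar–31 May}}\max(0, T_d - 5)$;
distribution = % of recorded heavily-recorded hectads occupied; range
margin = mean northing of the ten most northerly occupied hectads (ties
included).

**Trends and inference.** 20-year trends are year slopes (mixed models
with a site random intercept for phenology and log abundance, sign flipped
so positive phenology trend = advance; OLS for national distribution and
margin series). Trend-on-trend models are Gaussian mixed models
(`lme4`) with voltinism (× habitat class) interactions tested by
likelihood-ratio tests on maximum-likelihood fits, $\chi^2$ with 1 d.f.;
annual-response models use crossed species and year random intercepts.

## Worked example

The numbered drivers under `analysis/` run the whole study on synthetic
data and narrate each stage:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_flight_curves.R
Rscript analysis/03_selection.R
Rscript analysis/04_metrics.R
Rscript analysis/05_trends.R
Rscript analysis/06_inference.R
```

Stage 1 reports the injected forcing:

```
Simulated 12 species at 6 sites, 1980 - 2014
  count records: 58275 (9881 positive)
  spring GDD5: mean 383.6 - warming trend 2.18 GDD5 units/yr
  injected mean phenology advance: 0.109 days/yr
```

(the generator advances emergence by 0.05 days per GDD5 unit, and springs
warm by ≈ 2.2 GDD5 units/yr, so species should advance ≈ 1 day/decade).
Stage 5 recovers trends of that size from the fitted curves:

```
univoltine (n = 8): advance 1.03 days/decade, abundance +0.6%/yr
multivoltine (n = 4): advance 0.74 days/decade, abundance +3.3%/yr
```

and stage 6 recovers the annual-scale mechanisms, e.g. the GDD5 →
peak-day coefficients (injected −0.05 days per GDD5 unit) and the
earlier-peak → larger-second-brood effect (injected −0.04 per day):

```
peak day ~ GDD5 (crossed species/year effects):
         level       slope          se
1 multivoltine -0.04763524 0.004256861
2   univoltine -0.04660384 0.002638991
log intergenerational ratio ~ peak day (multivoltines):
  level       slope          se
1   all -0.03457811 0.002871357
```

Outputs (simulated tables, inclusion reports at every filter level, annual
metrics, trend tables, model summaries) are written under `results/`. The
same end-to-end run is available in one call as
`run_all(sim_config(seed = 1), out_dir = "results/run")`, which also writes
a manifest of row counts and MD5 hashes — outputs are byte-identical for a
fixed seed.

## Package layout

- `R/` — generator, flight-curve fitting and screening, selection cascade,
  annual metrics, trend estimation, inference models, IO and orchestration
- `analysis/` — numbered narrative drivers (the study, start to finish)
- `tests/testthat/` — unit, property and acceptance tests with independent
  brute-force oracles
- `vignettes/phenology-voltinism-pipeline.Rmd` — the models, parameter
  defaults and design decisions in full
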