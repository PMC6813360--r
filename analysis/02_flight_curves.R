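#!/usr/bin/env Rscript
# Stage 2: fit and screen per-population-year flight curves.
#
# Population-years need at least 10 recording events with the species
# positive on at least 3 before a curve is attempted. Each curve is a
# penalized Poisson spline (REML smoothing) over day-of-year; fits are
# screened (1 Jan abundance > 1, no qualifying peak, peak on the window
# boundary) and the first-generation peak day, inter-brood trough and
# intergenerational abundance ratio are extracted.

library(lepiphen)

counts <- read_table("results/data/counts.csv", "counts")
events <- read_table("results/data/events.csv", "events")

py <- select_population_years(events, counts)
write_table(py, "results/inclusion_population_year.csv")
cat("population-years:", nrow(py), "of which", sum(py$included),
    "pass the 10-event / 3-positive rule\n")

curves <- fit_population_curves(counts, events,
                                include = py[py$included,
                                             c("population_id", "year")])
write_table(curves, "results/curves.csv")

cat("curves fitted:", nrow(curves), "\n")
print(table(fail_reason = curves$fail_reason))
ok <- curves[curves$fit_ok, ]
cat("median first peak day:", median(ok$first_peak_day), "\n")
cat("curves with an inter-brood trough:", sum(!is.na(ok$trough_day)),
    sprintf("(%.1f%%)\n", 100 * mean(!is.na(ok$trough_day))))
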