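#!/usr/bin/env Rscript
# Stage 4: annual metrics.
#
# Per population-year: first-peak (phenology) day, mean individuals per
# recording event, intergenerational abundance ratio (multivoltines), and
# site spring GDD5. Per species-year: percentage of recorded heavy hectads
# occupied and range-margin northing (mean of the ten most northerly
# occupied hectads, ties included).

library(lepiphen)

curves <- utils::read.csv("results/curves.csv", stringsAsFactors = FALSE)
counts <- read_table("results/data/counts.csv", "counts")
events <- read_table("results/data/events.csv", "events")
presences <- read_table("results/data/presences.csv", "presences")
temperatures <- read_table("results/data/temperatures.csv", "temperatures")
heavy <- utils::read.csv("results/heavy_hectads.csv", stringsAsFactors = FALSE)

metrics <- annual_metrics(curves, counts, events, presences, heavy,
                          temperatures)
write_table(metrics$population, "results/metrics_population.csv")
write_table(metrics$species, "results/metrics_species.csv")

ok <- metrics$population[metrics$population$fit_ok, ]
cat("population-year metrics:", nrow(metrics$population), "rows (",
    nrow(ok), "with screened curves )\n")
cat("  phenology day: median", median(ok$phenology_day, na.rm = TRUE), "\n")
cat("  abundance/event: mean", round(mean(ok$abundance_index), 2), "\n")
cat("  GDD5: mean", round(mean(ok$gdd5), 1), "\n")
cat("species-year metrics:", nrow(metrics$species), "rows; occupancy mean",
    round(mean(metrics$species$distribution_pct, na.rm = TRUE), 1), "%\n")
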