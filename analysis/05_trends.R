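#!/usr/bin/env Rscript
# Stage 5: 20-year rates of change.
#
# Species-level phenology and abundance trends are year slopes of mixed
# models with a random site intercept (phenology sign flipped so positive =
# advance); distribution and margin trends are ordinary regressions on the
# national series; population-level trends are ordinary regressions.

library(lepiphen)

metrics_pop <- utils::read.csv("results/metrics_population.csv",
                               stringsAsFactors = FALSE)
metrics_sp <- utils::read.csv("results/metrics_species.csv",
                              stringsAsFactors = FALSE)
pop_rep <- utils::read.csv("results/inclusion_population.csv",
                           stringsAsFactors = FALSE)
sp_rep <- utils::read.csv("results/inclusion_species.csv",
                          stringsAsFactors = FALSE)
dist_rep <- utils::read.csv("results/inclusion_species_distribution.csv",
                            stringsAsFactors = FALSE)
traits <- read_table("results/data/traits.csv", "traits")

keep <- metrics_pop$population_id %in% pop_rep$population_id[pop_rep$included] &
  metrics_pop$species_id %in% sp_rep$species_id[sp_rep$included] &
  metrics_pop$year >= 1995 & metrics_pop$year <= 2014
trends <- compute_trends(
  metrics_pop[keep, ], metrics_sp,
  dist_species = dist_rep$species_id[dist_rep$level == "species_distribution" &
                                       dist_rep$included],
  margin_species = dist_rep$species_id[dist_rep$level == "margin_subset" &
                                         dist_rep$included])
write_table(trends$species, "results/trends_species.csv")
write_table(trends$population, "results/trends_population.csv")

sp <- merge(trends$species, traits, by = "species_id")
for (v in c("univoltine", "multivoltine")) {
  d <- sp[sp$voltinism == v, ]
  cat(sprintf("%s (n = %d): advance %.2f days/decade, abundance %+.1f%%/yr\n",
              v, nrow(d), 10 * mean(d$phenology_advance),
              100 * (exp(mean(d$abundance_change)) - 1)))
}
cat("population trends:", nrow(trends$population), "rows\n")
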