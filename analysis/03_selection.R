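#!/usr/bin/env Rscript
# Stage 3: the remaining selection cascade.
#
# Populations need successfully fitted curves in 15 of the 20 study years
# plus one pre-period (1980-1990) year; species need 3 such populations
# jointly covering every study year. Atlas hectads must be recorded in both
# halves of the study period and reach a median 25% of regional (100
# nearest neighbours) species richness; species need 20 occupied heavy
# hectads, mean recorded elevation at most 200 m, and enter the range-margin
# subset only if their margin lies over 100 km south of the northern limit.

library(lepiphen)

curves <- utils::read.csv("results/curves.csv", stringsAsFactors = FALSE)
counts <- read_table("results/data/counts.csv", "counts")
presences <- read_table("results/data/presences.csv", "presences")
elevations <- read_table("results/data/elevations.csv", "elevations")

pop_rep <- select_populations(curves)
write_table(pop_rep, "results/inclusion_population.csv")
cat("populations:", nrow(pop_rep), "->", sum(pop_rep$included), "included\n")

sp_rep <- select_species_from_populations(pop_rep, counts)
write_table(sp_rep, "results/inclusion_species.csv")
cat("species:", nrow(sp_rep), "->", sum(sp_rep$included), "included\n")

heavy <- select_heavily_recorded_hectads(presences)
write_table(heavy$report, "results/inclusion_hectad.csv")
write_table(heavy$heavy, "results/heavy_hectads.csv")
cat("hectads:", nrow(heavy$report), "->", nrow(heavy$heavy),
    "heavily recorded\n")

ph <- presences[hectad_id(presences$hectad_easting,
                          presences$hectad_northing) %in%
                  heavy$heavy$hectad_id, ]
dist_rep <- select_species_distributions(ph, elevations)
write_table(dist_rep, "results/inclusion_species_distribution.csv")
main <- dist_rep[dist_rep$level == "species_distribution", ]
marg <- dist_rep[dist_rep$level == "margin_subset", ]
cat("distribution species:", nrow(main), "->", sum(main$included),
    "included;", sum(marg$included), "in the margin subset\n")
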