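# Synthetic monitoring-scheme generator. Emulates the statistical structure
# the analysis assumes -- weekly transect and nightly light-trap counts,
# hectad-scale atlas presences with uneven recorder effort, daily site
# temperatures with a warming trend -- with known ground-truth parameters so
# every downstream stage can be tested by parameter recovery.

#' Configuration for the synthetic dataset generator
#'
#' All randomness flows from `seed` through named substreams (temperatures,
#' traits, populations, observation, presences, elevations), so an identical
#' configuration reproduces byte-identical tables and individual components
#' can be re-simulated independently.
#'
#' @param n_species number of species.
#' @param n_sites number of monitoring sites; alternate sites host butterfly
#'   transects and moth light traps.
#' @param years inclusive simulated year range; must span at least the
#'   20-year study window.
#' @param study_years inclusive 20-year analysis window.
#' @param pre_period inclusive early window used by the site-establishment
#'   filter.
#' @param frac_multivoltine,frac_specialist,frac_butterfly trait proportions.
#' @param sampling_interval_days light-trap sampling interval (days).
#' @param warming_rate warming trend applied to daily temperatures,
#'   degrees C per year.
#' @param phenology_sensitivity days of emergence advance per unit of spring
#'   GDD5 above its long-run mean.
#' @param abundance_trend_sd between-species s.d. of the log-scale annual
#'   population trend.
#' @param brood_coupling per-day-earlier multiplier (log scale) on
#'   second-brood size for multivoltine species.
#' @param carryover log-scale carry-over of one day's earlier emergence in
#'   year *t* onto population size in year *t+1* (positive for multivoltine
#'   species, negative for univoltine species).
#' @param emergence_noise_sd s.d. (days) of interannual emergence noise.
#' @param pop_noise_sd s.d. of log-scale interannual population noise.
#' @param site_effect_sd s.d. of log-scale site quality effects.
#' @param base_mean_temp,seasonal_amplitude,site_temp_sd,temp_noise_sd,temp_ar1
#'   temperature model: annual mean level, sinusoidal amplitude, s.d. of
#'   site offsets, innovation s.d. and autocorrelation of AR(1) daily noise.
#' @param brood_sd1,brood_sd2,brood_gap,brood2_rel flight-curve shape: brood
#'   s.d.s (days), inter-brood gap (days), and baseline relative size of the
#'   second brood.
#' @param hectad_grid_side side length of the square hectad grid (10-km
#'   cells); the grid must contain over 100 hectads for the
#'   regional-richness filter to be defined.
#' @param detection_threshold minimum local expected abundance for a species
#'   to be recordable in a hectad.
#' @param peak_count_scale expected count at the first-brood peak for an
#'   average population.
#' @param seed integer root seed.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_species = 12L, n_sites = 6L,
                       years = c(1980L, 2014L),
                       study_years = c(1995L, 2014L),
                       pre_period = c(1980L, 1990L),
                       frac_multivoltine = 0.3,
                       frac_specialist = 0.16,
                       frac_butterfly = 0.22,
                       sampling_interval_days = 7L,
                       warming_rate = 0.025,
                       phenology_sensitivity = 0.05,
                       abundance_trend_sd = 0.03,
                       brood_coupling = 0.04,
                       carryover = 0.01,
                       emergence_noise_sd = 5,
                       pop_noise_sd = 0.2,
                       site_effect_sd = 0.4,
                       base_mean_temp = 9,
                       seasonal_amplitude = 7.5,
                       site_temp_sd = 1.5,
                       temp_noise_sd = 2,
                       temp_ar1 = 0.7,
                       brood_sd1 = 10,
                       brood_sd2 = 12,
                       brood_gap = 70,
                       brood2_rel = 1.1,
                       hectad_grid_side = 24L,
                       detection_threshold = 0.2,
                       peak_count_scale = 6,
                       seed = 1L) {
  cfg <- as.list(environment())
  cfg$n_species <- as.integer(n_species)
  cfg$n_sites <- as.integer(n_sites)
  cfg$years <- as.integer(years)
  cfg$study_years <- as.integer(study_years)
  cfg$pre_period <- as.integer(pre_period)
  cfg$sampling_interval_days <- as.integer(sampling_interval_days)
  cfg$hectad_grid_side <- as.integer(hectad_grid_side)
  cfg$seed <- as.integer(seed)

  stop_cfg <- function(msg) stop("invalid simulation config: ", msg, call. = FALSE)
  for (p in c("frac_multivoltine", "frac_specialist", "frac_butterfly")) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop_cfg(sprintf("%s must be a proportion in [0, 1]", p))
  }
  if (length(cfg$years) != 2L || cfg$years[1] > cfg$years[2])
    stop_cfg("years must be an increasing pair")
  if (length(cfg$study_years) != 2L || cfg$study_years[1] > cfg$study_years[2])
    stop_cfg("study_years must be an increasing pair")
  if (diff(cfg$years) + 1L < diff(cfg$study_years) + 1L ||
      cfg$study_years[1] < cfg$years[1] || cfg$study_years[2] > cfg$years[2])
    stop_cfg("year range must span the study window")
  if (cfg$sampling_interval_days < 1L)
    stop_cfg("sampling_interval_days must be positive")
  if (cfg$n_species < 1L || cfg$n_sites < 1L)
    stop_cfg("n_species and n_sites must be positive")
  if (cfg$emergence_noise_sd < 0 || cfg$pop_noise_sd < 0)
    stop_cfg("noise s.d.s must be non-negative")
  if (is.na(cfg$seed)) stop_cfg("seed must be an integer")
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic substream seeds derived from the root seed.
.substream <- function(seed, name) {
  idx <- match(name, c("temperatures", "traits", "populations",
                       "observation", "presences", "elevations", "trends"))
  if (is.na(idx)) stop("unknown substream: ", name)
  as.integer((as.numeric(seed) * 1009 + idx * 7919) %% 2147483587) + 1L
}

.gauss_mix <- function(day, means, sds, amps) {
  out <- numeric(length(day))
  for (b in seq_along(means))
    out <- out + amps[b] * exp(-((day - means[b])^2) / (2 * sds[b]^2))
  out
}

#' Expected individuals per recording event for one species on one day
#'
#' The seasonal activity curve is a sum of Gaussian-shaped brood terms:
#' univoltine species have exactly one brood, multivoltine species two.
#'
#' @param traits a one-row species traits table (or list) with a
#'   `voltinism` field.
#' @param brood_params data frame with one row per brood and columns
#'   `mean` (peak day), `sd` (days, positive) and `amplitude`
#'   (expected count at the brood peak, non-negative).
#' @param day numeric day(s) of year.
#' @return expected individuals per recording event at `day` (vectorised).
#' @export
activity_rate <- function(traits, brood_params, day) {
  if (!all(c("mean", "sd", "amplitude") %in% names(brood_params)))
    stop("brood_params needs columns mean, sd, amplitude")
  if (any(brood_params$sd <= 0)) stop("brood sd must be positive")
  if (any(brood_params$amplitude < 0)) stop("brood amplitude must be non-negative")
  voltinism <- if (is.list(traits)) traits$voltinism else traits["voltinism"]
  n_expected <- if (identical(as.character(voltinism), "multivoltine")) 2L else 1L
  if (nrow(brood_params) != n_expected)
    stop(sprintf("%s species must have %d brood(s), got %d",
                 voltinism, n_expected, nrow(brood_params)))
  .gauss_mix(day, brood_params$mean, brood_params$sd, brood_params$amplitude)
}

.simulate_traits <- function(cfg) {
  set.seed(.substream(cfg$seed, "traits"))
  n <- cfg$n_species
  species_id <- sprintf("sp%03d", seq_len(n))
  n_butterfly <- max(1L, min(n, round(cfg$frac_butterfly * n)))
  taxon_group <- rep("moth", n)
  taxon_group[seq_len(n_butterfly)] <- "butterfly"
  n_multi <- round(cfg$frac_multivoltine * n)
  voltinism <- rep("univoltine", n)
  voltinism[sample.int(n, n_multi)] <- "multivoltine"
  n_spec <- round(cfg$frac_specialist * n)
  habitat_class <- rep("generalist", n)
  habitat_class[sample.int(n, n_spec)] <- "specialist"
  # First-brood baseline peak day: multivoltines emerge earlier so a second
  # brood fits inside the season; butterflies sit inside the transect window.
  base_day <- ifelse(voltinism == "multivoltine",
                     round(runif(n, 125, 150)),
                     ifelse(taxon_group == "butterfly",
                            round(runif(n, 155, 185)),
                            round(runif(n, 160, 220))))
  data.frame(
    species_id = species_id,
    taxon_group = taxon_group,
    voltinism = voltinism,
    habitat_class = habitat_class,
    base_day = base_day,
    true_phenology_sensitivity = rep(cfg$phenology_sensitivity, n),
    true_abundance_trend = rnorm(n, 0, cfg$abundance_trend_sd),
    true_brood_coupling = ifelse(voltinism == "multivoltine",
                                 cfg$brood_coupling, 0),
    stringsAsFactors = FALSE
  )
}

.site_table <- function(cfg) {
  data.frame(
    site_id = sprintf("st%02d", seq_len(cfg$n_sites)),
    scheme = rep(c("transect", "trap"), length.out = cfg$n_sites),
    stringsAsFactors = FALSE
  )
}

.simulate_temperatures <- function(cfg) {
  set.seed(.substream(cfg$seed, "temperatures"))
  sites <- .site_table(cfg)
  site_offset <- rnorm(cfg$n_sites, 0, cfg$site_temp_sd)
  yrs <- seq(cfg$years[1], cfg$years[2])
  doy <- rep(1:365, times = length(yrs))
  year <- rep(yrs, each = 365)
  n_day <- length(doy)
  seasonal <- cfg$base_mean_temp +
    cfg$seasonal_amplitude * cos(2 * pi * (doy - 200) / 365) +
    cfg$warming_rate * (year - cfg$years[1])
  out <- vector("list", cfg$n_sites)
  sd_innov <- cfg$temp_noise_sd * sqrt(1 - cfg$temp_ar1^2)
  for (s in seq_len(cfg$n_sites)) {
    eps <- numeric(n_day)
    eps[1] <- rnorm(1, 0, cfg$temp_noise_sd)
    innov <- rnorm(n_day - 1, 0, sd_innov)
    for (t in 2:n_day) eps[t] <- cfg$temp_ar1 * eps[t - 1] + innov[t - 1]
    out[[s]] <- data.frame(
      site_id = sites$site_id[s],
      date = date_from_doy365(year, doy),
      tmean = round(seasonal + site_offset[s] + eps, 4),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

# Site-by-year spring degree days from a daily temperature table.
.gdd5_table <- function(temperatures) {
  doy <- doy365(temperatures$date)
  year <- as.integer(format(temperatures$date, "%Y"))
  in_win <- doy >= .gdd5_window[1] & doy <= .gdd5_window[2]
  exc <- pmax(temperatures$tmean[in_win] - 5, 0)
  key <- paste(temperatures$site_id[in_win], year[in_win], sep = "\r")
  agg <- tapply(exc, key, sum)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  data.frame(
    site_id = vapply(parts, `[`, "", 1L),
    year = as.integer(vapply(parts, `[`, "", 2L)),
    gdd5 = as.numeric(agg),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Simulate a full synthetic recording-scheme dataset
#'
#' Generates daily site temperatures (sinusoidal annual cycle, linear
#' warming, AR(1) noise), species traits, population dynamics in which
#' emergence day responds to spring GDD5 and multivoltine populations gain a
#' carry-over benefit from earlier emergence, Poisson counts at transect and
#' light-trap recording events, and hectad-scale atlas presences under
#' effort-dependent detection.
#'
#' @param config a [sim_config()] object.
#' @return a list of data frames: `counts`, `events`, `presences`,
#'   `temperatures`, `traits`, `elevations`, `truth` (species-level ground
#'   truth), `truth_population` (realised emergence day and log population
#'   scale per population-year), plus the `sites` table and the
#'   site-by-year `gdd5` table used internally.
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  cfg <- config
  sites <- .site_table(cfg)
  traits <- .simulate_traits(cfg)
  temperatures <- .simulate_temperatures(cfg)
  gdd5_tab <- .gdd5_table(temperatures)
  gdd5_ref <- mean(gdd5_tab$gdd5)
  yrs <- seq(cfg$years[1], cfg$years[2])
  mid_year <- mean(cfg$study_years)

  # Populations: each species is observable at every site of its scheme.
  traits$scheme <- ifelse(traits$taxon_group == "butterfly", "transect", "trap")
  pops <- merge(traits[, c("species_id", "scheme")], sites, by = "scheme")
  pops <- pops[order(pops$species_id, pops$site_id), c("species_id", "site_id", "scheme")]
  rownames(pops) <- NULL
  n_pop <- nrow(pops)

  ti <- match(pops$species_id, traits$species_id)
  gkey <- paste(gdd5_tab$site_id, gdd5_tab$year)

  set.seed(.substream(cfg$seed, "populations"))
  site_eff <- rnorm(n_pop, 0, cfg$site_effect_sd)
  n_yr <- length(yrs)
  E <- matrix(NA_real_, n_pop, n_yr)    # emergence (first-brood peak) day
  LP <- matrix(NA_real_, n_pop, n_yr)   # log population scale
  dir <- ifelse(traits$voltinism[ti] == "multivoltine", 1, -1)
  for (j in seq_len(n_yr)) {
    g <- gdd5_tab$gdd5[match(paste(pops$site_id, yrs[j]), gkey)]
    E[, j] <- traits$base_day[ti] -
      traits$true_phenology_sensitivity[ti] * (g - gdd5_ref) +
      rnorm(n_pop, 0, cfg$emergence_noise_sd)
    carry <- if (j == 1) 0 else
      dir * cfg$carryover * (traits$base_day[ti] - E[, j - 1])
    LP[, j] <- log(cfg$peak_count_scale) + site_eff +
      traits$true_abundance_trend[ti] * (yrs[j] - mid_year) +
      carry + rnorm(n_pop, 0, cfg$pop_noise_sd)
  }

  # Recording events per site-year.
  ev <- do.call(rbind, lapply(seq_len(nrow(sites)), function(s) {
    doys <- if (sites$scheme[s] == "transect") seq(91L, 272L, by = 7L)
            else seq(1L, 365L, by = cfg$sampling_interval_days)
    data.frame(site_id = sites$site_id[s], scheme = sites$scheme[s],
               year = rep(yrs, each = length(doys)),
               doy = rep(doys, times = length(yrs)),
               stringsAsFactors = FALSE)
  }))
  events <- data.frame(site_id = ev$site_id,
                       date = date_from_doy365(ev$year, ev$doy),
                       scheme = ev$scheme, stringsAsFactors = FALSE)

  # Counts: expand events over the species recordable at each site, compute
  # the brood-mixture activity rate, and draw Poisson counts.
  sp_by_site <- merge(ev, pops, by = c("site_id", "scheme"))
  pi <- match(paste(sp_by_site$species_id, sp_by_site$site_id),
              paste(pops$species_id, pops$site_id))
  yi <- match(sp_by_site$year, yrs)
  idx <- cbind(pi, yi)
  ti2 <- match(sp_by_site$species_id, traits$species_id)
  e1 <- E[idx]
  amp1 <- exp(LP[idx])
  lambda <- amp1 * exp(-((sp_by_site$doy - e1)^2) / (2 * cfg$brood_sd1^2))
  multi <- traits$voltinism[ti2] == "multivoltine"
  if (any(multi)) {
    amp2 <- amp1 * cfg$brood2_rel *
      exp(traits$true_brood_coupling[ti2] * (traits$base_day[ti2] - e1))
    lambda <- lambda + ifelse(multi,
      amp2 * exp(-((sp_by_site$doy - e1 - cfg$brood_gap)^2) / (2 * cfg$brood_sd2^2)),
      0)
  }
  ord <- order(sp_by_site$species_id, sp_by_site$site_id,
               sp_by_site$year, sp_by_site$doy)
  sp_by_site <- sp_by_site[ord, ]
  lambda <- lambda[ord]
  set.seed(.substream(cfg$seed, "observation"))
  counts <- data.frame(
    site_id = sp_by_site$site_id,
    species_id = sp_by_site$species_id,
    date = date_from_doy365(sp_by_site$year, sp_by_site$doy),
    count = rpois(nrow(sp_by_site), lambda),
    scheme = sp_by_site$scheme,
    stringsAsFactors = FALSE
  )
  rownames(counts) <- NULL

  # Hectad grid, recorder effort, elevations.
  side <- cfg$hectad_grid_side
  hect <- expand.grid(easting = (seq_len(side) - 1L) * 10L,
                      northing = (seq_len(side) - 1L) * 10L)
  hect <- hect[order(hect$northing, hect$easting), ]
  rownames(hect) <- NULL
  n_h <- nrow(hect)
  set.seed(.substream(cfg$seed, "elevations"))
  elev <- pmax(0, round(60 + rnorm(n_h, 0, 40)))
  upland <- runif(n_h) < 0.08
  elev[upland] <- round(runif(sum(upland), 220, 500))
  elevations <- data.frame(easting = hect$easting, northing = hect$northing,
                           elevation_m = elev, stringsAsFactors = FALSE)

  # Atlas presences: a species is recorded in a hectad-year when its local
  # expected abundance clears the detection threshold and a recorder visit
  # (Bernoulli with hectad-specific effort) occurs.
  set.seed(.substream(cfg$seed, "presences"))
  effort <- sample(c(0.9, 0.5, 0.05), n_h, replace = TRUE,
                   prob = c(0.7, 0.2, 0.1))
  # Southern species dominate the margin subset, as in the British fauna.
  margin0 <- runif(cfg$n_species, 0.1, 1.0) * max(hect$northing)
  margin_trend <- 40 * traits$true_abundance_trend
  pres <- vector("list", cfg$n_species)
  for (s in seq_len(cfg$n_species)) {
    yr_m <- rep(yrs, each = n_h)
    nor <- rep(hect$northing, times = length(yrs))
    eas <- rep(hect$easting, times = length(yrs))
    marg <- margin0[s] + margin_trend[s] * (yr_m - mid_year)
    loc <- exp(log(3) + traits$true_abundance_trend[s] * (yr_m - mid_year)) *
      plogis((marg - nor) / 8)
    visited <- rbinom(length(loc), 1L, rep(effort, times = length(yrs))) == 1L
    keep <- loc > cfg$detection_threshold & visited
    pres[[s]] <- data.frame(species_id = traits$species_id[s],
                            hectad_easting = eas[keep],
                            hectad_northing = nor[keep],
                            year = yr_m[keep], stringsAsFactors = FALSE)
  }
  presences <- do.call(rbind, pres)
  rownames(presences) <- NULL

  # Ground truth, including the realised GDD5 trend each site experienced.
  gdd5_slope <- mean(vapply(split(gdd5_tab, gdd5_tab$site_id), function(d)
    unname(coef(lm(gdd5 ~ year, data = d))[2]), numeric(1)))
  truth <- traits
  truth$carryover <- cfg$carryover * ifelse(truth$voltinism == "multivoltine", 1, -1)
  truth$margin0 <- margin0
  truth$margin_trend <- margin_trend
  truth$gdd5_ref <- gdd5_ref
  truth$gdd5_year_slope <- gdd5_slope
  truth$scheme <- NULL

  truth_population <- data.frame(
    population_id = rep(paste(pops$site_id, pops$species_id, sep = ":"), n_yr),
    species_id = rep(pops$species_id, n_yr),
    site_id = rep(pops$site_id, n_yr),
    year = rep(yrs, each = n_pop),
    emergence_day = as.vector(E),
    log_pop = as.vector(LP),
    stringsAsFactors = FALSE)
  truth_population <- truth_population[order(truth_population$population_id,
                                             truth_population$year), ]
  rownames(truth_population) <- NULL

  traits_out <- traits[, c("species_id", "taxon_group", "voltinism", "habitat_class")]
  list(counts = counts, events = events, presences = presences,
       temperatures = temperatures, traits = traits_out,
       elevations = elevations, truth = truth,
       truth_population = truth_population,
       sites = sites, gdd5 = gdd5_tab)
}

#' Independent phenology/abundance change pairs under the null
#'
#' Generates, for each species, `n_populations` population-level
#' (phenology change, abundance change) pairs with the two columns drawn
#' independently, for calibrating the expected fraction of species showing a
#' significant positive slope by chance alone.
#'
#' @param n_species number of species.
#' @param n_populations populations per species (at least 3).
#' @param noise_sd length-2 s.d.s for the phenology and abundance columns.
#' @param seed integer seed.
#' @return data frame with columns `species_id`, `population_id`,
#'   `phenology_change`, `abundance_change`.
#' @export
null_trend_pairs <- function(n_species, n_populations,
                             noise_sd = c(phenology = 1, abundance = 1),
                             seed = 1L) {
  if (n_populations < 3) stop("n_populations must be at least 3")
  set.seed(as.integer(seed))
  n <- n_species * n_populations
  data.frame(
    species_id = rep(sprintf("sp%04d", seq_len(n_species)), each = n_populations),
    population_id = rep(sprintf("pop%03d", seq_len(n_populations)),
                        times = n_species),
    phenology_change = rnorm(n, 0, noise_sd[[1]]),
    abundance_change = rnorm(n, 0, noise_sd[[2]]),
    stringsAsFactors = FALSE
  )
}

#' Simulate species-level 20-year trend tables
#'
#' Generates the species-level trend layer directly (phenology advance,
#' abundance change, and abundance-mediated distribution and range-margin
#' change) with cell-specific phenology-abundance couplings: positive for
#' multivoltine species, negative for univoltine habitat specialists, zero
#' for univoltine generalists. Used for power and null-calibration studies
#' of the inference layer, where replicating the full count-level pipeline
#' is unnecessary.
#'
#' @param n_species number of species.
#' @param frac_multivoltine,frac_specialist,frac_butterfly trait proportions.
#' @param slope_multivoltine,slope_univoltine_specialist,slope_univoltine_generalist
#'   log-abundance change per day-per-year of phenology advance in each cell.
#' @param phen_mean,phen_sd named (univoltine, multivoltine) mean and s.d. of
#'   phenology advance, days per year.
#' @param resid_sd residual s.d. of abundance change, log units per year.
#' @param dist_slope,dist_resid_sd distribution change (% per year) per unit
#'   abundance change, and its residual s.d.
#' @param margin_slope,margin_resid_sd margin change (km per year) per unit
#'   abundance change, and its residual s.d.
#' @param seed integer seed.
#' @return data frame with one row per species.
#' @export
simulate_species_trends <- function(n_species = 130L,
                                    frac_multivoltine = 0.3,
                                    frac_specialist = 0.16,
                                    frac_butterfly = 0.22,
                                    slope_multivoltine = 0.03,
                                    slope_univoltine_specialist = -0.09,
                                    slope_univoltine_generalist = 0,
                                    phen_mean = c(univoltine = 0.15, multivoltine = 0.3),
                                    phen_sd = c(univoltine = 0.3, multivoltine = 0.8),
                                    resid_sd = 0.03,
                                    dist_slope = 40, dist_resid_sd = 1,
                                    margin_slope = 80, margin_resid_sd = 2,
                                    seed = 1L) {
  set.seed(as.integer(seed))
  n <- as.integer(n_species)
  voltinism <- rep("univoltine", n)
  voltinism[sample.int(n, round(frac_multivoltine * n))] <- "multivoltine"
  habitat_class <- rep("generalist", n)
  habitat_class[sample.int(n, round(frac_specialist * n))] <- "specialist"
  taxon_group <- rep("moth", n)
  taxon_group[sample.int(n, max(1L, round(frac_butterfly * n)))] <- "butterfly"
  multi <- voltinism == "multivoltine"
  phen <- rnorm(n,
                ifelse(multi, phen_mean[["multivoltine"]], phen_mean[["univoltine"]]),
                ifelse(multi, phen_sd[["multivoltine"]], phen_sd[["univoltine"]]))
  slope <- ifelse(multi, slope_multivoltine,
                  ifelse(habitat_class == "specialist",
                         slope_univoltine_specialist,
                         slope_univoltine_generalist))
  abund <- slope * phen + rnorm(n, 0, resid_sd)
  data.frame(
    species_id = sprintf("sp%04d", seq_len(n)),
    taxon_group = taxon_group,
    voltinism = voltinism,
    habitat_class = habitat_class,
    phenology_advance = phen,
    abundance_change = abund,
    distribution_change = dist_slope * abund + rnorm(n, 0, dist_resid_sd),
    margin_change = margin_slope * abund + rnorm(n, 0, margin_resid_sd),
    stringsAsFactors = FALSE
  )
}
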