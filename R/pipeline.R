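# End-to-end orchestration: simulate -> fit curves -> select -> metrics ->
# trends -> inference, with per-stage inclusion reports and a run manifest.

#' Analysis options
#'
#' Thresholds of the selection cascade and analysis layer. Defaults are the
#' uniform criteria the pipeline is built around: at least 10 recording
#' events and 3 positive events per population-year; curves fitted in at
#' least 15 of the 20 study years plus one pre-period year; at least 3
#' populations per species with all 20 study years jointly covered; heavy
#' hectads at a median 25% of regional richness; at least 20 occupied heavy
#' hectads; mean recorded elevation at most 200 m; a 100-km buffer below
#' the northern limit for the range-margin subset; alpha 0.05; local maxima
#' counted as generation peaks from 5% of the curve maximum.
#'
#' @param min_events,min_positive population-year thresholds.
#' @param min_years minimum fitted study years per population.
#' @param min_populations minimum included populations per species.
#' @param heavy_median_pct heavy-hectad median regional-richness threshold.
#' @param min_hectads,max_mean_elevation_m distribution-species thresholds.
#' @param margin_buffer_km margin-subset buffer below the northern limit.
#' @param alpha significance level.
#' @param plausibility_fraction,min_peak_height peak-qualification rule.
#' @param pre_period_mode `"fitted"` or `"recorded"` (see
#'   [select_populations()]).
#' @param northern_limit northing (km) of the northern limit; `NULL` uses
#'   the northernmost hectad in the data.
#' @return named list of options.
#' @export
analysis_options <- function(min_events = 10L, min_positive = 3L,
                             min_years = 15L, min_populations = 3L,
                             heavy_median_pct = 25, min_hectads = 20L,
                             max_mean_elevation_m = 200,
                             margin_buffer_km = 100, alpha = 0.05,
                             plausibility_fraction = 0.05,
                             min_peak_height = 0.05,
                             pre_period_mode = "fitted",
                             northern_limit = NULL) {
  opts <- as.list(environment())
  num <- opts[!vapply(opts, is.null, logical(1)) &
                !names(opts) %in% "pre_period_mode"]
  if (any(vapply(num, function(x) !is.numeric(x) || x <= 0, logical(1))))
    stop("all analysis thresholds must be positive")
  opts
}

.flatten_model <- function(name, fit) {
  ov <- fit$overall
  out <- data.frame(model = name, subset = "overall", n = ov$n, aic = ov$aic,
                    marginal_r2 = ov$marginal_r2,
                    effect_size = ov$effect_size %||% NA_real_,
                    se = ov$se %||% NA_real_,
                    chi_sq = ov$chi_sq, p_value = ov$p_value,
                    stringsAsFactors = FALSE)
  if (!is.null(fit$subsets)) {
    sb <- fit$subsets
    lab <- if ("habitat_class" %in% names(sb))
      paste(sb$voltinism, sb$habitat_class) else sb$voltinism
    out <- rbind(out, data.frame(
      model = name, subset = lab, n = sb$n, aic = NA_real_,
      marginal_r2 = NA_real_, effect_size = sb$effect_size, se = sb$se,
      chi_sq = sb$chi_sq, p_value = sb$p_value, stringsAsFactors = FALSE))
  }
  out
}

.annual_model_row <- function(name, fit) {
  sl <- fit$slopes
  data.frame(model = name, subset = sl$level, n = fit$overall$n,
             aic = fit$overall$aic, marginal_r2 = fit$overall$marginal_r2,
             effect_size = sl$slope, se = sl$se,
             chi_sq = fit$overall$chi_sq, p_value = fit$overall$p_value,
             stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline on a synthetic dataset
#'
#' Simulates a dataset, applies the selection cascade, fits and screens
#' flight curves, computes annual metrics and 20-year trends, and fits the
#' interspecific, intraspecific and annual-response models. With `out_dir`
#' set, writes every table as CSV plus a manifest of row counts and MD5
#' hashes; outputs are byte-identical across runs with the same
#' configuration.
#'
#' @param config a [sim_config()].
#' @param opts an [analysis_options()] list.
#' @param out_dir optional output directory.
#' @return list with the simulated tables (`sim`), `curves`, inclusion
#'   `reports`, `metrics`, `trends`, `models` (flat table), `model_fits`
#'   (full objects) and `manifest`.
#' @export
run_all <- function(config, opts = analysis_options(), out_dir = NULL) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  if (diff(config$study_years) + 1L < 3L)
    stop("configuration error: study window must span at least 3 years")

  sim <- simulate_dataset(config)
  study <- config$study_years

  py <- select_population_years(sim$events, sim$counts,
                                min_events = opts$min_events,
                                min_positive = opts$min_positive)
  inc_py <- py[py$included, c("population_id", "year")]
  curves <- fit_population_curves(
    sim$counts, sim$events, include = inc_py,
    plausibility_fraction = opts$plausibility_fraction,
    min_peak_height = opts$min_peak_height)
  pop_rep <- select_populations(curves, study_years = study,
                                pre_period = config$pre_period,
                                min_years = opts$min_years,
                                mode = opts$pre_period_mode)
  sp_rep <- select_species_from_populations(pop_rep, sim$counts,
                                            study_years = study,
                                            min_populations = opts$min_populations)
  heavy <- select_heavily_recorded_hectads(sim$presences, study_years = study,
                                           heavy_median_pct = opts$heavy_median_pct)
  pres_heavy <- sim$presences[
    hectad_id(sim$presences$hectad_easting, sim$presences$hectad_northing) %in%
      heavy$heavy$hectad_id, ]
  dist_rep <- select_species_distributions(
    pres_heavy, sim$elevations, northern_limit = opts$northern_limit,
    study_years = study, min_hectads = opts$min_hectads,
    max_mean_elevation = opts$max_mean_elevation_m,
    margin_buffer = opts$margin_buffer_km)

  metrics <- annual_metrics(curves, sim$counts, sim$events, sim$presences,
                            heavy$heavy, sim$temperatures, study_years = study)

  inc_pops <- pop_rep$population_id[pop_rep$included]
  inc_species <- sp_rep$species_id[sp_rep$included]
  pop_m <- metrics$population
  pop_m <- pop_m[pop_m$population_id %in% inc_pops &
                   pop_m$species_id %in% inc_species &
                   pop_m$year >= study[1] & pop_m$year <= study[2], ]
  dist_species <- dist_rep$species_id[dist_rep$level == "species_distribution" &
                                        dist_rep$included]
  margin_species <- dist_rep$species_id[dist_rep$level == "margin_subset" &
                                          dist_rep$included]
  trends <- compute_trends(pop_m, metrics$species,
                           dist_species = dist_species,
                           margin_species = margin_species)

  if (is.null(trends$species) || nrow(trends$species) == 0)
    stop("no species survived the selection cascade; ",
         "increase n_sites or n_species (each species needs at least ",
         opts$min_populations, " populations)")
  sp_tr <- merge(trends$species, sim$traits, by = "species_id")
  pop_tr <- merge(trends$population, sim$traits[, c("species_id", "voltinism")],
                  by = "species_id")

  fits <- list()
  models <- list()
  can_interact <- length(unique(sp_tr$voltinism)) > 1 && nrow(sp_tr) >= 6
  if (can_interact) {
    fits$abundance_vs_phenology <- fit_interaction_model(
      sp_tr, "abundance_change", "phenology_advance",
      covariates = "voltinism", alpha = opts$alpha)
    models$abundance_vs_phenology <-
      .flatten_model("abundance_vs_phenology", fits$abundance_vs_phenology)
    if (length(unique(sp_tr$habitat_class)) > 1) {
      fits$abundance_vs_phenology_class <- fit_interaction_model(
        sp_tr, "abundance_change", "phenology_advance",
        covariates = c("voltinism", "habitat_class"), alpha = opts$alpha)
      models$abundance_vs_phenology_class <-
        .flatten_model("abundance_vs_phenology_class",
                       fits$abundance_vs_phenology_class)
    }
    d_dist <- sp_tr[!is.na(sp_tr$distribution_change), ]
    if (nrow(d_dist) >= 6 && length(unique(d_dist$voltinism)) > 1) {
      fits$distribution_vs_phenology <- fit_interaction_model(
        d_dist, "distribution_change", "phenology_advance",
        covariates = "voltinism", alpha = opts$alpha)
      models$distribution_vs_phenology <-
        .flatten_model("distribution_vs_phenology",
                       fits$distribution_vs_phenology)
      fits$distribution_vs_abundance <- fit_interaction_model(
        d_dist, "distribution_change", "abundance_change",
        covariates = character(), alpha = opts$alpha)
      models$distribution_vs_abundance <-
        .flatten_model("distribution_vs_abundance",
                       fits$distribution_vs_abundance)
    }
    d_marg <- sp_tr[!is.na(sp_tr$margin_change), ]
    if (nrow(d_marg) >= 6) {
      fits$margin_vs_abundance <- fit_interaction_model(
        d_marg, "margin_change", "abundance_change",
        covariates = character(), alpha = opts$alpha)
      models$margin_vs_abundance <-
        .flatten_model("margin_vs_abundance", fits$margin_vs_abundance)
    }
    # Model-predicted abundance trends (phenology component) -> second stage.
    base <- fits$abundance_vs_phenology$model
    sp_tr$predicted_abundance <- predicted_abundance_trend(
      base, sp_tr[, c("phenology_advance", "voltinism", "taxon_group")])
    if (nrow(d_dist) >= 6) {
      d_dist2 <- sp_tr[!is.na(sp_tr$distribution_change), ]
      fits$distribution_vs_predicted <- fit_interaction_model(
        d_dist2, "distribution_change", "predicted_abundance",
        covariates = character(), alpha = opts$alpha)
      models$distribution_vs_predicted <-
        .flatten_model("distribution_vs_predicted",
                       fits$distribution_vs_predicted)
    }
    if (nrow(d_marg) >= 6) {
      d_marg2 <- sp_tr[!is.na(sp_tr$margin_change), ]
      fits$margin_vs_predicted <- fit_interaction_model(
        d_marg2, "margin_change", "predicted_abundance",
        covariates = character(), alpha = opts$alpha)
      models$margin_vs_predicted <-
        .flatten_model("margin_vs_predicted", fits$margin_vs_predicted)
    }
  }

  # Intraspecific population-level model.
  if (nrow(pop_tr) >= 6) {
    fits$intraspecific <- fit_intraspecific_model(pop_tr, alpha = opts$alpha)
    sb <- fits$intraspecific$subsets
    models$intraspecific <- data.frame(
      model = "intraspecific_abundance_vs_phenology", subset = sb$voltinism,
      n = sb$n, aic = sb$aic, marginal_r2 = sb$marginal_r2,
      effect_size = sb$effect_size, se = sb$se, chi_sq = sb$chi_sq,
      p_value = sb$p_value, stringsAsFactors = FALSE)
  }

  # Annual-response models on the population-level annual table.
  ann <- merge(pop_m[pop_m$fit_ok, ],
               sim$traits[, c("species_id", "voltinism")], by = "species_id")
  nxt <- ann[, c("population_id", "year", "abundance_index")]
  nxt$year <- nxt$year - 1L
  names(nxt)[3] <- "abundance_next"
  ann <- merge(ann, nxt, by = c("population_id", "year"), all.x = TRUE)
  if (nrow(ann) >= 20 && length(unique(ann$voltinism)) > 1) {
    fits$peak_vs_gdd5 <- fit_annual_response(ann, "phenology_day", "gdd5")
    models$peak_vs_gdd5 <- .annual_model_row("peakday_vs_gdd5",
                                             fits$peak_vs_gdd5)
    fits$abundance_vs_peak <- fit_annual_response(
      ann[ann$abundance_index > 0, ], "abundance_index", "phenology_day",
      log_dep = TRUE)
    models$abundance_vs_peak <- .annual_model_row("log_abundance_vs_peakday",
                                                  fits$abundance_vs_peak)
    ann_nx <- ann[!is.na(ann$abundance_next) & ann$abundance_next > 0, ]
    fits$abundance_next_vs_peak <- fit_annual_response(
      ann_nx, "abundance_next", "phenology_day", log_dep = TRUE)
    models$abundance_next_vs_peak <-
      .annual_model_row("log_abundance_next_vs_peakday",
                        fits$abundance_next_vs_peak)
    mv <- ann[ann$voltinism == "multivoltine" &
                !is.na(ann$intergenerational_ratio), ]
    if (nrow(mv) >= 20) {
      fits$ratio_vs_peak <- fit_annual_response(
        mv, "intergenerational_ratio", "phenology_day", covariate = NULL,
        log_dep = TRUE)
      models$ratio_vs_peak <- .annual_model_row("log_ratio_vs_peakday",
                                                fits$ratio_vs_peak)
    }
  }
  models <- if (length(models)) do.call(rbind, c(models, make.row.names = FALSE))
            else NULL

  reports <- list(population_year = py, population = pop_rep,
                  species = sp_rep, hectad = heavy$report,
                  species_distribution = dist_rep)
  result <- list(config = config, sim = sim, curves = curves,
                 reports = reports, heavy = heavy$heavy, metrics = metrics,
                 trends = trends, models = models, model_fits = fits)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(
      counts = "counts.csv", events = "events.csv", presences = "presences.csv",
      temperatures = "temperatures.csv", elevations = "elevations.csv",
      traits = "traits.csv", truth = "truth.csv")
    for (nm in names(files)) write_table(sim[[nm]], file.path(out_dir, files[nm]))
    write_table(curves, file.path(out_dir, "curves.csv"))
    for (nm in names(reports))
      write_table(reports[[nm]], file.path(out_dir,
                                           sprintf("inclusion_%s.csv", nm)))
    write_table(metrics$population, file.path(out_dir, "metrics_population.csv"))
    write_table(metrics$species, file.path(out_dir, "metrics_species.csv"))
    write_table(trends$species, file.path(out_dir, "trends_species.csv"))
    write_table(trends$population, file.path(out_dir, "trends_population.csv"))
    if (!is.null(models)) write_table(models, file.path(out_dir, "models.csv"))
    cfg_df <- data.frame(key = names(unlist(config)),
                         value = as.character(unlist(config)),
                         stringsAsFactors = FALSE)
    write_table(cfg_df, file.path(out_dir, "config.csv"))
    out_files <- sort(list.files(out_dir, pattern = "\\.csv$",
                                 full.names = TRUE))
    out_files <- out_files[basename(out_files) != "manifest.csv"]
    manifest <- data.frame(
      file = basename(out_files),
      md5 = unname(tools::md5sum(out_files)),
      rows = unname(vapply(out_files, function(f) length(readLines(f)) - 1L, 0L)),
      stringsAsFactors = FALSE)
    manifest <- rbind(manifest,
                      data.frame(file = "seed", md5 = as.character(config$seed),
                                 rows = NA_integer_, stringsAsFactors = FALSE))
    write_table(manifest, file.path(out_dir, "manifest.csv"))
    result$manifest <- manifest
  }
  result
}
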