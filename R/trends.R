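# 20-year rates of change. Species-level phenology and abundance trends are
# slopes of Gaussian mixed models on year with a random site intercept;
# distribution and margin trends are ordinary regressions on the single
# national series; population-level trends are ordinary regressions. The
# phenology slope's sign is reversed so that a positive trend is an advance
# (earlier emergence over time).

.trend_row <- function(unit, unit_id, variable, slope, se, n_years, n_sites) {
  data.frame(unit = unit, unit_id = unit_id, variable = variable,
             slope = slope, se = se, n_years = n_years, n_sites = n_sites,
             stringsAsFactors = FALSE)
}

.prep_trend_series <- function(metrics, variable) {
  out <- switch(variable,
    phenology_advance = data.frame(y = metrics$phenology_day,
                                   year = metrics$year,
                                   site = metrics$site_id),
    abundance_change = {
      if (any(metrics$abundance_index == 0, na.rm = TRUE))
        stop("zero abundance index in an included population-year; ",
             "selection should make this impossible")
      data.frame(y = log(metrics$abundance_index), year = metrics$year,
                 site = metrics$site_id)
    },
    distribution_change = data.frame(y = metrics$distribution_pct,
                                     year = metrics$year,
                                     site = "national"),
    margin_change = data.frame(y = metrics$margin_northing,
                               year = metrics$year, site = "national"),
    stop("unknown trend variable: ", variable)
  )
  out[!is.na(out$y), ]
}

.flip <- function(variable) if (variable == "phenology_advance") -1 else 1

#' Species-level 20-year trend
#'
#' For phenology and abundance: the year slope of a linear mixed model with
#' a random site intercept (falling back to ordinary regression when only
#' one site remains or the mixed fit fails). For distribution and margin:
#' the year slope of an ordinary regression on the national annual series.
#'
#' @param metrics per-population annual metrics for one species (columns
#'   `year`, `site_id` and the relevant variable), or the species-year table
#'   for distribution/margin variables.
#' @param variable one of `"phenology_advance"`, `"abundance_change"`,
#'   `"distribution_change"`, `"margin_change"`.
#' @param species_id identifier carried on the result.
#' @return one-row trend estimate (`slope`, `se`, `n_years`, `n_sites`),
#'   with the phenology slope sign-flipped so positive = advance.
#' @export
species_trend <- function(metrics, variable, species_id = NA_character_) {
  d <- .prep_trend_series(metrics, variable)
  n_years <- length(unique(d$year))
  n_sites <- length(unique(d$site))
  if (n_years < 3)
    return(.trend_row("species", species_id, variable, NA_real_, NA_real_,
                      n_years, n_sites))
  if (n_sites > 1) {
    co <- tryCatch(
      suppressMessages(suppressWarnings({
        fit <- lme4::lmer(y ~ year + (1 | site), data = d)
        summary(fit)$coefficients
      })),
      error = function(e) NULL)
    if (!is.null(co) && all(is.finite(co["year", c("Estimate", "Std. Error")]))) {
      return(.trend_row("species", species_id, variable,
                        .flip(variable) * co["year", "Estimate"],
                        co["year", "Std. Error"], n_years, n_sites))
    }
    warning("mixed-model trend fit failed for ", species_id,
            "; falling back to ordinary regression")
  }
  co <- suppressWarnings(summary(lm(y ~ year, data = d))$coefficients)
  .trend_row("species", species_id, variable,
             .flip(variable) * co["year", "Estimate"],
             co["year", "Std. Error"], n_years, n_sites)
}

#' Population-level 20-year trend
#'
#' Ordinary least-squares slope of the annual series for one population,
#' with the phenology sign flip. Fewer than three annual values yield an
#' absent estimate.
#'
#' @param metrics annual metrics for one population.
#' @param variable `"phenology_advance"` or `"abundance_change"`.
#' @param population_id identifier carried on the result.
#' @return one-row trend estimate.
#' @export
population_trend <- function(metrics, variable, population_id = NA_character_) {
  d <- .prep_trend_series(metrics, variable)
  n_years <- length(unique(d$year))
  if (n_years < 3)
    return(.trend_row("population", population_id, variable, NA_real_,
                      NA_real_, n_years, 1L))
  if (sd(d$y) == 0)
    return(.trend_row("population", population_id, variable, 0, 0, n_years, 1L))
  co <- suppressWarnings(summary(lm(y ~ year, data = d))$coefficients)
  .trend_row("population", population_id, variable,
             .flip(variable) * co["year", "Estimate"],
             co["year", "Std. Error"], n_years, 1L)
}

#' Trend tables for all included species and populations
#'
#' @param pop_metrics population-level annual metrics (from
#'   [annual_metrics()]), restricted to included populations and study
#'   years, with `fit_ok` rows only used for phenology.
#' @param sp_metrics species-level annual metrics.
#' @param dist_species optional species ids to keep for
#'   distribution/margin trends (the distribution selection); default all.
#' @param margin_species optional species ids in the margin subset.
#' @return list with `species` (wide data frame, one row per species with a
#'   column pair per variable) and `population` (long data frame of
#'   population-level phenology/abundance trends).
#' @export
compute_trends <- function(pop_metrics, sp_metrics, dist_species = NULL,
                           margin_species = NULL) {
  ok <- pop_metrics[pop_metrics$fit_ok, ]
  species <- sort(unique(ok$species_id))
  sp_rows <- lapply(species, function(s) {
    d <- ok[ok$species_id == s, ]
    ph <- species_trend(d, "phenology_advance", s)
    ab <- species_trend(d, "abundance_change", s)
    row <- data.frame(species_id = s,
                      phenology_advance = ph$slope, phenology_se = ph$se,
                      abundance_change = ab$slope, abundance_se = ab$se,
                      n_populations = length(unique(d$population_id)),
                      stringsAsFactors = FALSE)
    row
  })
  sp_tab <- do.call(rbind, sp_rows)
  sp_tab$distribution_change <- NA_real_
  sp_tab$distribution_se <- NA_real_
  sp_tab$margin_change <- NA_real_
  sp_tab$margin_se <- NA_real_
  for (s in sp_tab$species_id) {
    d <- sp_metrics[sp_metrics$species_id == s, ]
    if (nrow(d) == 0) next
    if (is.null(dist_species) || s %in% dist_species) {
      tr <- species_trend(d, "distribution_change", s)
      sp_tab[sp_tab$species_id == s,
             c("distribution_change", "distribution_se")] <- c(tr$slope, tr$se)
    }
    if (!is.null(margin_species) && s %in% margin_species) {
      tr <- species_trend(d, "margin_change", s)
      sp_tab[sp_tab$species_id == s,
             c("margin_change", "margin_se")] <- c(tr$slope, tr$se)
    }
  }
  pops <- sort(unique(ok$population_id))
  pop_rows <- lapply(pops, function(p) {
    d <- ok[ok$population_id == p, ]
    ph <- population_trend(d, "phenology_advance", p)
    ab <- population_trend(d, "abundance_change", p)
    data.frame(population_id = p, species_id = d$species_id[1],
               phenology_advance = ph$slope, phenology_se = ph$se,
               abundance_change = ab$slope, abundance_se = ab$se,
               n_years = ph$n_years, stringsAsFactors = FALSE)
  })
  list(species = sp_tab, population = do.call(rbind, pop_rows))
}
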