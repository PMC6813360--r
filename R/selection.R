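# The inclusion/exclusion cascade: uniform criteria applied to
# population-monitoring data (events, positive records, fitted-curve
# coverage, population and species counts) and to atlas data (recording
# effort, distribution size, elevation, range-margin subset), with
# audit-ready reports at every level.

#' Hectad identifier from grid coordinates
#'
#' @param easting,northing hectad coordinates in km (multiples of 10).
#' @return character id of the form `E010N120`.
#' @export
hectad_id <- function(easting, northing) {
  sprintf("E%03dN%03d", as.integer(easting), as.integer(northing))
}

.report <- function(level, unit_id, included, reasons, extra = NULL) {
  out <- data.frame(level = level, unit_id = unit_id, included = included,
                    reasons = reasons, stringsAsFactors = FALSE)
  if (!is.null(extra)) out <- cbind(out, extra)
  rownames(out) <- NULL
  out
}

#' Select population-years with sufficient recording
#'
#' A population-year is included iff its site-year had at least
#' `min_events` recording events (of any species) and the focal species was
#' recorded (count > 0) at no fewer than `min_positive` of them.
#'
#' @param events recording events (`site_id`, `date`).
#' @param counts count records (`site_id`, `species_id`, `date`, `count`);
#'   every count must refer to a listed event.
#' @param min_events,min_positive thresholds (defaults 10 and 3).
#' @return inclusion report, one row per population-year, with measured
#'   `n_events` and `n_positive`.
#' @export
select_population_years <- function(events, counts, min_events = 10L,
                                    min_positive = 3L) {
  events$date <- as.Date(events$date)
  counts$date <- as.Date(counts$date)
  ev_key <- paste(events$site_id, events$date)
  if (!all(paste(counts$site_id, counts$date) %in% ev_key))
    stop("counts reference recording events absent from the events table")
  events$year <- as.integer(format(events$date, "%Y"))
  counts$year <- as.integer(format(counts$date, "%Y"))
  n_events <- tapply(ev_key, paste(events$site_id, events$year),
                     function(x) length(unique(x)))
  counts$population_id <- paste(counts$site_id, counts$species_id, sep = ":")
  units <- unique(counts[, c("population_id", "site_id", "species_id", "year")])
  pos <- counts[counts$count > 0, ]
  n_pos <- tapply(paste(pos$site_id, pos$date),
                  paste(pos$population_id, pos$year),
                  function(x) length(unique(x)))
  ne <- as.integer(n_events[paste(units$site_id, units$year)])
  np <- as.integer(n_pos[paste(units$population_id, units$year)])
  np[is.na(np)] <- 0L
  ok_e <- ne >= min_events
  ok_p <- np >= min_positive
  reasons <- ifelse(ok_e & ok_p, "",
                    trimws(paste(ifelse(ok_e, "", sprintf("events_lt_%d=%d", min_events, ne)),
                                 ifelse(ok_p, "", sprintf("positive_lt_%d=%d", min_positive, np)))))
  .report("population_year", paste(units$population_id, units$year, sep = "@"),
          ok_e & ok_p, reasons,
          data.frame(population_id = units$population_id,
                     species_id = units$species_id, site_id = units$site_id,
                     year = units$year, n_events = ne, n_positive = np,
                     stringsAsFactors = FALSE))
}

#' Select populations with adequate fitted-curve coverage
#'
#' A population is included iff it has successfully fitted flight curves in
#' at least `min_years` years of the study period and in at least one year
#' of the pre-period (which screens out sites colonised just before the
#' study window). With `mode = "recorded"` the pre-period rule instead
#' requires any attempted (recorded) year.
#'
#' @param curve_results output of [fit_population_curves()].
#' @param study_years,pre_period inclusive year ranges.
#' @param min_years minimum successfully fitted study-period years.
#' @param mode `"fitted"` (default) or `"recorded"` for the pre-period rule.
#' @return inclusion report, one row per population.
#' @export
select_populations <- function(curve_results,
                               study_years = c(1995L, 2014L),
                               pre_period = c(1980L, 1990L),
                               min_years = 15L,
                               mode = c("fitted", "recorded")) {
  mode <- match.arg(mode)
  cr <- curve_results
  sp <- split(cr, cr$population_id)
  unit <- names(sp)
  n_ok <- vapply(sp, function(d)
    sum(d$fit_ok & d$year >= study_years[1] & d$year <= study_years[2]), 0L)
  pre_ok <- vapply(sp, function(d) {
    in_pre <- d$year >= pre_period[1] & d$year <= pre_period[2]
    if (mode == "fitted") any(d$fit_ok & in_pre) else any(in_pre)
  }, logical(1))
  ok <- n_ok >= min_years & pre_ok
  reasons <- ifelse(ok, "",
                    trimws(paste(
                      ifelse(n_ok >= min_years, "",
                             sprintf("fitted_years_lt_%d=%d", min_years, n_ok)),
                      ifelse(pre_ok, "", "no_pre_period_year"))))
  .report("population", unit, ok, reasons,
          data.frame(population_id = unit,
                     species_id = vapply(sp, function(d) d$species_id[1], ""),
                     n_fitted_study_years = as.integer(n_ok),
                     pre_period_ok = pre_ok, stringsAsFactors = FALSE))
}

#' Select species with enough well-covered populations
#'
#' A species is included iff at least `min_populations` of its populations
#' passed [select_populations()] and, jointly, those populations have a
#' positive record in every year of the study period.
#'
#' @param population_reports report from [select_populations()].
#' @param counts count records (used for year coverage; count > 0 rows are
#'   records).
#' @param study_years inclusive study window.
#' @param min_populations minimum included populations (default 3).
#' @return inclusion report, one row per species present in the population
#'   report.
#' @export
select_species_from_populations <- function(population_reports, counts,
                                            study_years = c(1995L, 2014L),
                                            min_populations = 3L) {
  counts$date <- as.Date(counts$date)
  counts$year <- as.integer(format(counts$date, "%Y"))
  counts$population_id <- paste(counts$site_id, counts$species_id, sep = ":")
  inc <- population_reports[population_reports$included, ]
  yrs <- seq(study_years[1], study_years[2])
  species <- sort(unique(population_reports$species_id))
  n_pops <- vapply(species, function(s)
    sum(inc$species_id == s), 0L)
  covered <- vapply(species, function(s) {
    pops <- inc$population_id[inc$species_id == s]
    rec <- counts[counts$population_id %in% pops & counts$count > 0 &
                    counts$year %in% yrs, "year"]
    all(yrs %in% rec)
  }, logical(1))
  ok <- n_pops >= min_populations & covered
  reasons <- ifelse(ok, "",
                    trimws(paste(
                      ifelse(n_pops >= min_populations, "",
                             sprintf("populations_lt_%d=%d", min_populations, n_pops)),
                      ifelse(covered, "", "study_years_not_covered"))))
  .report("species", species, ok, reasons,
          data.frame(species_id = species, n_included_populations = as.integer(n_pops),
                     years_covered = covered, stringsAsFactors = FALSE))
}

#' Select heavily recorded hectads
#'
#' Step 1 drops hectads without an any-species record in both halves of the
#' study period. Step 2 computes, for each surviving hectad and study year,
#' the hectad's species richness as a percentage of the combined richness of
#' its 100 nearest neighbouring hectads (the surrounding region, excluding
#' the hectad itself; Euclidean centroid distance, ties broken by northing
#' then easting), and keeps hectads whose median percentage over all study
#' years is at least `heavy_median_pct`. Years with zero regional richness
#' contribute 0%.
#'
#' @param presences atlas records (`species_id`, `hectad_easting`,
#'   `hectad_northing`, `year`).
#' @param study_years inclusive study window.
#' @param n_neighbours regional neighbourhood size (default 100).
#' @param heavy_median_pct median regional-richness percentage threshold.
#' @return list with `heavy` (data frame of surviving hectads with
#'   coordinates) and `report` (inclusion report, one row per hectad seen in
#'   the input).
#' @export
select_heavily_recorded_hectads <- function(presences,
                                            study_years = c(1995L, 2014L),
                                            n_neighbours = 100L,
                                            heavy_median_pct = 25) {
  pr <- presences[presences$year >= study_years[1] &
                    presences$year <= study_years[2], ]
  hect <- unique(presences[, c("hectad_easting", "hectad_northing")])
  hect <- hect[order(hect$hectad_northing, hect$hectad_easting), ]
  rownames(hect) <- NULL
  if (nrow(hect) < n_neighbours + 1L)
    stop(sprintf("need at least %d hectads to define the %d-nearest-neighbour region, got %d",
                 n_neighbours + 1L, n_neighbours, nrow(hect)))
  hect$hectad_id <- hectad_id(hect$hectad_easting, hect$hectad_northing)
  pr$hectad_id <- hectad_id(pr$hectad_easting, pr$hectad_northing)

  half <- study_years[1] + (diff(study_years) + 1L) %/% 2L - 1L
  rec1 <- unique(pr$hectad_id[pr$year <= half])
  rec2 <- unique(pr$hectad_id[pr$year > half])
  halves_ok <- hect$hectad_id %in% rec1 & hect$hectad_id %in% rec2

  yrs <- seq(study_years[1], study_years[2])
  surv <- hect[halves_ok, ]
  med_pct <- rep(NA_real_, nrow(hect))
  names(med_pct) <- hect$hectad_id
  if (nrow(surv) >= 2) {
    # species sets per hectad-year, over surviving hectads only
    pr_s <- pr[pr$hectad_id %in% surv$hectad_id, ]
    sets <- split(pr_s$species_id, paste(pr_s$hectad_id, pr_s$year))
    sets <- lapply(sets, unique)
    d2 <- outer(surv$hectad_easting, surv$hectad_easting, "-")^2 +
      outer(surv$hectad_northing, surv$hectad_northing, "-")^2
    for (i in seq_len(nrow(surv))) {
      ord <- order(d2[i, ], surv$hectad_northing, surv$hectad_easting)
      ord <- ord[ord != i]
      nb <- surv$hectad_id[ord[seq_len(min(n_neighbours, length(ord)))]]
      pct <- vapply(yrs, function(y) {
        own <- sets[[paste(surv$hectad_id[i], y)]]
        reg <- unique(unlist(sets[paste(nb, y)], use.names = FALSE))
        if (length(reg) == 0) return(0)
        100 * length(own) / length(reg)
      }, numeric(1))
      med_pct[surv$hectad_id[i]] <- median(pct)
    }
  }
  ok <- halves_ok & !is.na(med_pct) & med_pct >= heavy_median_pct
  reasons <- ifelse(ok, "",
                    ifelse(!halves_ok, "not_recorded_in_both_halves",
                           sprintf("median_richness_pct_lt_%g=%.1f",
                                   heavy_median_pct, med_pct)))
  report <- .report("hectad", hect$hectad_id, ok, reasons,
                    data.frame(hectad_easting = hect$hectad_easting,
                               hectad_northing = hect$hectad_northing,
                               median_richness_pct = round(unname(med_pct), 2),
                               stringsAsFactors = FALSE))
  list(heavy = hect[ok, c("hectad_id", "hectad_easting", "hectad_northing")],
       report = report)
}

#' Select species for distribution analyses and the margin subset
#'
#' From presences restricted to heavily recorded hectads: species occupying
#' fewer than `min_hectads` hectads over the full study period are excluded
#' (distribution too small), as are species whose recorded hectads have mean
#' elevation above `max_mean_elevation` (upland species, whose climate
#' response may be elevational). Species whose full-period range margin lies
#' within `margin_buffer` km of the northern limit are flagged out of the
#' margin subset but stay in the main set.
#'
#' @param presences atlas records already restricted to heavy hectads.
#' @param elevations hectad elevations (`easting`, `northing`,
#'   `elevation_m`); required for every recorded hectad.
#' @param northern_limit northing (km) of the northernmost point of the
#'   grid; defaults to the maximum hectad northing in `presences`.
#' @param study_years inclusive study window.
#' @param min_hectads,max_mean_elevation,margin_buffer thresholds
#'   (defaults 20 hectads, 200 m, 100 km).
#' @return inclusion report with one `species_distribution` row and one
#'   `margin_subset` row per species.
#' @export
select_species_distributions <- function(presences, elevations,
                                         northern_limit = NULL,
                                         study_years = c(1995L, 2014L),
                                         min_hectads = 20L,
                                         max_mean_elevation = 200,
                                         margin_buffer = 100) {
  pr <- presences[presences$year >= study_years[1] &
                    presences$year <= study_years[2], ]
  pr$hectad_id <- hectad_id(pr$hectad_easting, pr$hectad_northing)
  elevations$hectad_id <- hectad_id(elevations$easting, elevations$northing)
  if (is.null(northern_limit)) northern_limit <- max(pr$hectad_northing)
  species <- sort(unique(pr$species_id))
  occ <- lapply(split(pr, pr$species_id), function(d)
    unique(d[, c("hectad_id", "hectad_northing")]))
  missing_elev <- setdiff(unique(pr$hectad_id), elevations$hectad_id)
  if (length(missing_elev) > 0)
    stop("missing elevation for occupied hectads: ",
         paste(missing_elev, collapse = ", "))

  n_hect <- vapply(species, function(s) nrow(occ[[s]]), 0L)
  mean_elev <- vapply(species, function(s)
    mean(elevations$elevation_m[match(occ[[s]]$hectad_id,
                                      elevations$hectad_id)]), numeric(1))
  margin <- vapply(species, function(s)
    margin_northing(occ[[s]]$hectad_northing), numeric(1))

  ok_n <- n_hect >= min_hectads
  ok_e <- mean_elev <= max_mean_elevation
  main_ok <- ok_n & ok_e
  reasons <- ifelse(main_ok, "",
                    trimws(paste(
                      ifelse(ok_n, "", sprintf("hectads_lt_%d=%d", min_hectads, n_hect)),
                      ifelse(ok_e, "", sprintf("mean_elevation_gt_%g=%.0f",
                                               max_mean_elevation, mean_elev)))))
  extra <- data.frame(species_id = species, n_heavy_hectads = n_hect,
                      mean_elevation_m = round(mean_elev, 1),
                      margin_northing_km = round(margin, 1),
                      stringsAsFactors = FALSE)
  main <- .report("species_distribution", species, main_ok, reasons, extra)
  in_margin <- main_ok & (margin < northern_limit - margin_buffer)
  m_reason <- ifelse(in_margin, "",
                     ifelse(!main_ok, "excluded_from_main_set",
                            sprintf("margin_within_%gkm_of_limit=%.1f",
                                    margin_buffer, northern_limit - margin)))
  marg <- .report("margin_subset", species, in_margin, m_reason, extra)
  rbind(main, marg)
}
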