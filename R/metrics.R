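# Annual variables: phenology (first-peak day, from the curve module),
# abundance per recording event, occupied-distribution percentage, range
# margin northing, and spring growing degree days (GDD5).

#' Mean abundance per recording event
#'
#' Total individuals recorded in a population-year divided by the number of
#' recording events that year (zero counts included).
#'
#' @param counts non-negative integer counts for the population-year; events
#'   with no count row are implicit zeros, so only `n_events` matters for
#'   the denominator.
#' @param n_events number of recording events in the site-year (> 0).
#' @return mean individuals per recording event.
#' @export
abundance_index <- function(counts, n_events) {
  if (length(n_events) != 1 || is.na(n_events) || n_events <= 0)
    stop("n_events must be a positive count")
  if (any(counts < 0)) stop("counts must be non-negative")
  sum(counts) / n_events
}

#' Percentage of the recordable distribution occupied
#'
#' 100 x occupied / recorded heavily recorded hectads in a year; the
#' year-specific denominator accounts for growth in the number of heavy
#' hectads with any records in later years.
#'
#' @param occupied hectad ids occupied by the focal species in the year.
#' @param recorded hectad ids (heavy hectads with any species recorded) in
#'   the year; must be non-empty and a superset of `occupied`.
#' @return percentage in \[0, 100\].
#' @export
distribution_pct <- function(occupied, recorded) {
  recorded <- unique(recorded)
  occupied <- unique(occupied)
  if (length(recorded) == 0) stop("recorded hectad set is empty")
  if (!all(occupied %in% recorded))
    stop("occupied hectads must be a subset of recorded hectads")
  100 * length(occupied) / length(recorded)
}

#' Range-margin northing
#'
#' Mean northing of the ten most northerly occupied hectads, including all
#' hectads tied with the tenth.
#'
#' @param northings occupied hectad northings (km) for one species-year.
#' @param n_margin number of most-northerly hectads to average (default 10).
#' @return mean northing in km, or `NA` for an empty set.
#' @export
margin_northing <- function(northings, n_margin = 10L) {
  northings <- northings[!is.na(northings)]
  if (length(northings) == 0) return(NA_real_)
  s <- sort(northings, decreasing = TRUE)
  if (length(s) <= n_margin) return(mean(s))
  cutoff <- s[n_margin]
  mean(s[s >= cutoff])
}

#' Spring growing degree days above 5 degrees C
#'
#' Sum over 1 March-31 May (inclusive; 92 days on the 365-day calendar) of
#' the daily mean temperature excess above 5 degrees C.
#'
#' @param tmean_df daily series for one site-year with columns `date` (or
#'   `doy`) and `tmean`; the window must be complete.
#' @return degree days (non-negative).
#' @export
gdd5 <- function(tmean_df) {
  doy <- if ("doy" %in% names(tmean_df)) as.integer(tmean_df$doy)
         else doy365(tmean_df$date)
  win <- seq(.gdd5_window[1], .gdd5_window[2])
  missing <- setdiff(win, doy)
  if (length(missing) > 0)
    stop("incomplete spring series; missing day(s) of year: ",
         paste(missing, collapse = ", "))
  sel <- doy %in% win & !duplicated(doy)
  sum(pmax(tmean_df$tmean[sel] - 5, 0))
}

#' Annual population- and species-level metric tables
#'
#' Joins the curve summaries, counts, events, heavy-hectad presences and
#' temperatures into the two metric tables the trend layer consumes:
#' per population-year (phenology day, abundance index, intergenerational
#' ratio, site GDD5) and per species-year (distribution percentage, margin
#' northing).
#'
#' @param curve_results output of [fit_population_curves()] (screened fits).
#' @param counts,events count and event tables (as from
#'   [simulate_dataset()]).
#' @param presences atlas records restricted to heavily recorded hectads.
#' @param heavy heavy-hectad table from [select_heavily_recorded_hectads()].
#' @param temperatures daily site temperatures.
#' @param study_years inclusive study window for the species-level table.
#' @return list with `population` and `species` data frames.
#' @export
annual_metrics <- function(curve_results, counts, events, presences, heavy,
                           temperatures, study_years = c(1995L, 2014L)) {
  events$date <- as.Date(events$date)
  events$year <- as.integer(format(events$date, "%Y"))
  counts$date <- as.Date(counts$date)
  counts$year <- as.integer(format(counts$date, "%Y"))
  counts$population_id <- paste(counts$site_id, counts$species_id, sep = ":")

  n_events <- tapply(paste(events$site_id, events$date),
                     paste(events$site_id, events$year),
                     function(x) length(unique(x)))
  tot <- tapply(counts$count, paste(counts$population_id, counts$year), sum)

  gtab <- .gdd5_table(temperatures)
  cr <- curve_results
  cr$abundance_index <- as.numeric(tot[paste(cr$population_id, cr$year)]) /
    as.numeric(n_events[paste(cr$site_id, cr$year)])
  cr$gdd5 <- gtab$gdd5[match(paste(cr$site_id, cr$year),
                             paste(gtab$site_id, gtab$year))]
  pop <- cr[, c("population_id", "species_id", "site_id", "year", "fit_ok",
                "first_peak_day", "intergenerational_ratio",
                "abundance_index", "gdd5")]
  names(pop)[names(pop) == "first_peak_day"] <- "phenology_day"

  pr <- presences[presences$year >= study_years[1] &
                    presences$year <= study_years[2], ]
  pr$hectad_id <- hectad_id(pr$hectad_easting, pr$hectad_northing)
  pr <- pr[pr$hectad_id %in% heavy$hectad_id, ]
  yrs <- seq(study_years[1], study_years[2])
  recorded_by_year <- lapply(setNames(yrs, yrs), function(y)
    unique(pr$hectad_id[pr$year == y]))
  species <- sort(unique(pr$species_id))
  sp_rows <- expand.grid(species_id = species, year = yrs,
                         stringsAsFactors = FALSE)
  sp_rows$distribution_pct <- NA_real_
  sp_rows$margin_northing <- NA_real_
  for (i in seq_len(nrow(sp_rows))) {
    rec <- recorded_by_year[[as.character(sp_rows$year[i])]]
    d <- pr[pr$species_id == sp_rows$species_id[i] &
              pr$year == sp_rows$year[i], ]
    if (length(rec) == 0) next
    sp_rows$distribution_pct[i] <- distribution_pct(d$hectad_id, rec)
    if (nrow(d) > 0)
      sp_rows$margin_northing[i] <- margin_northing(d$hectad_northing)
  }
  list(population = pop, species = sp_rows)
}
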