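# A small deterministic world, built in code, whose pass/fail outcome at
# every level of the selection cascade can be computed by hand. Used by the
# golden selection tests and as a worked example of the cascade.

#' Toy dataset with hand-computable selection outcomes
#'
#' Constructs, without randomness, the inputs to every level of the
#' selection cascade:
#'
#' * `events`/`counts`: site `s1` with 10 recording events in 2001 and 9 in
#'   2002; species `spx` has 3 positive events in 2001 (included) and full
#'   positivity in 2002 (excluded: too few events); species `spy` has 2
#'   positive events in 2001 (excluded: too few positive events). 3
#'   population-year units, 1 included.
#' * `curve_results`/`coverage_counts`: species `spA` with populations
#'   `a1`-`a3` fitted in 15 study years plus 1985 (included) and `a4` (20
#'   study years, no pre-period year) and `a5` (14 study years) excluded;
#'   species `spB` with 2 included populations; species `spC` with 3
#'   included populations but no record anywhere in 2003. 10 population
#'   units, 8 included; 3 species units, 1 (`spA`) included.
#' * `presences`/`elevations`: a 10 x 11 hectad grid (110 hectads). Hectad
#'   `E000N000` is recorded only in 1995-2004 (fails the halves rule) and
#'   `E090N100` records 1 of the region's 5 species each year (20% median,
#'   fails the richness rule): 110 hectad units, 108 included. Species
#'   `sp1` (ubiquitous, low elevation) is included; `sp2` occupies 19 heavy
#'   hectads (excluded); `sp3` occupies 30 hectads of mean elevation 300 m
#'   (excluded); `sp4` (northing 70-100) and `sp5` (northing 0-30) are
#'   included, and with a 40-km margin buffer only `sp5` enters the margin
#'   subset: 5 distribution units, 3 included; margin subset 1.
#'
#' @return list with `events`, `counts`, `curve_results`,
#'   `coverage_counts`, `presences`, `elevations`, `margin_buffer`, and
#'   `golden` (the hand-computed unit and inclusion counts per level).
#' @export
toy_selection_data <- function() {
  # --- population-year level -------------------------------------------
  ev_dates <- c(date_from_doy365(2001, seq(120, 210, by = 10)),  # 10 events
                date_from_doy365(2002, seq(120, 200, by = 10)))  # 9 events
  events <- data.frame(site_id = "s1", date = ev_dates,
                       scheme = "transect", stringsAsFactors = FALSE)
  counts <- rbind(
    data.frame(site_id = "s1", species_id = "spx", date = ev_dates,
               count = c(c(1, 2, 1, rep(0, 7)), rep(1, 9)),
               scheme = "transect", stringsAsFactors = FALSE),
    data.frame(site_id = "s1", species_id = "spy",
               date = ev_dates[1:10], count = c(1, 1, rep(0, 8)),
               scheme = "transect", stringsAsFactors = FALSE))

  # --- population and species levels -----------------------------------
  ok_years <- function(years) years
  mk_curve <- function(site, species, years_ok, years_bad = integer()) {
    yrs <- c(years_ok, years_bad)
    data.frame(population_id = paste(site, species, sep = ":"),
               species_id = species, site_id = site, year = yrs,
               scheme = "transect",
               fit_ok = c(rep(TRUE, length(years_ok)),
                          rep(FALSE, length(years_bad))),
               fail_reason = c(rep("none", length(years_ok)),
                               rep("no_peak", length(years_bad))),
               first_peak_day = NA_integer_, trough_day = NA_integer_,
               intergenerational_ratio = NA_real_, stringsAsFactors = FALSE)
  }
  good_years <- c(1985L, 1995:2009)            # 15 study years + pre-period
  curve_results <- rbind(
    mk_curve("a1", "spA", good_years), mk_curve("a2", "spA", good_years),
    mk_curve("a3", "spA", good_years),
    mk_curve("a4", "spA", 1995:2014),          # no pre-period year
    mk_curve("a5", "spA", c(1985L, 1995:2008)),  # 14 study years
    mk_curve("b1", "spB", good_years), mk_curve("b2", "spB", good_years),
    mk_curve("c1", "spC", good_years), mk_curve("c2", "spC", good_years),
    mk_curve("c3", "spC", good_years))
  cover <- function(site, species, years) {
    data.frame(site_id = site, species_id = species,
               date = date_from_doy365(years, 180), count = 5L,
               scheme = "transect", stringsAsFactors = FALSE)
  }
  coverage_counts <- rbind(
    cover("a1", "spA", 1995:2014), cover("a2", "spA", 1995:2009),
    cover("a3", "spA", 1995:2009),
    cover("b1", "spB", 1995:2014), cover("b2", "spB", 1995:2014),
    cover("c1", "spC", setdiff(1995:2014, 2003L)),
    cover("c2", "spC", setdiff(1995:2014, 2003L)),
    cover("c3", "spC", setdiff(1995:2014, 2003L)))

  # --- hectad and species-distribution levels --------------------------
  grid <- expand.grid(hectad_easting = seq(0L, 90L, by = 10L),
                      hectad_northing = seq(0L, 100L, by = 10L))
  grid <- grid[order(grid$hectad_northing, grid$hectad_easting), ]
  hid <- hectad_id(grid$hectad_easting, grid$hectad_northing)
  x_id <- "E000N000"   # recorded first half only
  y_id <- "E090N100"   # poorly recorded: 1 of 5 regional species
  yrs <- 1995:2014
  occupy <- function(species, sel, years) {
    g <- grid[sel, ]
    data.frame(species_id = species,
               hectad_easting = rep(g$hectad_easting, times = length(years)),
               hectad_northing = rep(g$hectad_northing, times = length(years)),
               year = rep(years, each = nrow(g)), stringsAsFactors = FALSE)
  }
  sp3_sel <- grid$hectad_northing %in% c(40L, 50L, 60L)   # 30 upland cells
  presences <- rbind(
    occupy("sp1", hid != x_id & hid != y_id, yrs),
    occupy("sp1", hid == x_id, 1995:2004),            # halves-rule failure
    occupy("sp1", hid == y_id, yrs),                  # sole species at Y
    occupy("sp2", which(hid != x_id & hid != y_id &
                          grid$hectad_northing <= 10L)[1:19], yrs),
    occupy("sp3", sp3_sel, yrs),
    occupy("sp4", grid$hectad_northing >= 70L & hid != y_id, yrs),
    occupy("sp5", grid$hectad_northing <= 30L & hid != x_id, yrs))
  elevations <- data.frame(easting = grid$hectad_easting,
                           northing = grid$hectad_northing,
                           elevation_m = ifelse(sp3_sel, 300, 100),
                           stringsAsFactors = FALSE)

  golden <- list(
    population_year = c(units = 3L, included = 1L),
    population = c(units = 10L, included = 8L),
    species = c(units = 3L, included = 1L),
    hectad = c(units = 110L, included = 108L),
    species_distribution = c(units = 5L, included = 3L),
    margin_subset = c(units = 5L, included = 1L))

  list(events = events, counts = counts, curve_results = curve_results,
       coverage_counts = coverage_counts, presences = presences,
       elevations = elevations, margin_buffer = 40, golden = golden)
}
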