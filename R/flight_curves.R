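# Per-population-year seasonal flight curves: penalized Poisson spline fits
# with REML smoothness selection, screening of implausible fits, and
# extraction of the first-generation peak, the inter-brood trough and the
# intergenerational abundance ratio.

#' Fit a seasonal flight curve for one population-year
#'
#' Fits expected count against day-of-year by a penalized cubic regression
#' spline (20 basis functions, second-derivative penalty) under a Poisson
#' likelihood, with the smoothing parameter selected by REML, and predicts
#' on every integer day of the recording window. Fit and screening failures
#' are recorded in `fail_reason`, never raised.
#'
#' @param counts data frame with columns `date` (or `doy`) and `count` for
#'   one population-year; zero counts for events where the species was
#'   absent must be present (the upstream selection supplies them). Events
#'   missing from `counts` are taken as explicit zeros.
#' @param events data frame of recording events with a `date` (or `doy`)
#'   column, one row per event.
#' @param scheme `"transect"` or `"trap"`; sets the prediction window.
#' @param k spline basis dimension.
#' @param plausibility_fraction minimum height of a local maximum, as a
#'   fraction of the curve maximum, for it to count as a generation peak.
#' @param min_peak_height absolute floor (expected individuals per event)
#'   below which local maxima are regarded as numerical wiggle, not a peak.
#' @param population_id,year optional identifiers carried on the result.
#' @return an object of class `daily_curve`: list with `days`, `predicted`,
#'   `jan1` (predicted abundance on 1 January, extrapolated for transect
#'   windows), `fit_ok`, `fail_reason` (`"none"`, `"jan1_gt1"`, `"no_peak"`,
#'   `"peak_on_boundary"` or `"fit_error"`), `window`, `scheme` and the
#'   identifiers.
#' @export
fit_seasonal_curve <- function(counts, events, scheme = c("transect", "trap"),
                               k = 20, plausibility_fraction = 0.05,
                               min_peak_height = 0.05,
                               population_id = NA_character_,
                               year = NA_integer_) {
  scheme <- match.arg(scheme)
  win <- scheme_window(scheme)
  ev_doy <- if ("doy" %in% names(events)) as.integer(events$doy)
            else doy365(events$date)
  ct_doy <- if ("doy" %in% names(counts)) as.integer(counts$doy)
            else doy365(counts$date)
  y <- counts$count[match(ev_doy, ct_doy)]
  y[is.na(y)] <- 0L

  curve <- list(population_id = population_id, year = year, scheme = scheme,
                window = win, days = seq(win[1], win[2]),
                predicted = NULL, jan1 = NA_real_,
                fit_ok = FALSE, fail_reason = "fit_error",
                plausibility_fraction = plausibility_fraction,
                min_peak_height = min_peak_height)
  class(curve) <- "daily_curve"

  if (length(ev_doy) < 3) return(curve)
  dat <- data.frame(doy = ev_doy, count = y)
  fit <- tryCatch(
    suppressWarnings(
      mgcv::gam(count ~ s(doy, k = k, bs = "cr"), family = stats::poisson(),
                method = "REML", data = dat)),
    error = function(e) NULL
  )
  if (is.null(fit)) return(curve)
  pred_days <- unique(c(1L, curve$days))
  pr <- tryCatch(
    as.numeric(predict(fit, data.frame(doy = pred_days), type = "response")),
    error = function(e) NULL
  )
  if (is.null(pr) || any(!is.finite(pr))) return(curve)
  curve$jan1 <- pr[pred_days == 1L]
  curve$predicted <- pr[match(curve$days, pred_days)]
  scr <- screen_curve(curve)
  curve$fit_ok <- scr$pass
  curve$fail_reason <- if (scr$pass) "none" else scr$reason
  curve
}

# Locate candidate peaks in a daily series. Runs of equal values are
# collapsed; an interior run is a peak if it exceeds both flanking runs, and
# its peak day is the run's last day (plateau convention). A boundary run is
# flagged as a boundary peak if it exceeds its single neighbour.
.find_peaks <- function(x) {
  r <- rle(x)
  m <- length(r$values)
  if (m < 2) return(data.frame(index = integer(), height = numeric(),
                               boundary = logical()))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- integer(); hgt <- numeric(); bnd <- logical()
  for (i in seq_len(m)) {
    v <- r$values[i]
    if (i == 1L) {
      if (v > r$values[2]) { idx <- c(idx, starts[1]); hgt <- c(hgt, v); bnd <- c(bnd, TRUE) }
    } else if (i == m) {
      if (v > r$values[m - 1]) { idx <- c(idx, ends[m]); hgt <- c(hgt, v); bnd <- c(bnd, TRUE) }
    } else if (v > r$values[i - 1] && v > r$values[i + 1]) {
      idx <- c(idx, ends[i]); hgt <- c(hgt, v); bnd <- c(bnd, FALSE)
    }
  }
  data.frame(index = idx, height = hgt, boundary = bnd)
}

.qualifying_peaks <- function(curve) {
  x <- curve$predicted
  pk <- .find_peaks(x)
  if (nrow(pk) == 0) return(pk)
  thr <- max(curve$plausibility_fraction * max(x), curve$min_peak_height)
  pk[pk$height >= thr, , drop = FALSE]
}

#' Screen a fitted flight curve for plausibility
#'
#' A curve fails if predicted abundance on 1 January exceeds 1, if no day's
#' prediction exceeds both its neighbours (no generation peak), or if the
#' first qualifying peak falls on the first or last day of the recording
#' window (first-generation individuals flying at the window edge, so the
#' peak day cannot be estimated reliably).
#'
#' @param curve a `daily_curve` with predictions.
#' @return list with `pass` (logical) and `reason` (`"none"`, `"jan1_gt1"`,
#'   `"no_peak"` or `"peak_on_boundary"`).
#' @export
screen_curve <- function(curve) {
  if (is.null(curve$predicted)) return(list(pass = FALSE, reason = "fit_error"))
  if (is.finite(curve$jan1) && curve$jan1 > 1)
    return(list(pass = FALSE, reason = "jan1_gt1"))
  pk <- .qualifying_peaks(curve)
  if (nrow(pk) == 0) return(list(pass = FALSE, reason = "no_peak"))
  first <- pk[which.min(pk$index), ]
  if (first$boundary) return(list(pass = FALSE, reason = "peak_on_boundary"))
  list(pass = TRUE, reason = "none")
}

#' First-generation peak day of a screened curve
#'
#' The earliest interior local maximum whose height reaches the plausibility
#' threshold; ties between equal-height competing peaks resolve to the
#' earliest day.
#'
#' @param curve a `daily_curve` that passed [screen_curve()].
#' @return integer day-of-year of the first generation's peak.
#' @export
find_first_peak <- function(curve) {
  pk <- .qualifying_peaks(curve)
  pk <- pk[!pk$boundary, , drop = FALSE]
  if (nrow(pk) == 0)
    stop("no qualifying peak: curve should not have passed screening")
  curve$days[min(pk$index)]
}

#' Inter-brood trough and intergenerational abundance ratio
#'
#' The trough is the day of minimum predicted abundance strictly between the
#' first peak and the next qualifying peak; it is absent (with the ratio)
#' for unimodal curves. The ratio is the sum of predicted daily abundance on
#' days after the trough divided by the sum on days up to and including the
#' trough, so larger values mean proportionally larger later generations.
#'
#' @param curve a screened `daily_curve`.
#' @param first_peak_day day returned by [find_first_peak()].
#' @return list with `first_peak_day`, `trough_day` (NA if unimodal) and
#'   `intergenerational_ratio` (NA if unimodal).
#' @export
find_trough_and_ratio <- function(curve, first_peak_day) {
  pk <- .qualifying_peaks(curve)
  pk <- pk[!pk$boundary, , drop = FALSE]
  out <- list(first_peak_day = first_peak_day,
              trough_day = NA_integer_,
              intergenerational_ratio = NA_real_)
  later <- pk$index[curve$days[pk$index] > first_peak_day]
  if (length(later) == 0) return(out)
  i1 <- match(first_peak_day, curve$days)
  i2 <- min(later)
  if (i2 - i1 < 2) return(out)
  between <- (i1 + 1):(i2 - 1)
  tr <- between[which.min(curve$predicted[between])]
  before <- sum(curve$predicted[seq_len(tr)])
  after <- sum(curve$predicted[seq(tr + 1, length(curve$days))])
  out$trough_day <- curve$days[tr]
  out$intergenerational_ratio <- after / before
  out
}

#' Fit and summarise flight curves for many population-years
#'
#' Loops [fit_seasonal_curve()] over every population-year present in
#' `counts` (optionally restricted to `include`), screens each fit, and
#' extracts the first peak, trough and intergenerational ratio.
#'
#' @param counts count records (`site_id`, `species_id`, `date`, `count`,
#'   `scheme`) including explicit zeros.
#' @param events recording events (`site_id`, `date`).
#' @param include optional data frame of `population_id`, `year` rows to fit
#'   (e.g. the included units from [select_population_years()]); default all.
#' @param ... passed to [fit_seasonal_curve()].
#' @return data frame with one row per population-year: `population_id`,
#'   `species_id`, `site_id`, `year`, `scheme`, `fit_ok`, `fail_reason`,
#'   `first_peak_day`, `trough_day`, `intergenerational_ratio`.
#' @export
fit_population_curves <- function(counts, events, include = NULL, ...) {
  counts$year <- as.integer(format(as.Date(counts$date), "%Y"))
  events$year <- as.integer(format(as.Date(events$date), "%Y"))
  counts$population_id <- paste(counts$site_id, counts$species_id, sep = ":")
  key <- unique(counts[, c("population_id", "site_id", "species_id",
                           "year", "scheme")])
  if (!is.null(include)) {
    key <- key[paste(key$population_id, key$year) %in%
                 paste(include$population_id, include$year), ]
  }
  key <- key[order(key$population_id, key$year), ]
  ev_split <- split(events, paste(events$site_id, events$year))
  ct_split <- split(counts[, c("date", "count")],
                    paste(counts$population_id, counts$year))
  res <- vector("list", nrow(key))
  for (i in seq_len(nrow(key))) {
    ev <- ev_split[[paste(key$site_id[i], key$year[i])]]
    ct <- ct_split[[paste(key$population_id[i], key$year[i])]]
    cv <- fit_seasonal_curve(ct, ev, scheme = key$scheme[i],
                             population_id = key$population_id[i],
                             year = key$year[i], ...)
    pk <- tr <- NA_integer_; ratio <- NA_real_
    if (cv$fit_ok) {
      pk <- find_first_peak(cv)
      tt <- find_trough_and_ratio(cv, pk)
      tr <- tt$trough_day
      ratio <- tt$intergenerational_ratio
    }
    res[[i]] <- data.frame(
      population_id = key$population_id[i], species_id = key$species_id[i],
      site_id = key$site_id[i], year = key$year[i], scheme = key$scheme[i],
      fit_ok = cv$fit_ok, fail_reason = cv$fail_reason,
      first_peak_day = pk, trough_day = tr,
      intergenerational_ratio = ratio, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
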