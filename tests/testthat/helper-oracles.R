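# Independent oracles, deliberately written as plain loops over the daily
# series / record sets, never sharing code with the implementation.

# Construct a daily_curve object directly from a predicted series.
make_curve <- function(predicted, days = seq(91, length.out = length(predicted)),
                       jan1 = 0, plausibility_fraction = 0.05,
                       min_peak_height = 0.05, scheme = "transect") {
  structure(list(population_id = "toy", year = 2000L, scheme = scheme,
                 window = c(days[1], days[length(days)]), days = days,
                 predicted = predicted, jan1 = jan1, fit_ok = TRUE,
                 fail_reason = "none",
                 plausibility_fraction = plausibility_fraction,
                 min_peak_height = min_peak_height),
            class = "daily_curve")
}

# O(n) scan for qualifying interior peaks: strictly greater than both
# neighbours, height at least max(frac * max, floor).
oracle_peaks <- function(x, frac = 0.05, floor = 0.05) {
  thr <- max(frac * max(x), floor)
  out <- integer()
  for (i in 2:(length(x) - 1)) {
    if (x[i] > x[i - 1] && x[i] > x[i + 1] && x[i] >= thr) out <- c(out, i)
  }
  out
}

oracle_trough <- function(x, i1, i2) {
  best <- i1 + 1
  for (i in (i1 + 1):(i2 - 1)) if (x[i] < x[best]) best <- i
  best
}

oracle_ratio <- function(x, trough_idx) {
  before <- 0; after <- 0
  for (i in seq_along(x)) {
    if (i <= trough_idx) before <- before + x[i] else after <- after + x[i]
  }
  after / before
}

# Mean northing of the 10 most northerly hectads, ties at 10th included.
oracle_margin <- function(northings, n_margin = 10) {
  s <- sort(northings, decreasing = TRUE)
  if (length(s) <= n_margin) return(mean(s))
  kept <- s[1:n_margin]
  cutoff <- kept[n_margin]
  for (v in s[-(1:n_margin)]) if (v == cutoff) kept <- c(kept, v)
  mean(kept)
}

oracle_gdd5 <- function(doy, tmean) {
  total <- 0
  for (i in seq_along(doy)) {
    if (doy[i] >= 60 && doy[i] <= 151 && tmean[i] > 5)
      total <- total + (tmean[i] - 5)
  }
  total
}

# A smooth random daily series built from 1-3 Gaussian bumps.
random_curve <- function(days = 91:272) {
  nb <- sample(1:3, 1)
  means <- sort(runif(nb, days[1] + 10, days[length(days)] - 10))
  sds <- runif(nb, 5, 20)
  amps <- runif(nb, 0.5, 10)
  x <- numeric(length(days))
  for (b in seq_len(nb))
    x <- x + amps[b] * exp(-((days - means[b])^2) / (2 * sds[b]^2))
  x
}

# Small configuration used by tests that need the full generator quickly.
small_config <- function(...) {
  args <- list(n_species = 6L, n_sites = 4L, hectad_grid_side = 12L)
  user <- list(...)
  args[names(user)] <- user
  do.call(sim_config, args)
}
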