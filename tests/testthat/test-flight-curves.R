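weekly_events <- function(year = 2000L, doys = seq(91L, 272L, by = 7L)) {
  data.frame(site_id = "s", date = date_from_doy365(year, doys))
}

test_that("all-zero counts give a near-zero curve failing as no_peak", {
  ev <- weekly_events(doys = seq(91L, 272L, length.out = 20))
  ct <- data.frame(date = ev$date, count = 0L)
  cv <- fit_seasonal_curve(ct, ev, scheme = "transect")
  expect_false(cv$fit_ok)
  expect_identical(cv$fail_reason, "no_peak")
  expect_lt(max(cv$predicted), 0.05)
})

test_that("a unimodal Poisson-sampled curve is recovered near its true peak", {
  set.seed(42)
  ev <- weekly_events()
  mu <- 15 * exp(-(doy365(ev$date) - 180)^2 / (2 * 12^2))
  ct <- data.frame(date = ev$date, count = rpois(nrow(ev), mu))
  cv <- fit_seasonal_curve(ct, ev, scheme = "transect")
  expect_true(cv$fit_ok)
  expect_lt(abs(find_first_peak(cv) - 180), 7)
  # refitting identical input reproduces identical predictions
  cv2 <- fit_seasonal_curve(ct, ev, scheme = "transect")
  expect_identical(cv$predicted, cv2$predicted)
})

test_that("counts rising to the final event fail at the window boundary", {
  ev <- weekly_events()
  ct <- data.frame(date = ev$date, count = seq_len(nrow(ev)))
  cv <- fit_seasonal_curve(ct, ev, scheme = "transect")
  expect_false(cv$fit_ok)
  expect_identical(cv$fail_reason, "peak_on_boundary")
})

test_that("too few events are recorded as a fit error", {
  ev <- weekly_events(doys = seq(120L, 200L, by = 10L))  # 9 events < k + 1
  ct <- data.frame(date = ev$date, count = rpois(nrow(ev), 5))
  cv <- fit_seasonal_curve(ct, ev, scheme = "transect")
  expect_false(cv$fit_ok)
  expect_identical(cv$fail_reason, "fit_error")
})

test_that("screening applies the 1 January, no-peak and boundary rules", {
  days <- 91:272
  hump <- 5 * exp(-(days - 180)^2 / 200)
  expect_false(screen_curve(make_curve(hump, days, jan1 = 1.5))$pass)
  expect_identical(screen_curve(make_curve(hump, days, jan1 = 1.5))$reason,
                   "jan1_gt1")
  # flat curve: nothing exceeds both neighbours
  expect_identical(screen_curve(make_curve(rep(0.4, 182), days))$reason,
                   "no_peak")
  # maximum on the boundary
  expect_identical(screen_curve(make_curve(seq(0, 5, length.out = 182),
                                           days))$reason, "peak_on_boundary")
  scr <- screen_curve(make_curve(hump, days, jan1 = 0))
  expect_true(scr$pass)
  expect_identical(scr$reason, "none")
})

test_that("first-peak detection follows the plausibility and tie rules", {
  x <- c(0, 1, 3, 2, 1, rep(0.5, 20))
  cv <- make_curve(x, days = seq(91, length.out = length(x)))
  expect_equal(find_first_peak(cv), 93)

  # an early bump at 2% of the maximum is not a generation peak
  days <- 91:272
  bump <- 0.02 * 10 * exp(-(days - 110)^2 / 50) + 10 * exp(-(days - 200)^2 / 200)
  expect_equal(find_first_peak(make_curve(bump, days)),
               days[which.max(bump)])

  # equal-height twin peaks resolve to the earlier day
  twin <- exp(-(days - 140)^2 / 50) + exp(-(days - 220)^2 / 50)
  expect_equal(find_first_peak(make_curve(twin, days)), 140)
})

test_that("trough and intergenerational ratio match their oracles", {
  days <- 1:365
  # symmetric, well-separated equal broods: ratio exactly 1
  sym <- exp(-(days - 120)^2 / (2 * 64)) + exp(-(days - 240)^2 / (2 * 64))
  cv <- make_curve(sym, days, scheme = "trap")
  pk <- find_first_peak(cv)
  res <- find_trough_and_ratio(cv, pk)
  expect_equal(res$trough_day, 180)
  expect_lt(abs(res$intergenerational_ratio - 1), 1e-6)

  # second brood with twice the integrated area: ratio 2 on the daily grid
  dbl <- exp(-(days - 120)^2 / (2 * 100)) +
    2 * exp(-(days - 260)^2 / (2 * 100))
  cvd <- make_curve(dbl, days, scheme = "trap")
  resd <- find_trough_and_ratio(cvd, find_first_peak(cvd))
  expect_lt(abs(resd$intergenerational_ratio - 2), 0.02)

  # unimodal curve: no trough, no ratio
  uni <- exp(-(days - 180)^2 / (2 * 100))
  cvu <- make_curve(uni, days, scheme = "trap")
  resu <- find_trough_and_ratio(cvu, find_first_peak(cvu))
  expect_true(is.na(resu$trough_day))
  expect_true(is.na(resu$intergenerational_ratio))
})

test_that("peak and trough detection equals an exhaustive scan on random curves", {
  set.seed(101)
  days <- 91:272
  for (rep in 1:100) {
    x <- random_curve(days)
    pk_oracle <- oracle_peaks(x)
    cv <- make_curve(x, days)
    scr <- screen_curve(cv)
    if (length(pk_oracle) == 0) {
      expect_false(scr$pass)
      next
    }
    expect_equal(find_first_peak(cv), days[pk_oracle[1]])
    if (length(pk_oracle) >= 2) {
      res <- find_trough_and_ratio(cv, days[pk_oracle[1]])
      tr_oracle <- oracle_trough(x, pk_oracle[1], pk_oracle[2])
      expect_equal(res$trough_day, days[tr_oracle])
      expect_equal(res$intergenerational_ratio, oracle_ratio(x, tr_oracle))
    }
  }
})

test_that("recovered peak days track injected emergence days", {
  cfg <- small_config(seed = 21L)
  sim <- simulate_dataset(cfg)
  sp <- sim$truth$species_id[sim$truth$voltinism == "multivoltine"][1]
  counts <- sim$counts[sim$counts$species_id == sp, ]
  yr <- as.integer(format(counts$date, "%Y"))
  counts <- counts[yr >= 1995 & yr <= 2014, ]
  ev <- sim$events[as.integer(format(sim$events$date, "%Y")) %in% 1995:2014, ]
  cr <- fit_population_curves(counts, ev)
  ok <- cr[cr$fit_ok, ]
  tp <- sim$truth_population
  inj <- tp$emergence_day[match(paste(ok$population_id, ok$year),
                                paste(tp$population_id, tp$year))]
  expect_gt(cor(inj, ok$first_peak_day, method = "spearman"), 0.8)
})
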