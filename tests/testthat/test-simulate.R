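test_that("activity_rate is a sum of Gaussian brood terms", {
  uni <- list(voltinism = "univoltine")
  b1 <- data.frame(mean = 150, sd = 10, amplitude = 20)
  expect_equal(activity_rate(uni, b1, 150), 20.0)
  expect_lt(activity_rate(uni, b1, 350), 1e-12)

  multi <- list(voltinism = "multivoltine")
  b2 <- data.frame(mean = c(150, 230), sd = c(10, 10), amplitude = c(20, 40))
  # brute-force evaluation of each Gaussian term independently
  expected <- 20 * exp(-(190 - 150)^2 / 200) + 40 * exp(-(190 - 230)^2 / 200)
  expect_equal(activity_rate(multi, b2, 190), expected)

  expect_error(activity_rate(uni, data.frame(mean = 1, sd = 0, amplitude = 1),
                             1), "sd")
  expect_error(activity_rate(uni, b2, 150), "1 brood")
  expect_error(activity_rate(multi, b1, 150), "2 brood")
})

test_that("identical seed gives byte-identical simulated tables", {
  cfg <- small_config(n_species = 4L, seed = 7L)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  for (nm in names(a)) expect_identical(a[[nm]], b[[nm]])
  # different seed changes the counts
  c2 <- simulate_dataset(small_config(n_species = 4L, seed = 8L))
  expect_false(identical(a$counts$count, c2$counts$count))
})

test_that("without forcing, emergence day has no trend over years", {
  cfg <- small_config(warming_rate = 0, phenology_sensitivity = 0, seed = 3L)
  sim <- simulate_dataset(cfg)
  fit <- summary(lm(emergence_day ~ year, data = sim$truth_population))
  sl <- fit$coefficients["year", ]
  ci <- sl["Estimate"] + c(-2, 2) * sl["Std. Error"]
  expect_gt(ci[2], 0)
  expect_lt(ci[1], 0)
})

test_that("counts are Poisson draws around the brood-mixture rate", {
  cfg <- small_config(seed = 5L)
  sim <- simulate_dataset(cfg)
  counts <- sim$counts
  counts$year <- as.integer(format(counts$date, "%Y"))
  counts$doy <- doy365(counts$date)
  tp <- sim$truth_population
  tr <- sim$truth
  # reconstruct the expected rate for every count record of one species
  sp <- tr$species_id[tr$voltinism == "multivoltine"][1]
  d <- counts[counts$species_id == sp, ]
  i <- match(paste(d$site_id, sp, d$year), paste(tp$site_id, tp$species_id, tp$year))
  e1 <- tp$emergence_day[i]
  amp1 <- exp(tp$log_pop[i])
  j <- match(sp, tr$species_id)
  amp2 <- amp1 * cfg$brood2_rel *
    exp(tr$true_brood_coupling[j] * (tr$base_day[j] - e1))
  lambda <- amp1 * exp(-(d$doy - e1)^2 / (2 * cfg$brood_sd1^2)) +
    amp2 * exp(-(d$doy - e1 - cfg$brood_gap)^2 / (2 * cfg$brood_sd2^2))
  # total observed count is within 3 SD of the total expected count
  expect_lt(abs(sum(d$count) - sum(lambda)), 3 * sqrt(sum(lambda)))
  expect_true(all(d$count >= 0))
  expect_true(all(d$count == floor(d$count)))
})

test_that("GDD5 increases with the warming rate, seed held fixed", {
  base <- simulate_dataset(small_config(warming_rate = 0, seed = 2L))$gdd5
  warm <- simulate_dataset(small_config(warming_rate = 0.05, seed = 2L))$gdd5
  late <- base$year > 1980
  expect_true(all(warm$gdd5[late] > base$gdd5[late]))
  # and the across-year GDD5 slope becomes positive
  sl <- function(g) coef(lm(gdd5 ~ year, data = g))[2]
  expect_gt(sl(warm), sl(base))
})

test_that("univoltine curves rarely yield a trough", {
  cfg <- small_config(n_species = 8L, seed = 9L)
  sim <- simulate_dataset(cfg)
  uni <- sim$traits$species_id[sim$traits$voltinism == "univoltine"]
  counts <- sim$counts[sim$counts$species_id %in% uni, ]
  yr <- as.integer(format(counts$date, "%Y"))
  counts <- counts[yr >= 2000 & yr <= 2014, ]
  ev <- sim$events
  ev <- ev[as.integer(format(ev$date, "%Y")) %in% 2000:2014, ]
  cr <- fit_population_curves(counts, ev)
  ok <- cr[cr$fit_ok, ]
  expect_gt(nrow(ok), 100)
  expect_gte(mean(is.na(ok$trough_day)), 0.95)
})

test_that("null trend pairs are independent and reproducible", {
  a <- null_trend_pairs(1, 10000, seed = 4L)
  expect_lt(abs(cor(a$phenology_change, a$abundance_change)), 0.03)
  b <- null_trend_pairs(1, 10000, seed = 4L)
  expect_identical(a, b)
  expect_error(null_trend_pairs(1, 2), "at least 3")
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(frac_multivoltine = 1.2), "proportion")
  expect_error(sim_config(years = c(2000L, 2014L)), "span")
  expect_error(sim_config(sampling_interval_days = 0), "positive")
})
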