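test_that("likelihood-ratio test matches an independent chi-square evaluation", {
  set.seed(10)
  d <- data.frame(x = rnorm(60), g = rep(letters[1:3], 20))
  d$y <- 0.4 * d$x + rnorm(60)
  full <- lm(y ~ x, data = d)
  red <- lm(y ~ 1, data = d)
  res <- likelihood_ratio_test(full, red)
  chi_ind <- 2 * (as.numeric(logLik(full)) - as.numeric(logLik(red)))
  expect_equal(res$chi_sq, chi_ind)
  expect_equal(res$df, 1)
  expect_equal(res$p_value, pchisq(chi_ind, 1, lower.tail = FALSE))

  # contract violations
  expect_error(likelihood_ratio_test(red, full), "not nested")
  d2 <- d[1:50, ]
  expect_error(likelihood_ratio_test(full, lm(y ~ 1, data = d2)),
               "different data")
  mer <- lme4::lmer(y ~ x + (1 | g), data = d, REML = TRUE)
  mer0 <- lme4::lmer(y ~ 1 + (1 | g), data = d, REML = TRUE)
  expect_error(likelihood_ratio_test(mer, mer0), "REML")
})

test_that("marginal R2 matches the variance-component decomposition", {
  set.seed(20)
  d <- data.frame(x = rnorm(100), g = "a")
  d$y <- rnorm(100)
  expect_equal(marginal_r2(lm(y ~ 1, data = d)), 0)
  d$y2 <- 3 * d$x + rnorm(100, 0, 1e-4)
  expect_gt(marginal_r2(lm(y2 ~ x, data = d)), 0.99)

  # known components: slope 2, group sd 1, residual sd 1
  set.seed(21)
  n_g <- 40; n_per <- 50
  dd <- data.frame(g = rep(sprintf("g%02d", 1:n_g), each = n_per),
                   x = rnorm(n_g * n_per))
  geff <- rnorm(n_g, 0, 1)
  dd$y <- 2 * dd$x + geff[match(dd$g, sprintf("g%02d", 1:n_g))] +
    rnorm(nrow(dd))
  fit <- lme4::lmer(y ~ x + (1 | g), data = dd, REML = FALSE)
  plug_in <- var(2 * dd$x) / (var(2 * dd$x) + 1 + 1)
  expect_lt(abs(marginal_r2(fit) - plug_in), 0.02)
})

test_that("perfect dependence gives an overwhelming LRT", {
  set.seed(30)
  d <- data.frame(x = rnorm(60), taxon_group = rep(c("b", "m"), 30))
  d$y <- d$x
  res <- fit_interaction_model(d, "y", "x", covariates = character())
  expect_gt(res$overall$chi_sq, 100)
  expect_lt(res$overall$p_value, 1e-10)
  expect_gt(res$overall$marginal_r2, 0.99)
})

test_that("interaction LRT p-values are uniform under the null", {
  set.seed(40)
  ps <- replicate(200, {
    d <- simulate_species_trends(n_species = 80, slope_multivoltine = 0,
                                 slope_univoltine_specialist = 0,
                                 seed = sample.int(1e6, 1))
    fit_interaction_model(d, "abundance_change", "phenology_advance",
                          covariates = "voltinism")$overall$p_value
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the LRT statistic is invariant to affine rescaling of the response", {
  set.seed(50)
  d <- simulate_species_trends(n_species = 60, seed = 50)
  f1 <- fit_interaction_model(d, "abundance_change", "phenology_advance",
                              covariates = "voltinism")
  d$abundance_change <- 10 * d$abundance_change + 3
  f2 <- fit_interaction_model(d, "abundance_change", "phenology_advance",
                              covariates = "voltinism")
  expect_equal(f1$overall$chi_sq, f2$overall$chi_sq, tolerance = 1e-4)
})

test_that("predicted abundance trends are the fixed-effect arithmetic", {
  d <- expand.grid(phenology_advance = seq(-1, 1, by = 0.25),
                   voltinism = c("univoltine", "multivoltine"),
                   stringsAsFactors = FALSE)
  d$abundance_change <- ifelse(d$voltinism == "multivoltine",
                               0.02 * d$phenology_advance, 0)
  fit <- lm(abundance_change ~ voltinism + phenology_advance:voltinism,
            data = d)
  nd <- data.frame(phenology_advance = c(0.5, 0),
                   voltinism = c("multivoltine", "multivoltine"))
  pred <- predicted_abundance_trend(fit, nd)
  expect_equal(pred[1], 0.01, tolerance = 1e-10)
  expect_equal(pred[2], 0.00, tolerance = 1e-10)  # intercept of the cell
})

test_that("phenology-mediated margin effects are detected in most runs", {
  set.seed(60)
  hits <- 0L
  for (i in 1:100) {
    d <- simulate_species_trends(seed = sample.int(1e6, 1))
    first <- fit_interaction_model(d, "abundance_change", "phenology_advance",
                                   covariates = "voltinism")
    d$predicted_abundance <- predicted_abundance_trend(
      first$model, d[, c("phenology_advance", "voltinism", "taxon_group")])
    second <- fit_interaction_model(d, "margin_change", "predicted_abundance",
                                    covariates = character())
    if (second$overall$p_value < 0.05 && second$overall$effect_size > 0)
      hits <- hits + 1L
  }
  expect_gte(hits, 80L)
})

test_that("intraspecific model flags coupled species and recovers the slope", {
  set.seed(70)
  # one species with an exact positive coupling among nulls
  d <- null_trend_pairs(10, 20, seed = 70)
  d$voltinism <- "multivoltine"
  coupled <- d$species_id == "sp0001"
  d$abundance_change[coupled] <- 0.5 * d$phenology_change[coupled]
  names(d)[names(d) == "phenology_change"] <- "phenology_advance"
  res <- suppressWarnings(fit_intraspecific_model(d))
  ps <- res$per_species
  expect_true(ps$p_value[ps$species_id == "sp0001"] < 0.05)
  expect_gt(ps$slope[ps$species_id == "sp0001"], 0)

  # injected common slope recovered within 2 SE
  set.seed(71)
  n_sp <- 30; n_pop <- 20
  dd <- data.frame(
    species_id = rep(sprintf("s%02d", 1:n_sp), each = n_pop),
    voltinism = "multivoltine",
    phenology_advance = rnorm(n_sp * n_pop, 0.2, 0.5))
  sp_eff <- rnorm(n_sp, 0, 0.01)
  dd$abundance_change <- 0.01 * dd$phenology_advance +
    sp_eff[match(dd$species_id, sprintf("s%02d", 1:n_sp))] +
    rnorm(nrow(dd), 0, 0.02)
  res2 <- fit_intraspecific_model(dd)
  sub <- res2$subsets[res2$subsets$voltinism == "multivoltine", ]
  expect_lt(abs(sub$effect_size - 0.01), 2 * sub$se)
})

test_that("annual-response models recover the GDD5 effect and its null", {
  mk_annual <- function(b, seed) {
    set.seed(seed)
    n_sp <- 24; yrs <- 1995:2014; n_site <- 3
    d <- expand.grid(species_id = sprintf("s%02d", 1:n_sp), year = yrs,
                     site = 1:n_site, stringsAsFactors = FALSE)
    d$voltinism <- ifelse(as.integer(sub("s", "", d$species_id)) <= 8,
                          "multivoltine", "univoltine")
    yr_eff <- rnorm(length(yrs), 0, 20)
    d$gdd5 <- 320 + yr_eff[match(d$year, yrs)] + rnorm(nrow(d), 0, 60)
    sp_eff <- rnorm(n_sp, 0, 10)
    d$phenology_day <- 170 - b * (d$gdd5 - 320) +
      sp_eff[match(d$species_id, sprintf("s%02d", 1:n_sp))] +
      rnorm(nrow(d), 0, 4)
    d
  }
  d <- mk_annual(0.05, 81)
  res <- fit_annual_response(d, "phenology_day", "gdd5")
  for (i in seq_len(nrow(res$slopes))) {
    expect_lt(abs(res$slopes$slope[i] + 0.05), 2 * res$slopes$se[i])
    expect_lt(res$slopes$slope[i], 0)
  }
  d0 <- mk_annual(0, 82)
  res0 <- fit_annual_response(d0, "phenology_day", "gdd5")
  for (i in seq_len(nrow(res0$slopes))) {
    lo <- res0$slopes$slope[i] - 2 * res0$slopes$se[i]
    hi <- res0$slopes$slope[i] + 2 * res0$slopes$se[i]
    expect_true(lo < 0 && hi > 0)
  }
})

test_that("the log-ratio model is multivoltine-only with a negative peak effect", {
  set.seed(91)
  n_sp <- 12; yrs <- 1995:2014
  d <- expand.grid(species_id = sprintf("m%02d", 1:n_sp), year = yrs,
                   stringsAsFactors = FALSE)
  d$voltinism <- "multivoltine"
  d$phenology_day <- rnorm(nrow(d), 150, 8)
  d$intergenerational_ratio <- exp(-0.04 * (d$phenology_day - 150) +
                                     rnorm(nrow(d), 0, 0.2))
  res <- fit_annual_response(d, "intergenerational_ratio", "phenology_day",
                             covariate = NULL, log_dep = TRUE)
  expect_lt(res$slopes$slope, 0)
  expect_lt(abs(res$slopes$slope + 0.04), 2 * res$slopes$se)

  d$voltinism[1] <- "univoltine"
  expect_error(fit_annual_response(d, "intergenerational_ratio",
                                   "phenology_day", covariate = NULL,
                                   log_dep = TRUE), "univoltine")
})
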