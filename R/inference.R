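# Statistical analysis layer: Gaussian mixed models with interaction terms,
# likelihood-ratio tests (models compared by maximum likelihood), marginal
# R-squared, subset splits by voltinism and habitat class, model-predicted
# abundance trends, intraspecific population-level models, and
# annual-response models with crossed species and year random effects.

.is_mer <- function(m) inherits(m, "merMod")

.loglik_df <- function(m) {
  ll <- logLik(m)
  c(ll = as.numeric(ll), df = attr(ll, "df"), n = attr(ll, "nobs") %||% nobs(m))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Likelihood-ratio test of two nested fitted models
#'
#' Both models must be fitted by maximum likelihood on identical data, with
#' the reduced model nested in the full one. The statistic is twice the
#' log-likelihood difference, referred to a chi-squared distribution on the
#' parameter-count difference (one for every comparison in this pipeline).
#'
#' @param full,reduced fitted `lm` or `merMod` models.
#' @return list with `chi_sq`, `df` and `p_value`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  a <- .loglik_df(full)
  b <- .loglik_df(reduced)
  if (a[["n"]] != b[["n"]])
    stop("models fitted to different data (n = ", a[["n"]], " vs ", b[["n"]], ")")
  if (a[["df"]] <= b[["df"]])
    stop("reduced model is not nested in full (df ", b[["df"]], " >= ", a[["df"]], ")")
  if (.is_mer(full) && lme4::isREML(full))
    stop("models compared by LRT must be fitted by maximum likelihood, not REML")
  chi <- max(0, 2 * (a[["ll"]] - b[["ll"]]))
  df <- a[["df"]] - b[["df"]]
  list(chi_sq = chi, df = df, p_value = pchisq(chi, df, lower.tail = FALSE))
}

#' Marginal R-squared of a Gaussian (mixed) model
#'
#' Variance of the fixed-effect predictions over the sum of fixed-effect,
#' random-effect and residual variances (the standard mixed-model
#' decomposition); for an ordinary linear model this is the usual R-squared.
#'
#' @param model fitted `lm` or Gaussian `merMod`.
#' @return proportion in \[0, 1\].
#' @export
marginal_r2 <- function(model) {
  if (.is_mer(model)) {
    fixed <- as.numeric(model.matrix(model) %*% lme4::fixef(model))
    v_f <- var(fixed)
    vc <- lme4::VarCorr(model)
    v_r <- sum(vapply(vc, function(m) sum(diag(m)), numeric(1)))
    v_e <- sigma(model)^2
    return(unname(v_f / (v_f + v_r + v_e)))
  }
  f <- as.numeric(fitted(model))
  v_f <- var(f)
  unname(v_f / (v_f + sigma(model)^2))
}

# Fit dep ~ indep (+ random intercept) by ML and test the indep slope by
# LRT; falls back to ordinary regression when the mixed fit is unavailable.
.effect_test <- function(data, dep, indep, random = NULL) {
  use_mer <- !is.null(random) && length(unique(data[[random]])) > 1
  if (use_mer) {
    full <- tryCatch(suppressMessages(suppressWarnings(
      lme4::lmer(as.formula(sprintf("%s ~ %s + (1 | %s)", dep, indep, random)),
                 data = data, REML = FALSE))), error = function(e) NULL)
    red <- tryCatch(suppressMessages(suppressWarnings(
      lme4::lmer(as.formula(sprintf("%s ~ 1 + (1 | %s)", dep, random)),
                 data = data, REML = FALSE))), error = function(e) NULL)
    if (is.null(full) || is.null(red)) use_mer <- FALSE
    if (use_mer) {
      co_try <- tryCatch(
        suppressWarnings(summary(full)$coefficients),
        error = function(e) NULL)
      if (is.null(co_try) ||
          !all(is.finite(co_try[indep, c("Estimate", "Std. Error")])))
        use_mer <- FALSE
    }
  }
  if (!use_mer) {
    full <- lm(as.formula(sprintf("%s ~ %s", dep, indep)), data = data)
    red <- lm(as.formula(sprintf("%s ~ 1", dep)), data = data)
  }
  lrt <- likelihood_ratio_test(full, red)
  co <- suppressWarnings(summary(full)$coefficients)
  list(model = full, n = nrow(data),
       effect_size = unname(co[indep, "Estimate"]),
       se = unname(co[indep, "Std. Error"]),
       chi_sq = lrt$chi_sq, p_value = lrt$p_value,
       aic = AIC(full), marginal_r2 = marginal_r2(full))
}

.fit_ml <- function(formula, data) {
  suppressMessages(suppressWarnings(
    lme4::lmer(formula, data = data, REML = FALSE)))
}

#' Interspecific interaction model between two species-level trends
#'
#' Gaussian mixed model of one species-level trend on another with a random
#' taxon-group intercept, testing by LRT the highest-order interaction with
#' voltinism (and, optionally, habitat specialisation class). Non-significant
#' interactions are simplified stepwise (three-way, then two-way, then main
#' effect), a term being retained iff its LRT is significant at `alpha` or
#' it improves AIC. If the retained model has an interaction, the data are
#' split and the focal slope is tested separately in each voltinism (x
#' class) cell; cells with fewer than `min_cell_n` species are reported but
#' not tested.
#'
#' @param data species-level trend table with the dependent and independent
#'   columns plus `voltinism`, `habitat_class`, `taxon_group`.
#' @param dep,indep column names of the dependent and independent trends.
#' @param covariates `character()` for a plain slope model, `"voltinism"`,
#'   or `c("voltinism", "habitat_class")`.
#' @param random grouping column for the random intercept.
#' @param alpha significance level used in model simplification.
#' @param min_cell_n smallest subset cell that is tested (default 4).
#' @return list with `overall` (n, AIC, marginal R2, effect size and s.e.
#'   where a single slope exists, chi-squared and P for the focal term, and
#'   the formula), `subsets` (one row per tested cell) and `model`.
#' @export
fit_interaction_model <- function(data, dep, indep,
                                  covariates = c("voltinism", "habitat_class"),
                                  random = "taxon_group",
                                  alpha = 0.05, min_cell_n = 4L) {
  covariates <- intersect(covariates, c("voltinism", "habitat_class"))
  for (v in covariates)
    if (length(unique(data[[v]])) < 2)
      stop("covariate ", v, " needs at least 2 levels")
  re <- sprintf("(1 | %s)", random)

  if (length(covariates) == 0) {
    res <- .effect_test(data, dep, indep, random)
    overall <- data.frame(n = res$n, aic = res$aic, marginal_r2 = res$marginal_r2,
                          effect_size = res$effect_size, se = res$se,
                          chi_sq = res$chi_sq, p_value = res$p_value,
                          formula = sprintf("%s ~ %s", dep, indep),
                          stringsAsFactors = FALSE)
    return(list(overall = overall, subsets = NULL, model = res$model))
  }

  # Candidate fixed structures, highest-order interaction first.
  fx <- paste(c(indep, covariates), collapse = " * ")
  terms_order <- if (length(covariates) == 2) {
    three <- sprintf("%s:%s:%s", indep, covariates[1], covariates[2])
    two <- sprintf("%s:%s", indep, covariates)
    list(full = sprintf("%s * %s * %s", indep, covariates[1], covariates[2]),
         drops = c(three, two))
  } else {
    list(full = sprintf("%s * %s", indep, covariates[1]),
         drops = sprintf("%s:%s", indep, covariates[1]))
  }
  make <- function(rhs) as.formula(sprintf("%s ~ %s + %s", dep, rhs, re))
  current <- .fit_ml(make(terms_order$full), data)
  focal_lrt <- NULL
  focal_term <- NULL
  for (term in terms_order$drops) {
    reduced <- tryCatch(suppressMessages(suppressWarnings(
      update(current, as.formula(sprintf(". ~ . - %s", term))))),
      error = function(e) NULL)
    if (is.null(reduced)) next
    # A term unsupported by the data (rank-deficient cell) leaves the
    # likelihood unchanged; treat it as not retainable.
    lrt <- tryCatch(likelihood_ratio_test(current, reduced),
                    error = function(e) NULL)
    if (is.null(lrt)) { current <- reduced; next }
    if (is.null(focal_lrt)) { focal_lrt <- lrt; focal_term <- term }
    keep <- lrt$p_value < alpha || AIC(current) < AIC(reduced)
    if (keep) break
    current <- reduced
  }
  if (is.null(focal_lrt)) focal_lrt <- list(chi_sq = NA_real_, p_value = NA_real_)

  overall <- data.frame(n = nrow(data), aic = AIC(current),
                        marginal_r2 = marginal_r2(current),
                        effect_size = NA_real_, se = NA_real_,
                        chi_sq = focal_lrt$chi_sq, p_value = focal_lrt$p_value,
                        formula = paste(deparse(formula(current)), collapse = ""),
                        stringsAsFactors = FALSE)

  cells <- if (length(covariates) == 2)
    expand.grid(voltinism = sort(unique(data$voltinism)),
                habitat_class = sort(unique(data$habitat_class)),
                stringsAsFactors = FALSE)
  else data.frame(voltinism = sort(unique(data$voltinism)),
                  stringsAsFactors = FALSE)
  subs <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- rep(TRUE, nrow(data))
    for (v in names(cells)) sel <- sel & data[[v]] == cells[i, v]
    d <- data[sel, ]
    base <- cbind(cells[i, , drop = FALSE],
                  data.frame(n = nrow(d), effect_size = NA_real_, se = NA_real_,
                             chi_sq = NA_real_, p_value = NA_real_,
                             tested = FALSE, stringsAsFactors = FALSE))
    if (nrow(d) < min_cell_n) return(base)
    res <- .effect_test(d, dep, indep, random)
    base$effect_size <- res$effect_size
    base$se <- res$se
    base$chi_sq <- res$chi_sq
    base$p_value <- res$p_value
    base$tested <- TRUE
    base
  })
  subsets <- do.call(rbind, subs)
  rownames(subsets) <- NULL
  list(overall = overall, subsets = subsets, model = current,
       focal_term = focal_term)
}

#' Fixed-effects prediction of abundance trend for given species
#'
#' Evaluates the fixed-effects linear predictor of a fitted
#' phenology-to-abundance model at each species' observed phenology change
#' and covariates, yielding the component of abundance change attributable
#' to phenology; used as the independent variable of second-stage
#' distribution/margin models.
#'
#' @param model fitted model from [fit_interaction_model()].
#' @param newdata species rows with the model's covariate columns.
#' @return numeric vector of predicted abundance trends.
#' @export
predicted_abundance_trend <- function(model, newdata) {
  if (.is_mer(model)) {
    for (v in names(newdata)) {
      xl <- tryCatch(levels(model.frame(model)[[v]]), error = function(e) NULL)
      if (!is.null(xl) && is.character(newdata[[v]]) &&
          !all(newdata[[v]] %in% xl))
        stop("unseen level in covariate ", v)
    }
    as.numeric(predict(model, newdata = newdata, re.form = NA))
  } else {
    as.numeric(predict(model, newdata = newdata))
  }
}

#' Intraspecific phenology-abundance model at population level
#'
#' Fits, per voltinism subset, a mixed model of population-level abundance
#' change on phenology change with a random species intercept, and
#' independently an ordinary regression per species (two-tailed slope test
#' at `alpha`), returning the counts of species with significant positive
#' and negative slopes.
#'
#' @param pop_trends population-level trend table with `species_id`,
#'   `voltinism`, `phenology_advance`, `abundance_change`.
#' @param alpha significance level (default 0.05).
#' @param min_populations minimum populations for a per-species test.
#' @return list with `subsets` (one row per voltinism level: n populations,
#'   effect, s.e., chi-squared, P, AIC, marginal R2), `per_species` (slope,
#'   s.e., P per species) and `counts` (significant positive/negative
#'   species per voltinism level, with fractions).
#' @export
fit_intraspecific_model <- function(pop_trends, alpha = 0.05,
                                    min_populations = 3L) {
  keep <- stats::complete.cases(pop_trends[, c("phenology_advance",
                                               "abundance_change")])
  d <- pop_trends[keep, ]
  levs <- sort(unique(d$voltinism))
  subsets <- do.call(rbind, lapply(levs, function(v) {
    dv <- d[d$voltinism == v, ]
    res <- .effect_test(dv, "abundance_change", "phenology_advance",
                        "species_id")
    data.frame(voltinism = v, n = res$n, aic = res$aic,
               marginal_r2 = res$marginal_r2, effect_size = res$effect_size,
               se = res$se, chi_sq = res$chi_sq, p_value = res$p_value,
               stringsAsFactors = FALSE)
  }))
  per_species <- do.call(rbind, lapply(split(d, d$species_id), function(ds) {
    out <- data.frame(species_id = ds$species_id[1],
                      voltinism = ds$voltinism[1],
                      n_populations = nrow(ds), slope = NA_real_,
                      se = NA_real_, p_value = NA_real_,
                      stringsAsFactors = FALSE)
    if (nrow(ds) < min_populations || sd(ds$phenology_advance) == 0)
      return(out)
    co <- summary(lm(abundance_change ~ phenology_advance,
                     data = ds))$coefficients
    if (nrow(co) < 2) return(out)
    out$slope <- co[2, "Estimate"]
    out$se <- co[2, "Std. Error"]
    out$p_value <- co[2, "Pr(>|t|)"]
    out
  }))
  rownames(per_species) <- NULL
  counts <- do.call(rbind, lapply(levs, function(v) {
    ps <- per_species[per_species$voltinism == v & !is.na(per_species$p_value), ]
    sig_pos <- sum(ps$p_value < alpha & ps$slope > 0)
    sig_neg <- sum(ps$p_value < alpha & ps$slope < 0)
    data.frame(voltinism = v, n_species = nrow(ps), sig_positive = sig_pos,
               sig_negative = sig_neg,
               frac_positive = if (nrow(ps) > 0) sig_pos / nrow(ps) else NA_real_,
               frac_negative = if (nrow(ps) > 0) sig_neg / nrow(ps) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(subsets = subsets, per_species = per_species, counts = counts)
}

#' Annual-response mixed model with crossed species and year effects
#'
#' Gaussian mixed model of an annual population-level response on an annual
#' predictor with crossed random intercepts for species and year, testing
#' the predictor-by-voltinism interaction (or, without a covariate, the
#' predictor itself) by LRT. Per-voltinism slopes come from the equivalent
#' nested parameterisation. Intergenerational-ratio responses are defined
#' for multivoltine species only, so passing univoltine rows with
#' `dep = "intergenerational_ratio"` is an error.
#'
#' @param data annual population-level table with the dependent and
#'   independent columns plus `species_id`, `year`, `voltinism`.
#' @param dep,indep column names.
#' @param covariate `"voltinism"` or `NULL`.
#' @param log_dep take the natural log of the dependent variable (used for
#'   abundance and ratio responses).
#' @return list with `overall` (n, AIC, marginal R2, chi-squared, P for the
#'   focal term), `slopes` (per voltinism level, or a single slope),
#'   and `model`.
#' @export
fit_annual_response <- function(data, dep, indep, covariate = "voltinism",
                                log_dep = FALSE) {
  if (dep == "intergenerational_ratio" &&
      any(data$voltinism == "univoltine", na.rm = TRUE))
    stop("intergenerational ratio is undefined for univoltine species")
  d <- data[stats::complete.cases(data[, c(dep, indep)]), ]
  d$.y <- if (log_dep) log(d[[dep]]) else d[[dep]]
  d$.x <- d[[indep]]
  d$year_f <- factor(d$year)
  re <- "(1 | species_id) + (1 | year_f)"
  if (!is.null(covariate) && length(unique(d[[covariate]])) > 1) {
    full <- .fit_ml(as.formula(sprintf(".y ~ .x * %s + %s", covariate, re)), d)
    red <- .fit_ml(as.formula(sprintf(".y ~ .x + %s + %s", covariate, re)), d)
    lrt <- likelihood_ratio_test(full, red)
    nested <- .fit_ml(as.formula(sprintf(".y ~ %s + .x:%s + %s",
                                         covariate, covariate, re)), d)
    co <- summary(nested)$coefficients
    sl <- co[grepl("\\.x", rownames(co)), , drop = FALSE]
    lev <- gsub("\\.x|:", "", rownames(sl))
    lev <- sub(sprintf("^%s", covariate), "", lev)
    slopes <- data.frame(level = lev, slope = sl[, "Estimate"],
                         se = sl[, "Std. Error"], stringsAsFactors = FALSE)
    model <- full
  } else {
    full <- .fit_ml(as.formula(sprintf(".y ~ .x + %s", re)), d)
    red <- .fit_ml(as.formula(sprintf(".y ~ 1 + %s", re)), d)
    lrt <- likelihood_ratio_test(full, red)
    co <- summary(full)$coefficients
    slopes <- data.frame(level = "all", slope = co[".x", "Estimate"],
                         se = co[".x", "Std. Error"], stringsAsFactors = FALSE)
    model <- full
  }
  rownames(slopes) <- NULL
  list(overall = data.frame(n = nrow(d), aic = AIC(model),
                            marginal_r2 = marginal_r2(model),
                            chi_sq = lrt$chi_sq, p_value = lrt$p_value,
                            stringsAsFactors = FALSE),
       slopes = slopes, model = model)
}
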