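# build a study-table-like data.frame directly for the modelling layer
make_table <- function(n_regions = 8, per_region = 20, slope = 0,
                       ranef_sd = 0.3, resid_sd = 1, seed = 1,
                       response = "resistance") {
  set.seed(seed)
  n <- n_regions * per_region
  region <- rep(sprintf("R%02d", seq_len(n_regions)), each = per_region)
  x <- rnorm(n)
  u <- rep(rnorm(n_regions, 0, ranef_sd), each = per_region)
  y <- slope * x + u + rnorm(n, 0, resid_sd)
  df <- data.frame(region = region, log_frequency = x,
                   frequency = exp(x), pace = runif(n),
                   category = sample(c("environmental", "cultural",
                                       "mixed", "unclear"), n, TRUE),
                   dist_type = sample(c("aridity", "mobility", "cooling"),
                                      n, TRUE),
                   land_use = sample(c("hunter-gatherer", "agriculture"),
                                     n, TRUE),
                   change = sample(c(TRUE, FALSE), n, TRUE),
                   duration = exp(rnorm(n, 4.5, 1)),
                   resilience_defined = TRUE)
  df$time_to_min <- df$duration * df$pace
  df[[response]] <- y
  if (!"resistance" %in% names(df)) df$resistance <- rnorm(n)
  if (!"resilience" %in% names(df)) df$resilience <- rnorm(n)
  df
}

test_that("skewness is the adjusted Fisher-Pearson coefficient", {
  set.seed(3)
  expect_lt(abs(skewness(rnorm(1000))), 0.15)
  # closed-form check on a tiny fixture
  x <- c(1, 2, 4)
  n <- 3; m <- mean(x)
  g1 <- mean((x - m)^3) / mean((x - m)^2)^1.5
  expect_equal(skewness(x), g1 * sqrt(n * (n - 1)) / (n - 2))
  # exponential samples are strongly right-skewed
  expect_gt(skewness(rexp(2000)), 1.5)
})

test_that("eta squared equals SS_between / SS_total on closed-form fixtures", {
  df <- data.frame(g = rep(c("a", "b"), each = 4),
                   y = c(0, 0, 0, 0, 1, 1, 1, 1))
  expect_equal(unname(eta_squared(aov(y ~ g, df))), 1)
  df2 <- data.frame(g = rep(c("a", "b"), each = 2), y = c(0, 2, 1, 3))
  # SS_between = 2 * (1-1.5)^2 + 2 * (2-1.5)^2 = 1; SS_total = 5
  expect_equal(unname(eta_squared(aov(y ~ g, df2))), 1 / 5)
})

test_that("one-way ANOVA F agrees with a permutation oracle under the null", {
  set.seed(11)
  tab <- make_table(n_regions = 4, per_region = 50, slope = 0,
                    ranef_sd = 0, seed = 11)
  f_obs <- summary(aov(resistance ~ category, tab))[[1]][["F value"]][1]
  perm <- replicate(400, {
    tab$category <- sample(tab$category)
    summary(aov(resistance ~ category, tab))[[1]][["F value"]][1]
  })
  p_perm <- mean(perm >= f_obs)
  p_aov <- summary(aov(resistance ~ category, tab))[[1]][["Pr(>F)"]][1]
  expect_lt(abs(p_perm - p_aov), 0.1)
})

test_that("describe reports medians, classes, skew and ANOVAs", {
  tab <- make_table(seed = 21)
  rep <- describe(tab)
  expect_equal(rep$n, nrow(tab))
  expect_equal(rep$medians$overall[["resistance"]],
               median(tab$resistance))
  expect_equal(sum(rep$duration_classes$proportions), 1)
  expect_equal(rep$anova$resistance$df, 3)  # four categories
  expect_true(rep$anova$resistance$eta_sq >= 0 &&
                rep$anova$resistance$eta_sq <= 1)
  expect_s3_class(rep$shapiro_pace, "htest")
  expect_error(describe(tab[1:2, ]), "at least 3")
})

test_that("fit_mixed recovers a known standardized slope", {
  tab <- make_table(n_regions = 8, per_region = 100, slope = 0.4,
                    ranef_sd = 0.3, resid_sd = 1, seed = 31)
  fit <- fit_mixed(tab, "resistance", "log_frequency")
  expect_true(fit$converged)
  # predictor is z-scored in generation; raw slope targets 0.4
  expect_equal(unname(fit$coefficients["log_frequency", "Estimate"]), 0.4,
               tolerance = 0.25)
  expect_lt(abs(fit$coefficients["log_frequency", "Estimate"] - 0.4), 0.1)
  expect_gt(fit$ranef_var, 0)
})

test_that("single-region fits degenerate to ordinary least squares", {
  tab <- make_table(n_regions = 1, per_region = 60, slope = 0.5, seed = 41,
                    ranef_sd = 0)
  fit <- fit_mixed(tab, "resistance", "log_frequency")
  ls <- coef(lm(resistance ~ log_frequency, tab))
  expect_equal(unname(fit$coefficients[, "Estimate"]), unname(ls),
               tolerance = 1e-6)
  expect_true(fit$singular)
})

test_that("standardized coefficients equal Pearson r on noiseless data", {
  set.seed(51)
  x <- rnorm(80)
  tab <- data.frame(region = "A", log_frequency = x,
                    resistance = 2 + 3 * x)
  # noiseless by construction; lm warns about the perfect fit
  fit <- suppressWarnings(fit_mixed(tab, "resistance", "log_frequency"))
  expect_equal(unname(fit$std_coefficients["log_frequency", "Estimate"]),
               cor(x, tab$resistance), tolerance = 1e-6)
})

test_that("REML and ML agree in the zero-random-variance limit", {
  tab <- make_table(n_regions = 1, per_region = 50, slope = 0.3, seed = 61)
  f_reml <- fit_mixed(tab, "resistance", "log_frequency", reml = TRUE)
  f_ml <- fit_mixed(tab, "resistance", "log_frequency", reml = FALSE)
  expect_equal(unname(f_reml$coefficients[, "Estimate"]),
               unname(f_ml$coefficients[, "Estimate"]), tolerance = 1e-4)
})

test_that("stepwise selection keeps the predictive term and is deterministic", {
  tab <- make_table(n_regions = 8, per_region = 30, slope = 0.6,
                    ranef_sd = 0.2, resid_sd = 0.5, seed = 71)
  sel1 <- stepwise_ic(tab, "resistance")
  sel2 <- stepwise_ic(tab, "resistance")
  expect_true("log_frequency" %in% sel1$fixed)
  expect_identical(sel1$fixed, sel2$fixed)
  expect_identical(sel1$selection_path, sel2$selection_path)
  # criterion decreases monotonically along the path
  expect_true(all(diff(sel1$selection_path$aic) < 0))
})

test_that("all-noise candidates are mostly rejected by selection", {
  hits <- vapply(1:12, function(s) {
    tab <- make_table(n_regions = 6, per_region = 15, slope = 0,
                      seed = 100 + s)
    length(stepwise_ic(tab, "resistance")$fixed)
  }, numeric(1))
  expect_gt(mean(hits == 0), 0.5)
})

test_that("fit_frequency_model uses hunter-gatherer as reference and finds a constructed contrast", {
  tab <- make_table(n_regions = 10, per_region = 20, seed = 81)
  # agriculture rows get twice the frequency: +log(2) on the log scale
  tab$log_frequency <- rnorm(nrow(tab), 0, 0.1) +
    ifelse(tab$land_use == "agriculture", log(2), 0)
  fit <- fit_frequency_model(tab)
  expect_true(fit$converged)
  co <- fit$coefficients
  row <- grep("agriculture", rownames(co), value = TRUE)
  expect_equal(unname(co[row, "Estimate"]), log(2), tolerance = 0.1)
  expect_gt(unname(co[row, "t value"]), 2)

  # reference coding: on balanced noiseless data the intercept equals the
  # hunter-gatherer mean
  tab2 <- tab[, c("region", "land_use", "pace", "change", "dist_type")]
  tab2$log_frequency <- ifelse(tab2$land_use == "agriculture", 1, 0.25)
  # a noiseless two-level contrast; lme4 flags the degenerate fit
  fit2 <- suppressWarnings(fit_frequency_model(tab2, fixed = "land_use"))
  expect_equal(unname(fit2$coefficients["(Intercept)", "Estimate"]), 0.25,
               tolerance = 1e-6)

  # rare land-use levels are merged with a warning
  tab3 <- tab
  tab3$land_use[1] <- "marine foraging"
  expect_warning(fit_frequency_model(tab3), "merged")
})

test_that("permuted labels show null type-I behaviour", {
  hits <- vapply(1:20, function(s) {
    tab <- make_table(n_regions = 8, per_region = 20, slope = 0,
                      seed = 200 + s)
    fit <- fit_frequency_model(tab, fixed = c("land_use", "pace"))
    co <- fit$coefficients
    row <- grep("agriculture", rownames(co), value = TRUE)
    abs(co[row, "t value"]) < 2
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
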