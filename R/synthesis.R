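#' Adjusted Fisher-Pearson skewness
#'
#' Sample skewness with the small-sample bias correction,
#' `g1 * sqrt(n(n-1)) / (n-2)`.
#'
#' @param x Numeric vector (n >= 3).
#' @return Skewness coefficient.
#' @export
skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) stop("skewness needs at least 3 observations", call. = FALSE)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  g1 <- mean((x - m)^3) / s2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Eta-squared from a fitted aov model
#'
#' Proportion of total variance explained by each model term,
#' `SS_term / SS_total`.
#'
#' @param fit An `aov` fit.
#' @return Named numeric vector of eta-squared values per term.
#' @export
eta_squared <- function(fit) {
  ss <- summary(fit)[[1]][["Sum Sq"]]
  terms <- trimws(rownames(summary(fit)[[1]]))
  out <- ss / sum(ss)
  names(out) <- terms
  out[terms != "Residuals"]
}

#' Descriptive statistics of a downturn study table
#'
#' Computes the descriptive layer of the cross-regional synthesis: medians
#' of resistance, resilience and frequency (overall and by disturbance
#' category, region and disturbance type), counts and proportions of
#' downturn durations in decadal/centennial/millennial classes, adjusted
#' Fisher-Pearson skewness of duration and time-to-minimum, a Shapiro-Wilk
#' normality test on pace, and one-way ANOVAs of resistance and resilience
#' across disturbance categories with eta-squared effect sizes.
#'
#' @param table A `study_table` from [assemble_table()] (>= 3 rows).
#' @return A list of class `descriptive_report`.
#' @export
describe <- function(table) {
  if (nrow(table) < 3L)
    stop("descriptive statistics need at least 3 downturns", call. = FALSE)
  med_by <- function(v, g) {
    vapply(split(table[[v]], table[[g]]),
           stats::median, numeric(1), na.rm = TRUE)
  }
  dur_class <- cut(table$duration, breaks = c(-Inf, 50, 100, 500, Inf),
                   labels = c("<=50", "50-100", "100-500", ">500"))
  counts <- table(dur_class)
  aov_res <- stats::aov(resistance ~ category, data = table)
  aov_resil <- stats::aov(resilience ~ category,
                          data = table[table$resilience_defined, ])
  sum_res <- summary(aov_res)[[1]]
  sum_resil <- summary(aov_resil)[[1]]
  structure(list(
    n = nrow(table),
    medians = list(
      overall = vapply(c("resistance", "resilience", "frequency", "pace",
                         "duration"),
                       function(v) stats::median(table[[v]], na.rm = TRUE),
                       numeric(1)),
      resistance_by_category = med_by("resistance", "category"),
      resilience_by_category = med_by("resilience", "category"),
      frequency_by_dist_type = med_by("frequency", "dist_type"),
      frequency_by_region = med_by("frequency", "region")
    ),
    duration_classes = list(counts = counts,
                            proportions = counts / sum(counts)),
    skewness = c(duration = skewness(table$duration),
                 time_to_min = skewness(table$time_to_min)),
    shapiro_pace = stats::shapiro.test(table$pace),
    anova = list(
      resistance = list(F = sum_res[["F value"]][1],
                        p = sum_res[["Pr(>F)"]][1],
                        df = sum_res[["Df"]][1],
                        eta_sq = unname(eta_squared(aov_res)[1])),
      resilience = list(F = sum_resil[["F value"]][1],
                        p = sum_resil[["Pr(>F)"]][1],
                        df = sum_resil[["Df"]][1],
                        eta_sq = unname(eta_squared(aov_resil)[1]))
    )
  ), class = "descriptive_report")
}

#' @export
print.descriptive_report <- function(x, ...) {
  cat("Downturn study: n =", x$n, "\n")
  cat("Median resistance ",
      signif(x$medians$overall[["resistance"]], 3),
      ", resilience ", signif(x$medians$overall[["resilience"]], 3),
      ", duration ", x$medians$overall[["duration"]], " years\n", sep = "")
  cat("Skewness: duration ", signif(x$skewness[["duration"]], 3),
      ", time to minimum ", signif(x$skewness[["time_to_min"]], 3), "\n",
      sep = "")
  cat("ANOVA across categories: resistance F =",
      signif(x$anova$resistance$F, 3), "(d.f. =", x$anova$resistance$df,
      "); resilience F =", signif(x$anova$resilience$F, 3), "\n")
  invisible(x)
}

# z-score helper that leaves factors/logicals untouched
standardize_cols <- function(df, cols) {
  for (cl in cols) {
    v <- df[[cl]]
    if (is.numeric(v) && stats::sd(v, na.rm = TRUE) > 0)
      df[[cl]] <- (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
  }
  df
}

fit_one_mixed <- function(table, response, fixed, reml = TRUE,
                          standardized = TRUE) {
  keep <- stats::complete.cases(table[, c(response, fixed, "region"),
                                      drop = FALSE])
  dat <- as.data.frame(table[keep, , drop = FALSE])
  rhs <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
  form <- stats::as.formula(paste(response, "~", rhs, "+ (1 | region)"))
  single_region <- length(unique(dat$region)) < 2L
  std_dat <- if (standardized)
    standardize_cols(dat, c(response, fixed)) else dat
  if (single_region) {
    lm_form <- stats::as.formula(paste(response, "~", rhs))
    fit <- stats::lm(lm_form, data = dat)
    co <- summary(fit)$coefficients
    std_fit <- stats::lm(lm_form, data = std_dat)
    res <- list(fit = fit, coefficients = co,
                std_coefficients = summary(std_fit)$coefficients,
                ranef_var = 0, resid_var = summary(fit)$sigma^2,
                aic = stats::AIC(fit), converged = TRUE,
                singular = TRUE, n = nrow(dat))
  } else {
    fit <- tryCatch(
      suppressMessages(lmerTest::lmer(form, data = dat, REML = reml)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      res <- list(fit = NULL, coefficients = NULL, std_coefficients = NULL,
                  ranef_var = NA_real_, resid_var = NA_real_,
                  aic = NA_real_, converged = FALSE, singular = NA,
                  n = nrow(dat), message = conditionMessage(fit))
    } else {
      co <- stats::coef(summary(fit))
      std_fit <- suppressWarnings(suppressMessages(
        lmerTest::lmer(form, data = std_dat, REML = reml)))
      vc <- as.data.frame(lme4::VarCorr(fit))
      res <- list(
        fit = fit, coefficients = co,
        std_coefficients = stats::coef(summary(std_fit)),
        ranef_var = vc$vcov[vc$grp == "region"],
        resid_var = vc$vcov[vc$grp == "Residual"],
        aic = suppressWarnings(stats::AIC(lme4::refitML(fit))),
        converged = length(fit@optinfo$conv$lme4$messages) == 0L,
        singular = lme4::isSingular(fit), n = nrow(dat))
    }
  }
  res$response <- response
  res$fixed <- fixed
  res$reml <- reml
  class(res) <- "mixed_model_result"
  res
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat("Mixed model: ", x$response, " ~ ",
      if (length(x$fixed)) paste(x$fixed, collapse = " + ") else "1",
      " + (1 | region)   [n = ", x$n, "]\n", sep = "")
  if (!x$converged) {
    cat("  NOT CONVERGED: ", x$message, "\n")
    return(invisible(x))
  }
  stats::printCoefmat(x$coefficients, digits = 3)
  cat("Random intercept variance (region):", signif(x$ranef_var, 4),
      "  residual:", signif(x$resid_var, 4), "\n")
  invisible(x)
}

#' Random-intercept mixed model for resistance or resilience
#'
#' Fits `response ~ fixed terms + (1 | region)` by restricted maximum
#' likelihood, the workhorse of the cross-regional synthesis. Standardized
#' coefficients are computed by refitting with the response and continuous
#' predictors z-scored. Rows with missing response (e.g. undefined
#' resilience) are dropped listwise. With a single region the model
#' degenerates to ordinary least squares. Non-convergence is reported in the
#' result, not raised.
#'
#' @param table A `study_table`.
#' @param response `"resistance"` or `"resilience"` (any numeric column is
#'   accepted).
#' @param fixed Character vector of fixed-effect terms, default
#'   `"log_frequency"`.
#' @param reml Fit by REML (default) or ML.
#' @return A `mixed_model_result`: coefficient tables (raw and
#'   standardized), variance components, marginal AIC (from an ML refit) and
#'   convergence flags.
#' @export
fit_mixed <- function(table, response = c("resistance", "resilience"),
                      fixed = "log_frequency", reml = TRUE) {
  if (length(response) > 1L) response <- match.arg(response)
  fit_one_mixed(table, response, fixed, reml = reml)
}

#' Stepwise fixed-effect selection by information criterion
#'
#' Forward selection over candidate fixed effects for a random-intercept
#' model: starting from the intercept-only model, the candidate giving the
#' greatest AIC improvement (on ML refits, so fixed effects are comparable)
#' is added until no addition improves the criterion. The region random
#' intercept is always retained. Selection is deterministic given the data.
#'
#' @param table A `study_table`.
#' @param response Response column name.
#' @param candidates Candidate fixed-effect terms.
#' @return The selected model (refitted by REML), with the selection path in
#'   `$selection_path`.
#' @export
stepwise_ic <- function(table, response,
                        candidates = c("log_frequency", "pace", "category",
                                       "dist_type", "land_use", "change")) {
  candidates <- intersect(candidates, names(table))
  # common row set across all candidates so criteria are comparable
  keep <- stats::complete.cases(table[, c(response, candidates, "region"),
                                      drop = FALSE])
  tab <- table[keep, , drop = FALSE]
  selected <- character(0)
  current <- fit_one_mixed(tab, response, selected, reml = FALSE)
  path <- data.frame(step = 0L, added = "(none)", aic = current$aic)
  repeat {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    trials <- lapply(remaining, function(cand)
      fit_one_mixed(tab, response, c(selected, cand), reml = FALSE))
    aics <- vapply(trials, function(f)
      if (is.na(f$aic)) Inf else f$aic, numeric(1))
    best <- which.min(aics)
    if (aics[best] >= current$aic - 1e-8) break
    selected <- c(selected, remaining[best])
    current <- trials[[best]]
    path <- rbind(path, data.frame(step = nrow(path),
                                   added = remaining[best],
                                   aic = current$aic))
  }
  final <- fit_one_mixed(tab, response, selected, reml = TRUE)
  final$selection_path <- path
  final
}

#' Mixed model for the frequency of downturns
#'
#' Fits `log_frequency ~ land_use + change + dist_type + pace +
#' (1 | region)` with hunter-gatherer as the land-use reference level.
#' Land-use levels observed fewer than twice are merged into `"mixed"` with
#' a warning.
#'
#' @param table A `study_table` with complete annotation columns.
#' @param fixed Fixed-effect terms, defaulting to the full suite.
#' @return A `mixed_model_result`.
#' @export
fit_frequency_model <- function(table,
                                fixed = c("land_use", "change", "dist_type",
                                          "pace")) {
  table <- as.data.frame(table)
  lu <- table$land_use
  rare <- names(which(table(lu) < 2L))
  if (length(rare)) {
    warning("land-use level(s) with < 2 rows merged into 'mixed': ",
            paste(rare, collapse = ", "), call. = FALSE)
    lu[lu %in% rare] <- "mixed"
  }
  levs <- unique(lu)
  ref <- if ("hunter-gatherer" %in% levs) "hunter-gatherer" else levs[1]
  table$land_use <- stats::relevel(factor(lu), ref = ref)
  out <- fit_one_mixed(table, "log_frequency", fixed, reml = TRUE)
  class(out) <- "mixed_model_result"
  out
}
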