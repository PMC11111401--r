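# deterministic 32-bit string hash so per-region, per-stage seeds do not
# depend on region order
hash_seed <- function(base_seed, name, stage) {
  h <- as.double(base_seed %% 2147483647L)
  for (ch in utf8ToInt(paste0(name, ":", stage)))
    h <- (h * 31 + ch) %% 2147483629
  as.integer(h %% 2147483647)
}

#' Region configuration for a study run
#'
#' @param name Region label (unique within a study).
#' @param dates A `c14_dates` table or CSV path.
#' @param bounds Numeric `c(a, b)` model bounds, cal BP.
#' @param breakpoints Calendar years BP of documented demographic
#'   transitions at which the dataset is split (default none).
#' @param region_start Older edge of the regional record for the frequency
#'   denominator; defaults to the older bound.
#' @return A list of class `region_config`.
#' @export
region_config <- function(name, dates, bounds, breakpoints = numeric(0),
                          region_start = NULL) {
  structure(list(name = name, dates = dates, bounds = bounds,
                 breakpoints = breakpoints,
                 region_start = if (is.null(region_start)) max(bounds)
                                else region_start),
            class = "region_config")
}

# run every stage for one region (or one split segment thereof)
run_segment <- function(dates, curve, bounds, mcmc, n_sim, level, seed,
                        region, min_duration = 10) {
  bins <- bin_dates(dates)
  dens <- lapply(seq_len(nrow(dates)), function(i)
    calibrate_date(dates$cra[i], dates$error[i], curve))
  spd <- build_spd(dens, bins, bounds, region = region)
  cb <- prepare_bins(dates, curve, bounds, bins = bins)
  mcmc$seed <- hash_seed(seed, region, "mcmc")
  post <- fit_mcmc(cb, mcmc)
  env <- posterior_predictive_envelope(
    post, n_dates = cb$n_bins, lab_errors = dates$error, curve = curve,
    bounds = bounds, n_sim = n_sim, level = level,
    seed = hash_seed(seed, region, "envelope"))
  list(downturns = detect_downturns(spd, env, min_duration = min_duration),
       posterior = post, envelope = env, spd = spd,
       diagnostics = diagnostics(post))
}

#' Run the full downturn meta-analysis pipeline
#'
#' For each region: calibrate and bin the dates, build the SPD, fit the
#' bounded exponential growth model by MCMC (per segment when the region is
#' split at demographic transitions), derive the posterior-predictive
#' envelope, detect downturns, drop transition-adjacent ones, and attach
#' frequency metrics. Regional downturn tables are concatenated, joined with
#' the annotations, and passed to the descriptive and mixed-model synthesis.
#' A failing region is recorded and skipped; the others still run.
#'
#' Seeds for each region and stage are derived from the global seed by a
#' name-keyed hash, so adding a region does not perturb the others' draws.
#'
#' @param regions List of [region_config()] entries.
#' @param curve A [cal_curve()] (shared; per-region curves may be supplied
#'   as a named list keyed by region name).
#' @param annotations Annotation table or CSV path (see
#'   [assemble_table()]); `NULL` to stop after metric extraction.
#' @param mcmc An [mcmc_config()] template.
#' @param n_sim Posterior-predictive replicates per region.
#' @param level Envelope coverage.
#' @param margin Transition-adjacency margin in years.
#' @param seed Global seed.
#' @return List of class `study_run`: `table` (the study table, or the bare
#'   downturn table when `annotations` is `NULL`), `per_region` results,
#'   `describe` + fitted models (when annotations are present), and
#'   `failures`.
#' @export
run_study <- function(regions, curve, annotations = NULL,
                      mcmc = mcmc_config(), n_sim = 1000L, level = 0.90,
                      margin = 0, seed = 1L) {
  nms <- vapply(regions, function(r) r$name, character(1))
  if (anyDuplicated(nms))
    stop("region names must be unique", call. = FALSE)
  per_region <- list()
  failures <- list()
  all_downturns <- NULL
  for (rc in regions) {
    res <- tryCatch({
      dates <- read_dates(rc$dates, region = rc$name)
      crv <- if (inherits(curve, "cal_curve")) curve else curve[[rc$name]]
      segs <- split_region(dates, crv, rc$bounds, rc$breakpoints)
      seg_res <- lapply(segs, function(sg)
        run_segment(sg$dates, crv, sg$bounds, mcmc, n_sim, level, seed,
                    rc$name))
      dts <- do.call(rbind, lapply(seg_res, `[[`, "downturns"))
      dts <- dts[order(-dts$T_start), , drop = FALSE]
      dts <- drop_transition_adjacent(dts, rc$breakpoints, margin = margin)
      dts <- downturn_frequency(dts, region_start = rc$region_start)
      list(downturns = dts, segments = seg_res)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[rc$name]] <- conditionMessage(res)
      next
    }
    per_region[[rc$name]] <- res
    all_downturns <- rbind(all_downturns, res$downturns)
  }
  out <- list(per_region = per_region, failures = failures,
              table = all_downturns)
  if (!is.null(annotations) && !is.null(all_downturns) &&
      nrow(all_downturns)) {
    tab <- assemble_table(all_downturns, annotations)
    out$table <- tab
    if (nrow(tab) >= 3L && length(unique(tab$region)) >= 2L) {
      out$describe <- tryCatch(describe(tab), error = function(e) NULL)
      out$model_resistance <- fit_mixed(tab, "resistance")
      out$model_resilience <- fit_mixed(tab[tab$resilience_defined, ],
                                        "resilience")
      out$model_frequency <- tryCatch(fit_frequency_model(tab),
                                      error = function(e) NULL)
    }
  }
  class(out) <- "study_run"
  out
}

#' @export
print.study_run <- function(x, ...) {
  n <- length(x$per_region)
  cat("Study run: ", n, " region(s) completed, ",
      length(x$failures), " failed\n", sep = "")
  if (!is.null(x$table))
    cat("  downturns detected: ", nrow(x$table), "\n", sep = "")
  for (nm in names(x$failures))
    cat("  FAILED ", nm, ": ", x$failures[[nm]], "\n", sep = "")
  invisible(x)
}
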