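#' Define a synthetic regional scenario
#'
#' A scenario fixes the demographic truth behind a synthetic radiocarbon
#' dataset: a bounded exponential growth trajectory over `[b, a]` cal BP
#' with growth rate `r`, reshaped by zero or more injected "bust" episodes.
#' Each bust is a multiplicative V-shape: the trajectory declines linearly
#' to `1 - depth` of its unperturbed level at the bust midpoint, then
#' recovers linearly to `1 - depth + depth * recovery` at the bust end.
#'
#' @param region Region label.
#' @param a,b Older and younger bounds, cal BP.
#' @param r True annual growth rate.
#' @param busts data.frame with columns `T_start`, `T_end`, `depth`
#'   (fraction in (0, 1]) and `recovery` (fraction of the depth regained by
#'   the bust end); `NULL` for none. Busts must lie within the bounds and
#'   not overlap.
#' @param n_dates Number of radiocarbon dates to simulate.
#' @param n_sites Number of sites the dates are spread over.
#' @param lab_error_mean,lab_error_sd Gaussian lab-error distribution
#'   (years), truncated at 10 years to mimic realistic assays.
#' @param seed Integer seed.
#' @return A list of class `scenario`.
#' @export
scenario <- function(region = "synthetic", a = 6000, b = 1000, r = 0.002,
                     busts = NULL, n_dates = 500, n_sites = 25,
                     lab_error_mean = 40, lab_error_sd = 10, seed = 1L) {
  if (a <= b) stop("bounds must satisfy a > b", call. = FALSE)
  if (n_dates < 1L) stop("n_dates must be at least 1", call. = FALSE)
  if (!is.null(busts) && nrow(busts)) {
    stopifnot(all(c("T_start", "T_end", "depth", "recovery") %in%
                    names(busts)))
    if (any(busts$T_start <= busts$T_end))
      stop("each bust needs T_start > T_end", call. = FALSE)
    if (any(busts$T_start > a | busts$T_end < b))
      stop("busts must lie within the scenario bounds", call. = FALSE)
    if (any(busts$depth <= 0 | busts$depth > 1))
      stop("bust depth must be in (0, 1]", call. = FALSE)
    bs <- busts[order(-busts$T_start), , drop = FALSE]
    if (nrow(bs) > 1L &&
        any(bs$T_end[-nrow(bs)] < bs$T_start[-1]))
      stop("busts must not overlap", call. = FALSE)
    busts <- bs
  }
  structure(list(region = region, a = a, b = b, r = r, busts = busts,
                 n_dates = n_dates, n_sites = n_sites,
                 lab_error_mean = lab_error_mean,
                 lab_error_sd = lab_error_sd, seed = as.integer(seed)),
            class = "scenario")
}

#' True relative-activity trajectory of a scenario
#'
#' Evaluates the scenario's generating density on the 1-year calendar grid:
#' the bounded exponential growth density multiplied by each bust's V-shaped
#' factor, renormalized to unit mass. The truth record reports, per bust,
#' the trajectory values at its start, minimum and end, and the implied
#' resistance and resilience under the study's metric definitions.
#'
#' @param s A [scenario()].
#' @return List of class `trajectory`: `cal_bp` (descending grid),
#'   `density` (sums to 1 over the grid), `raw` (before renormalization) and
#'   `truth` (per-bust data.frame).
#' @export
trajectory <- function(s) {
  stopifnot(inherits(s, "scenario"))
  grid <- seq(s$a, s$b, by = -1)
  base <- growth_density(grid, s$r, s$a, s$b)
  fac <- rep(1, length(grid))
  truth <- NULL
  if (!is.null(s$busts) && nrow(s$busts)) {
    for (i in seq_len(nrow(s$busts))) {
      ts <- s$busts$T_start[i]; te <- s$busts$T_end[i]
      depth <- s$busts$depth[i]; rec <- s$busts$recovery[i]
      tm <- (ts + te) / 2
      floor_val <- 1 - depth
      end_val <- 1 - depth + depth * rec
      in_decline <- grid <= ts & grid >= tm
      in_recover <- grid < tm & grid >= te
      fac[in_decline] <- 1 + (floor_val - 1) * (ts - grid[in_decline]) /
        (ts - tm)
      fac[in_recover] <- floor_val + (end_val - floor_val) *
        (tm - grid[in_recover]) / (tm - te)
      b_val <- base[grid == round(ts)]
      x_val <- base[grid == round(tm)] * floor_val
      e_val <- base[grid == round(te)] * end_val
      truth <- rbind(truth, data.frame(
        T_start = ts, T_end = te, t_min = tm, depth = depth,
        recovery = rec, b = b_val, x = x_val, e = e_val,
        resistance = resistance(b_val, x_val),
        resilience = resilience(b_val, x_val, e_val)))
    }
  }
  raw <- base * fac
  structure(list(cal_bp = grid, density = raw / sum(raw), raw = raw,
                 truth = truth),
            class = "trajectory")
}

#' Generate a synthetic regional radiocarbon dataset
#'
#' Samples calendar years from the scenario's trajectory, back-calibrates
#' each through the calibration curve with a lab error drawn from the
#' scenario's (truncated Gaussian) error distribution, assigns dates
#' round-robin to synthetic sites and labels them with synthetic lab IDs.
#' Deterministic given the scenario seed.
#'
#' @param s A [scenario()].
#' @param curve A [cal_curve()] spanning the scenario bounds.
#' @return List: `dates` (a `c14_dates` data.frame), `truth` (the
#'   trajectory truth record) and `trajectory`.
#' @export
generate_region <- function(s, curve) {
  stopifnot(inherits(s, "scenario"), inherits(curve, "cal_curve"))
  if (max(curve$cal_bp) < s$a || min(curve$cal_bp) > s$b)
    stop("curve does not span the scenario bounds", call. = FALSE)
  tr <- trajectory(s)
  rng <- local_rng(s$seed)
  dates <- rng({
    cal_years <- sample(tr$cal_bp, s$n_dates, replace = TRUE,
                        prob = tr$density)
    errs <- pmax(10, stats::rnorm(s$n_dates, s$lab_error_mean,
                                  s$lab_error_sd))
    cras <- sample_uncal(cal_years, curve, errs)
    data.frame(
      lab_id = sprintf("SYN-%s-%04d", s$region, seq_len(s$n_dates)),
      site_id = sprintf("%s_site%02d", s$region,
                        (seq_len(s$n_dates) - 1L) %% s$n_sites + 1L),
      cra = round(cras), error = round(errs), region = s$region,
      true_cal_bp = cal_years, stringsAsFactors = FALSE)
  })
  list(dates = read_dates(dates), truth = tr$truth, trajectory = tr)
}

#' Generate a multi-region synthetic study with annotations
#'
#' Emulates the cross-sectional design of the meta-analysis: several
#' regions, each with its own bust history, where by construction the
#' land-use class shifts the expected number of busts by a configured
#' multiplier. Each region is assigned a land use, its bust count is drawn
#' from a Poisson with mean `base_busts * multiplier[land_use]`, and bust
#' intervals are placed without overlap. Annotations (category, disturbance
#' type, land use, change flag) are emitted alongside the truth.
#'
#' @param n_regions Number of regions (>= 2).
#' @param curve A [cal_curve()] spanning the template bounds.
#' @param a,b,r,n_dates,n_sites Scenario template shared by all regions.
#' @param base_busts Expected bust count for the reference land use.
#' @param land_uses Land-use classes to assign (recycled across regions).
#' @param multipliers Named multipliers on the bust rate per land use;
#'   classes not named get 1.
#' @param bust_depth,bust_duration,bust_recovery Bust shape parameters.
#' @param seed Integer seed.
#' @return List: `regions` (per-region [generate_region()] output),
#'   `annotations` (data.frame), `truth` (per-region land use, multiplier
#'   and bust count).
#' @export
generate_study <- function(n_regions = 8, curve, a = 6000, b = 1000,
                           r = 0.002, n_dates = 400, n_sites = 20,
                           base_busts = 2,
                           land_uses = c("hunter-gatherer", "agriculture"),
                           multipliers = c(agriculture = 1),
                           bust_depth = 0.5, bust_duration = 300,
                           bust_recovery = 0.8, seed = 1L) {
  if (n_regions < 2L) stop("need at least 2 regions", call. = FALSE)
  rng <- local_rng(seed)
  rng({
    regions <- vector("list", n_regions)
    ann <- NULL
    truth <- NULL
    for (g in seq_len(n_regions)) {
      name <- sprintf("R%02d", g)
      lu <- land_uses[(g - 1L) %% length(land_uses) + 1L]
      mult <- if (lu %in% names(multipliers)) multipliers[[lu]] else 1
      n_busts <- stats::rpois(1, base_busts * mult)
      # place busts on a jittered regular layout so they cannot overlap
      busts <- NULL
      if (n_busts > 0) {
        slots <- seq(a - bust_duration, b + bust_duration,
                     length.out = max(n_busts, 2))
        centers <- sort(sample(slots, min(n_busts, length(slots))),
                        decreasing = TRUE)
        busts <- data.frame(T_start = centers + bust_duration / 2,
                            T_end = centers - bust_duration / 2,
                            depth = bust_depth, recovery = bust_recovery)
        busts <- busts[busts$T_start <= a & busts$T_end >= b, ,
                       drop = FALSE]
        if (!nrow(busts)) busts <- NULL
      }
      sc <- scenario(region = name, a = a, b = b, r = r, busts = busts,
                     n_dates = n_dates, n_sites = n_sites,
                     seed = sample.int(2^31 - 1, 1))
      regions[[g]] <- c(generate_region(sc, curve), list(scenario = sc))
      nb <- if (is.null(busts)) 0L else nrow(busts)
      truth <- rbind(truth, data.frame(region = name, land_use = lu,
                                       multiplier = mult, n_busts = nb))
      if (nb > 0) {
        ann <- rbind(ann, data.frame(
          region = name, T_start = busts$T_start,
          category = sample(c("environmental", "cultural", "mixed",
                              "unclear"), nb, replace = TRUE),
          dist_type = sample(c("aridity", "mobility", "cooling",
                               "variability"), nb, replace = TRUE),
          land_use = lu,
          change = sample(c(TRUE, FALSE), nb, replace = TRUE)))
      }
    }
    list(regions = regions, annotations = ann, truth = truth)
  })
}

#' Study table implied by a synthetic study's generating truth
#'
#' Builds the per-downturn analysis table directly from the true bust
#' records of [generate_study()] — the table an ideal detector would
#' extract — with metrics, frequencies and annotations joined. Useful for
#' testing the statistical synthesis separately from the detection stages.
#'
#' @param study Output of [generate_study()].
#' @return A `study_table` (empty regions contribute no rows).
#' @export
truth_table <- function(study) {
  rows <- NULL
  for (g in seq_along(study$regions)) {
    reg <- study$regions[[g]]
    tru <- reg$truth
    if (is.null(tru) || !nrow(tru)) next
    sc <- reg$scenario
    dt <- data.frame(region = sc$region, T_start = tru$T_start,
                     T_end = tru$T_end, t_min = tru$t_min,
                     b = tru$b, x = tru$x, e = tru$e,
                     duration = tru$T_start - tru$T_end,
                     time_to_min = tru$T_start - tru$t_min,
                     stringsAsFactors = FALSE)
    dt <- downturn_frequency(dt, region_start = sc$a)
    rows <- rbind(rows, dt)
  }
  if (is.null(rows)) stop("no busts in the study truth", call. = FALSE)
  assemble_table(rows, study$annotations, tolerance = 0.5)
}
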