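#' Posterior-predictive critical envelope for an observed SPD
#'
#' For each replicate a growth rate is drawn from the posterior, `n_dates`
#' calendar years are drawn from the fitted growth density, each is
#' back-calibrated through the curve with a lab error resampled (with
#' replacement) from the observed errors, re-calibrated, and summed into an
#' SPD. Pointwise lower and upper quantiles across replicates form the
#' critical envelope (default 90%: 5th/95th percentiles of 1,000 replicates).
#'
#' Replicates use one simulated date per sampling unit, so `n_dates` should
#' equal the number of bins behind the observed SPD.
#'
#' @param posterior A `posterior_sample` from [fit_mcmc()].
#' @param n_dates Number of dates per simulated dataset.
#' @param lab_errors Observed 1-sigma lab errors to resample from.
#' @param curve A [cal_curve()] covering the bounds.
#' @param bounds Numeric `c(a, b)` model bounds, cal BP.
#' @param n_sim Number of replicates, default 1000.
#' @param level Envelope coverage, default 0.90 (two-sided pointwise).
#' @param normalize Passed to [calibrate_date()]; must match the observed SPD.
#' @param trunc Per-date truncation threshold as a fraction of peak mass;
#'   must match the observed SPD's calibration truncation.
#' @param seed Integer seed.
#' @return Object of class `pp_envelope`: `cal_bp` grid, `lower`, `upper`,
#'   `level`, `n_sim`.
#' @export
posterior_predictive_envelope <- function(posterior, n_dates, lab_errors,
                                          curve, bounds, n_sim = 1000L,
                                          level = 0.90, normalize = FALSE,
                                          trunc = 1e-7, seed = 1L) {
  stopifnot(inherits(posterior, "posterior_sample"))
  if (length(posterior$draws) == 0L)
    stop("empty posterior sample", call. = FALSE)
  if (n_dates < 1L) stop("n_dates must be at least 1", call. = FALSE)
  a <- max(bounds); b <- min(bounds)
  grid <- seq(a, b, by = -1)
  at <- curve_at(curve, grid)
  if (anyNA(at$c14))
    stop("calibration curve does not cover the bounds", call. = FALSE)
  sims <- matrix(NA_real_, nrow = n_sim, ncol = length(grid))
  draws <- as.numeric(posterior$draws)
  # calibrated mass below `trunc` of the peak is treated as zero (as in
  # calibrate_date), so each simulated date only touches a window of
  # z_cut = sqrt(-2 log(trunc)) sigmas around its age; computing on those
  # windows instead of the full grid keeps the 1,000-replicate default fast
  z_cut <- sqrt(-2 * log(trunc)) + 1
  half_w <- ceiling(z_cut * sqrt(max(lab_errors)^2 + max(at$sigma)^2))
  offsets <- seq(-half_w, half_w)
  # a monotone curve has a single calendar solution per age, so each date's
  # mass lives in one window; wiggly (non-monotone) curves fall back to the
  # full grid to keep multimodal calibration exact
  monotone <- all(diff(at$c14) < 0)  # grid is oldest-first
  c14_rev <- if (monotone) rev(at$c14) else NULL
  one_spd <- function(cras, errs) {
    n <- length(cras)
    if (monotone) {
      center <- length(grid) + 1L -
        findInterval(cras, c14_rev, all.inside = TRUE)
      idx <- outer(center, offsets, `+`)
      ok <- idx >= 1L & idx <= length(grid)
      idx_c <- pmin(pmax(idx, 1L), length(grid))
      mass <- stats::dnorm(matrix(cras, n, length(offsets)),
                           mean = matrix(at$c14[idx_c], n,
                                         length(offsets)),
                           sd = sqrt(errs^2 +
                                       matrix(at$sigma[idx_c]^2, n,
                                              length(offsets))))
      mass[!ok] <- 0
      peak <- apply(mass, 1, max)
      mass[mass < trunc * peak] <- 0
      if (normalize) {
        tot <- rowSums(mass)
        tot[tot == 0] <- 1
        mass <- mass / tot
      }
      spd_s <- numeric(length(grid))
      acc <- rowsum(as.numeric(mass)[as.logical(ok)],
                    as.integer(idx)[as.logical(ok)])
      spd_s[as.integer(rownames(acc))] <- acc[, 1]
      spd_s
    } else {
      mass <- stats::dnorm(matrix(cras, n, length(grid)),
                           mean = matrix(at$c14, n, length(grid),
                                         byrow = TRUE),
                           sd = sqrt(outer(errs^2, at$sigma^2, `+`)))
      peak <- apply(mass, 1, max)
      mass[mass < trunc * peak] <- 0
      if (normalize) {
        tot <- rowSums(mass)
        tot[tot == 0] <- 1
        mass <- mass / tot
      }
      colSums(mass)
    }
  }
  rng <- local_rng(seed)
  rng({
    for (s in seq_len(n_sim)) {
      r <- draws[sample.int(length(draws), 1L)]
      cal_years <- sample_growth(n_dates, r, a, b)
      errs <- lab_errors[sample.int(length(lab_errors), n_dates,
                                    replace = TRUE)]
      mu <- stats::approx(curve$cal_bp, curve$c14_age, xout = cal_years)$y
      sg <- stats::approx(curve$cal_bp, curve$sigma_curve,
                          xout = cal_years)$y
      cras <- stats::rnorm(n_dates, mu, sqrt(errs^2 + sg^2))
      sims[s, ] <- one_spd(cras, errs)
    }
  })
  alpha <- (1 - level) / 2
  lower <- apply(sims, 2, stats::quantile, probs = alpha, names = FALSE)
  upper <- apply(sims, 2, stats::quantile, probs = 1 - alpha, names = FALSE)
  structure(list(cal_bp = grid, lower = lower, upper = upper,
                 level = level, n_sim = n_sim),
            class = "pp_envelope")
}

#' @export
print.pp_envelope <- function(x, ...) {
  cat("Posterior-predictive envelope: ", 100 * x$level, "% pointwise, ",
      x$n_sim, " replicates, ", max(x$cal_bp), "-", min(x$cal_bp),
      " cal BP\n", sep = "")
  invisible(x)
}

#' Detect population downturns below the critical envelope
#'
#' A downturn is a maximal run of consecutive calendar years where the
#' observed SPD falls strictly below the lower envelope bound. Runs lasting
#' `min_duration` years or fewer are conservatively discarded (default: only
#' events greater than ten years in duration are kept). For each surviving
#' run, the baseline `b` is the SPD value at the first sub-envelope year, `x`
#' the minimum over the run, `e` the value at the last sub-envelope year, and
#' `t_min` the year of the minimum (oldest on ties).
#'
#' @param spd An `spd_grid`.
#' @param env A `pp_envelope` on the same grid.
#' @param min_duration Minimum duration in years (exclusive), default 10.
#' @return data.frame of class `downturn_table` with columns `region`,
#'   `T_start`, `T_end`, `t_min`, `b`, `x`, `e`, `duration`, `time_to_min`,
#'   ordered oldest first.
#' @export
detect_downturns <- function(spd, env, min_duration = 10) {
  stopifnot(inherits(spd, "spd_grid"), inherits(env, "pp_envelope"))
  if (length(spd$cal_bp) != length(env$cal_bp) ||
      any(spd$cal_bp != env$cal_bp))
    stop("SPD and envelope grids are not aligned", call. = FALSE)
  below <- spd$spd < env$lower
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    T_start <- spd$cal_bp[i0]; T_end <- spd$cal_bp[i1]
    duration <- T_start - T_end
    if (duration <= min_duration) next
    seg <- spd$spd[i0:i1]
    imin <- i0 + which.min(seg) - 1L  # which.min takes the first = oldest
    out[[length(out) + 1L]] <- data.frame(
      region = spd$region, T_start = T_start, T_end = T_end,
      t_min = spd$cal_bp[imin], b = spd$spd[i0], x = spd$spd[imin],
      e = spd$spd[i1], duration = duration,
      time_to_min = T_start - spd$cal_bp[imin],
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(region = character(0), T_start = numeric(0),
               T_end = numeric(0), t_min = numeric(0), b = numeric(0),
               x = numeric(0), e = numeric(0), duration = numeric(0),
               time_to_min = numeric(0), stringsAsFactors = FALSE)
  res <- res[order(-res$T_start), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("downturn_table", "data.frame")
  res
}

#' Drop downturns adjacent to dataset transition points
#'
#' Regional datasets split at demographic transitions can show edge
#' artefacts; downturns whose interval overlaps a breakpoint (within an
#' optional margin) are removed from the sample.
#'
#' @param downturns A `downturn_table`.
#' @param breakpoints Calendar years BP of the transitions.
#' @param margin Years around each breakpoint also treated as adjacent,
#'   default 0 (only overlapping downturns dropped).
#' @return The filtered `downturn_table`.
#' @export
drop_transition_adjacent <- function(downturns, breakpoints,
                                     margin = 0) {
  if (length(breakpoints) == 0L || nrow(downturns) == 0L) return(downturns)
  keep <- vapply(seq_len(nrow(downturns)), function(i) {
    !any(downturns$T_start[i] >= breakpoints - margin &
           downturns$T_end[i] <= breakpoints + margin)
  }, logical(1))
  out <- downturns[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
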