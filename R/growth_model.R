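#' Bounded exponential growth density
#'
#' Probability density per calendar year of a bounded exponential growth
#' model with growth toward the present: on `b <= t <= a` (cal BP),
#' `f(t) = r * exp(r * (a - t)) / (exp(r * (a - b)) - 1)` for `r != 0`, with
#' the uniform limit `1 / (a - b)` as `r -> 0`. Outside the bounds the
#' density is zero.
#'
#' @param t Calendar years BP (vectorized).
#' @param r Annual growth rate.
#' @param a,b Older and younger bounds, cal BP (`a > b`).
#' @return Density values per year.
#' @export
growth_density <- function(t, r, a, b) {
  if (a <= b) stop("bounds must satisfy a > b", call. = FALSE)
  if (!is.finite(r)) stop("r must be finite", call. = FALSE)
  L <- a - b
  f <- if (abs(r) < 1e-12) {
    rep(1 / L, length(t))
  } else {
    r * exp(r * (a - t)) / expm1(r * L)
  }
  f[t < b | t > a] <- 0
  f
}

# Inverse-CDF sampler for the bounded exponential density; u = a - t is
# truncated-exponential on [0, a - b].
sample_growth <- function(n, r, a, b) {
  p <- stats::runif(n)
  L <- a - b
  u <- if (abs(r) < 1e-12) p * L else log1p(p * expm1(r * L)) / r
  a - u
}

#' Prepare binned calibration data for model fitting
#'
#' Precomputes, for every bin, the averaged measurement likelihood over the
#' 1-year calendar grid spanning the model bounds: for a bin with member
#' dates i, `w(t) = mean_i Normal(cra_i; curve_mean(t), lab_error_i^2 +
#' curve_error(t)^2)`. Multi-date bins contribute a single averaged
#' likelihood, keeping the fitted model on the same sampling unit as the
#' bin-averaged SPD.
#'
#' @param dates A `c14_dates` table (see [read_dates()]).
#' @param curve A [cal_curve()] on a 1-year grid covering `[b, a]`.
#' @param bounds Numeric `c(a, b)`, older bound first or not (sorted
#'   internally).
#' @param bins Bin assignment from [bin_dates()]; `NULL` to compute with the
#'   default 50-year cut.
#' @return Object of class `c14_bins`: calendar grid (descending), the
#'   n_bins x n_grid likelihood matrix, the bin table and bounds.
#' @export
prepare_bins <- function(dates, curve, bounds, bins = NULL) {
  dates <- read_dates(dates)
  a <- max(bounds); b <- min(bounds)
  grid <- seq(a, b, by = -1)
  at <- curve_at(curve, grid)
  if (anyNA(at$c14))
    stop("calibration curve does not cover the model bounds", call. = FALSE)
  if (is.null(bins)) bins <- bin_dates(dates)
  # per-date likelihood over the grid, then bin means
  lik_date <- function(i) {
    stats::dnorm(dates$cra[i], mean = at$c14,
                 sd = sqrt(dates$error[i]^2 + at$sigma^2))
  }
  bin_ids <- unique(bins$bin_id)
  lik <- matrix(0, nrow = length(bin_ids), ncol = length(grid),
                dimnames = list(bin_ids, NULL))
  for (j in seq_along(bin_ids)) {
    ids <- which(bins$bin_id == bin_ids[j])
    m <- lik_date(ids[1])
    if (length(ids) > 1L)
      for (i in ids[-1]) m <- m + lik_date(i)
    lik[j, ] <- m / length(ids)
  }
  # far Gaussian tails (< 1e-12 of the row peak) carry no information but
  # dominate the matrix size; zero them and store sparsely
  lik[lik < 1e-12 * apply(lik, 1, max)] <- 0
  lik <- Matrix::Matrix(lik, sparse = TRUE)
  structure(list(cal_bp = grid, lik = lik, bins = bins,
                 a = a, b = b, n_dates = nrow(dates),
                 n_bins = length(bin_ids)),
            class = "c14_bins")
}

#' Log likelihood of the growth model over binned dates
#'
#' Each bin's marginal probability integrates the growth density against the
#' bin's averaged measurement likelihood over the 1-year grid, accounting for
#' radiocarbon measurement error and sampling error simultaneously; the log
#' likelihood sums the per-bin log marginals.
#'
#' @param bins A `c14_bins` object from [prepare_bins()].
#' @param r Growth rate.
#' @return Log likelihood; `-Inf` (with a warning naming the bins) when any
#'   bin has zero marginal probability.
#' @export
log_likelihood <- function(bins, r) {
  stopifnot(inherits(bins, "c14_bins"))
  f <- growth_density(bins$cal_bp, r, bins$a, bins$b)
  marg <- as.numeric(bins$lik %*% f)
  if (any(marg <= 0)) {
    warning("zero marginal probability for bin(s): ",
            paste(rownames(bins$lik)[marg <= 0], collapse = ", "),
            call. = FALSE)
    return(-Inf)
  }
  sum(log(marg))
}

#' MCMC configuration
#'
#' Defaults follow the study protocol: three chains of 50,000 iterations,
#' burn-in 5,000, thinning interval 2, and a weakly informative exponential
#' prior on the growth rate with mean 4e-4 (rate 2500).
#'
#' @param n_chains Number of chains.
#' @param n_iter Iterations per chain.
#' @param burn_in Burn-in iterations discarded per chain.
#' @param thin Thinning interval.
#' @param prior_rate Rate of the exponential prior on `r >= 0`.
#' @param two_sided Allow negative growth rates under a symmetric
#'   (Laplace-type) prior; off by default.
#' @param proposal_sd Initial random-walk proposal s.d.
#' @param seed Integer seed.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3L, n_iter = 50000L, burn_in = 5000L,
                        thin = 2L, prior_rate = 2500, two_sided = FALSE,
                        proposal_sd = 5e-4, seed = 1L) {
  stopifnot(burn_in < n_iter, thin >= 1, prior_rate > 0, n_chains >= 1)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 prior_rate = prior_rate, two_sided = two_sided,
                 proposal_sd = proposal_sd, seed = as.integer(seed)),
            class = "mcmc_config")
}

log_prior <- function(r, cfg) {
  if (cfg$two_sided) {
    log(0.5) + stats::dexp(abs(r), rate = cfg$prior_rate, log = TRUE)
  } else {
    if (r < 0) -Inf else stats::dexp(r, rate = cfg$prior_rate, log = TRUE)
  }
}

#' Fit the bounded exponential growth model by MCMC
#'
#' Random-walk Metropolis on the growth rate with an exponential prior.
#' Chains are initialized at independent prior draws; the proposal scale
#' adapts during burn-in toward an acceptance rate between 0.2 and 0.5 and is
#' frozen afterwards to preserve detailed balance. Deterministic given the
#' configuration seed.
#'
#' @param bins A `c14_bins` object from [prepare_bins()] (>= 5 bins).
#' @param config An [mcmc_config()].
#' @return Object of class `posterior_sample`: matrix of retained draws
#'   (rows = draws, columns = chains), per-chain acceptance rates, and the
#'   config.
#' @export
fit_mcmc <- function(bins, config = mcmc_config()) {
  stopifnot(inherits(bins, "c14_bins"), inherits(config, "mcmc_config"))
  if (bins$n_bins < 5L)
    stop("at least 5 bins are required to fit the growth model",
         call. = FALSE)
  n_keep <- (config$n_iter - config$burn_in) %/% config$thin
  draws <- matrix(NA_real_, nrow = n_keep, ncol = config$n_chains)
  accept <- numeric(config$n_chains)
  rng <- local_rng(config$seed)
  rng({
    for (ch in seq_len(config$n_chains)) {
      r <- stats::rexp(1, rate = config$prior_rate)
      if (config$two_sided && stats::runif(1) < 0.5) r <- -r
      lp <- log_likelihood(bins, r) + log_prior(r, config)
      step <- config$proposal_sd
      n_acc <- 0L; n_acc_win <- 0L; k <- 0L
      for (it in seq_len(config$n_iter)) {
        prop <- r + stats::rnorm(1, 0, step)
        lp_prop <- log_prior(prop, config)
        if (is.finite(lp_prop)) lp_prop <- lp_prop + log_likelihood(bins, prop)
        if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
          r <- prop; lp <- lp_prop
          n_acc <- n_acc + 1L; n_acc_win <- n_acc_win + 1L
        }
        if (it <= config$burn_in && it %% 100L == 0L) {
          rate <- n_acc_win / 100
          if (rate < 0.2) step <- step * 0.7
          if (rate > 0.5) step <- step * 1.4
          n_acc_win <- 0L
        }
        if (it > config$burn_in &&
            (it - config$burn_in) %% config$thin == 0L) {
          k <- k + 1L
          draws[k, ch] <- r
        }
      }
      accept[ch] <- n_acc / config$n_iter
      k <- 0L
    }
  })
  if (any(accept < 0.01))
    warning("chain(s) ", paste(which(accept < 0.01), collapse = ", "),
            " accepted fewer than 1% of proposals; the sampler failed to ",
            "move — inspect the data and proposal scale", call. = FALSE)
  structure(list(draws = draws, accept = accept, config = config,
                 a = bins$a, b = bins$b, n_bins = bins$n_bins),
            class = "posterior_sample")
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat("Posterior sample: ", ncol(x$draws), " chains x ", nrow(x$draws),
      " draws; mean r = ", signif(mean(x$draws), 4),
      ", 95% CrI [", signif(stats::quantile(x$draws, 0.025), 4), ", ",
      signif(stats::quantile(x$draws, 0.975), 4), "]\n", sep = "")
  invisible(x)
}

# --- convergence diagnostics -------------------------------------------------

# rank-normalize a draws matrix (rows = iterations, cols = chains)
rank_normalize <- function(draws) {
  S <- length(draws)
  z <- stats::qnorm((rank(draws) - 3 / 8) / (S + 1 / 4))
  matrix(z, nrow = nrow(draws), ncol = ncol(draws))
}

split_chains <- function(draws) {
  n <- nrow(draws)
  half <- n %/% 2L
  cbind(draws[seq_len(half), , drop = FALSE],
        draws[(n - half + 1L):n, , drop = FALSE])
}

# potential scale reduction on (rank-normalized, split) chains; the
# conservative form sqrt(1 + B/(n W)) is bounded below by 1
rhat_basic <- function(draws) {
  n <- nrow(draws)
  means <- colMeans(draws)
  vars <- apply(draws, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(1 + B / (n * W))
}

ess_basic <- function(draws) {
  n <- nrow(draws); m <- ncol(draws)
  vars <- apply(draws, 2, stats::var)
  W <- mean(vars)
  means <- colMeans(draws)
  var_plus <- (n - 1) / n * W + stats::var(means)
  if (var_plus == 0) return(n * m)
  # chain-averaged autocorrelations (Geyer initial monotone sequence)
  acov <- sapply(seq_len(m), function(ch) {
    x <- draws[, ch] - means[ch]
    stats::acf(x, lag.max = n - 1, type = "covariance",
               plot = FALSE, demean = FALSE)$acf[, 1, 1]
  })
  rho <- 1 - (W - rowMeans(acov)) / var_plus
  # sum consecutive pairs while positive and non-increasing
  max_pairs <- floor((length(rho) - 1) / 2)
  tau <- rho[1]
  prev <- Inf
  for (k in seq_len(max_pairs)) {
    pair <- rho[2 * k] + rho[2 * k + 1]
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, prev)
    tau <- tau + 2 * pair
    prev <- pair
  }
  min(n * m, n * m / max(tau, 1e-12))
}

#' Convergence diagnostics for a posterior sample
#'
#' Rank-normalized split-Rhat and bulk effective sample size, the standard
#' modern formulas for Markov chain convergence assessment.
#'
#' @param p A `posterior_sample` with at least two chains.
#' @return List of class `convergence_report` with `rhat` and `ess`.
#' @export
diagnostics <- function(p) {
  draws <- if (inherits(p, "posterior_sample")) p$draws else as.matrix(p)
  if (ncol(draws) < 2L)
    stop("diagnostics require at least two chains", call. = FALSE)
  sp <- split_chains(draws)
  z <- rank_normalize(sp)
  structure(list(rhat = rhat_basic(z), ess = ess_basic(z),
                 n_draws = length(draws)),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("Rhat = ", signif(x$rhat, 5), ", bulk ESS = ", round(x$ess),
      " of ", x$n_draws, " draws\n", sep = "")
  invisible(x)
}

#' Split a regional dataset at demographic transitions
#'
#' Partitions dates at documented palaeodemographic transitions so each
#' segment can be fitted as an independent bounded exponential model. Dates
#' are assigned to segments by the calendar year of their calibrated mode; a
#' mode falling exactly on a breakpoint goes to the older segment.
#'
#' @param dates A `c14_dates` table.
#' @param curve A [cal_curve()] covering the bounds.
#' @param bounds Numeric `c(a, b)` region bounds, cal BP.
#' @param breakpoints Calendar years BP strictly inside the bounds.
#' @return List of segments, each a list with `dates` and `bounds`, ordered
#'   oldest first.
#' @export
split_region <- function(dates, curve, bounds, breakpoints = numeric(0)) {
  dates <- read_dates(dates)
  a <- max(bounds); b <- min(bounds)
  if (length(breakpoints) == 0L)
    return(list(list(dates = dates, bounds = c(a, b))))
  if (any(breakpoints >= a | breakpoints <= b))
    stop("breakpoints must lie strictly inside the region bounds",
         call. = FALSE)
  bps <- sort(unique(breakpoints), decreasing = TRUE)
  modes <- vapply(seq_len(nrow(dates)), function(i) {
    d <- calibrate_date(dates$cra[i], dates$error[i], curve)
    d$cal_bp[which.max(d$mass)]
  }, numeric(1))
  edges_old <- c(a, bps)
  edges_young <- c(bps, b)
  lapply(seq_along(edges_old), function(k) {
    # segments are closed at their younger edge, open at the older edge
    # (except the oldest), so a mode exactly on a breakpoint goes older
    sel <- if (k == 1L) modes <= edges_old[k] & modes >= edges_young[k]
           else modes < edges_old[k] & modes >= edges_young[k]
    list(dates = dates[sel, , drop = FALSE],
         bounds = c(edges_old[k], edges_young[k]))
  })
}
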