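#' Radiocarbon date tables
#'
#' Validates a table of conventional radiocarbon ages. Required columns:
#' `lab_id`, `site_id`, `cra` (radiocarbon age BP) and `error` (1-sigma lab
#' error, years); an optional `region` column defaults to a single label.
#' A `col_map` named vector can translate supplementary-table header variants
#' (e.g. `c(cra = "C14Age", error = "C14SD")`).
#'
#' @param x A data.frame of dates, or a path to a CSV file.
#' @param region Region label applied when the table has no `region` column.
#' @param col_map Optional named character vector mapping required column
#'   names to the names present in `x`.
#' @return A validated data.frame of class `c14_dates`.
#' @export
read_dates <- function(x, region = "region", col_map = NULL) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("dates file not found: ", x, call. = FALSE)
    x <- utils::read.csv(x, stringsAsFactors = FALSE)
  }
  x <- as.data.frame(x)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (col_map[[std]] %in% names(x))
        names(x)[names(x) == col_map[[std]]] <- std
    }
  }
  need <- c("lab_id", "site_id", "cra", "error")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    stop("dates table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"region" %in% names(x)) x$region <- region
  x$cra <- as.numeric(x$cra)
  x$error <- as.numeric(x$error)
  if (anyNA(x$cra) || any(!is.finite(x$cra)))
    stop("cra must be finite and numeric", call. = FALSE)
  if (anyNA(x$error) || any(x$error <= 0))
    stop("error must be positive", call. = FALSE)
  class(x) <- c("c14_dates", "data.frame")
  x
}

#' Calibrate a single radiocarbon measurement
#'
#' Converts a conventional radiocarbon age to a probability mass function
#' over calendar years. The mass at calendar year t is proportional to the
#' Gaussian density of the measured age at the curve mean, with variance
#' equal to the lab error squared plus the curve error squared at t. Support
#' is truncated where the mass falls below `trunc` times the peak. Following
#' standard SPD practice the default output is not normalized; with
#' `normalize = TRUE` the mass is rescaled to sum to one.
#'
#' @param cra Conventional radiocarbon age BP.
#' @param error 1-sigma lab error, years (> 0).
#' @param curve A [cal_curve()] interpolated to a 1-year grid.
#' @param normalize Rescale mass to sum to 1?
#' @param trunc Truncation threshold as a fraction of peak mass.
#' @return An object of class `cal_density` with fields `cal_bp` (descending
#'   1-year grid) and `mass`, plus a `normalized` flag.
#' @export
calibrate_date <- function(cra, error, curve, normalize = FALSE,
                           trunc = 1e-7) {
  stopifnot(inherits(curve, "cal_curve"))
  if (error <= 0) stop("error must be positive", call. = FALSE)
  sd2 <- error^2 + curve$sigma_curve^2
  mass <- stats::dnorm(cra, mean = curve$c14_age, sd = sqrt(sd2))
  peak <- max(mass)
  if (peak <= 0 || !is.finite(peak))
    stop("date ", cra, " +/- ", error,
         " has no probability mass on the curve span", call. = FALSE)
  keep <- mass >= trunc * peak
  # clip to the contiguous window around the peak's support
  idx <- range(which(keep))
  sel <- idx[1]:idx[2]
  cal_bp <- curve$cal_bp[sel]
  mass <- mass[sel]
  mass[mass < trunc * peak] <- 0
  if (normalize) mass <- mass / sum(mass)
  structure(list(cal_bp = cal_bp, mass = mass, normalized = normalize),
            class = "cal_density")
}

#' @export
print.cal_density <- function(x, ...) {
  cat("Calibrated density: ", max(x$cal_bp), "-", min(x$cal_bp),
      " cal BP, mode at ", x$cal_bp[which.max(x$mass)], " cal BP",
      if (x$normalized) " (normalized)", "\n", sep = "")
  invisible(x)
}

#' Highest posterior density intervals of a calibrated date
#'
#' Returns the smallest set of calendar years holding at least `level` of the
#' probability mass, merged into contiguous intervals; the conventional
#' reporting level is the 95.4% (2-sigma) range.
#'
#' @param d A normalized `cal_density`.
#' @param level Coverage level, default 0.954.
#' @return data.frame with columns `start`, `end` (cal BP, start >= end) and
#'   `mass` (probability within the interval), ordered oldest first.
#' @export
hpd_interval <- function(d, level = 0.954) {
  stopifnot(inherits(d, "cal_density"))
  if (!isTRUE(d$normalized))
    stop("hpd_interval requires a normalized density", call. = FALSE)
  ord <- order(d$mass, decreasing = TRUE)
  cum <- cumsum(d$mass[ord])
  k <- which(cum >= level)[1]
  if (is.na(k)) k <- length(ord)
  years <- sort(d$cal_bp[ord[seq_len(k)]], decreasing = TRUE)
  brk <- c(0, which(diff(years) < -1), length(years))
  out <- do.call(rbind, lapply(seq_len(length(brk) - 1L), function(i) {
    yy <- years[(brk[i] + 1L):brk[i + 1L]]
    data.frame(start = max(yy), end = min(yy),
               mass = sum(d$mass[d$cal_bp <= max(yy) & d$cal_bp >= min(yy)]))
  }))
  out[order(-out$start), , drop = FALSE]
}

#' Pool dates within sites into bins
#'
#' Dates from a single site whose radiocarbon ages lie within `h` radiocarbon
#' years of one another are pooled before aggregation, damping between-site
#' differences in sampling intensity. Pooling uses complete-linkage
#' hierarchical clustering of the raw ages cut at height `h`; bins never span
#' sites.
#'
#' @param dates A `c14_dates` table (see [read_dates()]).
#' @param h Clustering cut height in radiocarbon years, default 50.
#' @return data.frame with one row per date: `lab_id`, `site_id`, `bin_id`.
#' @export
bin_dates <- function(dates, h = 50) {
  dates <- read_dates(dates)
  out <- do.call(rbind, lapply(split(dates, dates$site_id), function(sd) {
    if (nrow(sd) == 1L) {
      cl <- 1L
    } else {
      hc <- stats::hclust(stats::dist(sd$cra), method = "complete")
      cl <- stats::cutree(hc, h = h)
    }
    data.frame(lab_id = sd$lab_id, site_id = sd$site_id[1],
               bin_id = paste0(sd$site_id[1], "_", cl),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(match(out$lab_id, dates$lab_id)), , drop = FALSE]
}

#' Summed probability distribution of calibrated dates
#'
#' Aggregates per-date calibrated densities into a regional SPD: densities
#' are averaged within bins (so heavily sampled site phases count once) and
#' the bin means are summed per calendar year over the model bounds.
#'
#' @param densities List of `cal_density` objects, one per date, in the same
#'   order as the rows of `bins`.
#' @param bins Bin assignment from [bin_dates()]; if `NULL` every date is its
#'   own bin.
#' @param bounds Numeric `c(a, b)` with `a` the older and `b` the younger
#'   bound in cal BP.
#' @param region Region label.
#' @return An object of class `spd_grid` with fields `region`, `cal_bp`
#'   (descending 1-year grid over `[a, b]`), `spd`, `n_dates`, `n_bins`.
#' @export
build_spd <- function(densities, bins = NULL, bounds, region = "region") {
  if (length(densities) == 0L) stop("no densities supplied", call. = FALSE)
  a <- max(bounds); b <- min(bounds)
  if (a <= b) stop("bounds must satisfy a > b", call. = FALSE)
  grid <- seq(a, b, by = -1)
  if (is.null(bins)) {
    bin_id <- as.character(seq_along(densities))
  } else {
    if (nrow(bins) != length(densities))
      stop("bins and densities disagree in length", call. = FALSE)
    bin_id <- bins$bin_id
  }
  on_grid <- function(d) {
    m <- numeric(length(grid))
    pos <- a - d$cal_bp + 1L  # descending grid: index of each density year
    ok <- pos >= 1L & pos <= length(grid)
    m[pos[ok]] <- d$mass[ok]
    m
  }
  spd <- numeric(length(grid))
  for (ids in split(seq_along(densities), bin_id)) {
    bin_mean <- Reduce(`+`, lapply(densities[ids], on_grid)) / length(ids)
    spd <- spd + bin_mean
  }
  structure(list(region = region, cal_bp = grid, spd = spd,
                 n_dates = length(densities),
                 n_bins = length(unique(bin_id))),
            class = "spd_grid")
}

#' @export
print.spd_grid <- function(x, ...) {
  cat("SPD '", x$region, "': ", max(x$cal_bp), "-", min(x$cal_bp),
      " cal BP, ", x$n_dates, " dates in ", x$n_bins, " bins\n", sep = "")
  invisible(x)
}

#' Back-calibrate a calendar year into a radiocarbon measurement
#'
#' Simulates the radiocarbon age a lab would report for a sample of known
#' calendar age: a Gaussian draw centred on the curve mean at that year with
#' variance equal to lab error squared plus curve error squared.
#'
#' @param cal_year Calendar year BP, within the curve span.
#' @param curve A [cal_curve()].
#' @param lab_error Reported 1-sigma lab error, years.
#' @param seed Optional integer seed for a reproducible single draw; when
#'   `NULL` the current RNG stream is used (vectorized over `cal_year`).
#' @return Numeric vector of simulated radiocarbon ages.
#' @export
sample_uncal <- function(cal_year, curve, lab_error, seed = NULL) {
  at <- curve_at(curve, cal_year)
  if (anyNA(at$c14))
    stop("cal_year outside the calibration curve span", call. = FALSE)
  sd <- sqrt(lab_error^2 + at$sigma^2)
  if (!is.null(seed)) {
    rng <- local_rng(seed)
    rng(stats::rnorm(length(cal_year), at$c14, sd))
  } else {
    stats::rnorm(length(cal_year), at$c14, sd)
  }
}
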