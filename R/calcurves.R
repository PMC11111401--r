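#' Construct a calibration curve object
#'
#' A `cal_curve` maps calendar years BP to conventional radiocarbon ages with
#' a per-year 1-sigma curve uncertainty. Curves are stored oldest-first
#' (descending cal BP).
#'
#' @param cal_bp Numeric vector of calendar years BP, strictly monotone.
#' @param c14_age Numeric vector of radiocarbon ages BP, same length.
#' @param sigma_curve Numeric vector of 1-sigma curve errors (years), same
#'   length, all non-negative.
#' @param name Label for the curve.
#' @return An object of class `cal_curve` with fields `name`, `cal_bp`,
#'   `c14_age`, `sigma_curve`.
#' @export
cal_curve <- function(cal_bp, c14_age, sigma_curve, name = "curve") {
  cal_bp <- as.numeric(cal_bp)
  c14_age <- as.numeric(c14_age)
  sigma_curve <- as.numeric(sigma_curve)
  if (length(cal_bp) < 2L)
    stop("a calibration curve needs at least two knots", call. = FALSE)
  if (length(c14_age) != length(cal_bp) || length(sigma_curve) != length(cal_bp))
    stop("cal_bp, c14_age and sigma_curve must have equal length", call. = FALSE)
  if (anyNA(cal_bp) || anyNA(c14_age) || anyNA(sigma_curve))
    stop("calibration curve columns must not contain NA", call. = FALSE)
  d <- diff(cal_bp)
  if (!(all(d > 0) || all(d < 0)))
    stop("cal_bp must be strictly monotone", call. = FALSE)
  if (any(sigma_curve < 0))
    stop("sigma_curve must be non-negative", call. = FALSE)
  if (all(d > 0)) { # store oldest-first
    cal_bp <- rev(cal_bp); c14_age <- rev(c14_age); sigma_curve <- rev(sigma_curve)
  }
  structure(
    list(name = name, cal_bp = cal_bp, c14_age = c14_age,
         sigma_curve = sigma_curve),
    class = "cal_curve"
  )
}

#' @export
print.cal_curve <- function(x, ...) {
  cat("Calibration curve '", x$name, "': ", length(x$cal_bp), " knots, ",
      max(x$cal_bp), "-", min(x$cal_bp), " cal BP\n", sep = "")
  invisible(x)
}

#' Read a calibration curve from an IntCal-style .14c file
#'
#' Parses the comma-separated dialect used by the published IntCal20/SHCal20
#' distribution files: lines starting with `#` are comments, the first three
#' columns are cal BP, 14C age BP and 1-sigma error; any further columns
#' (Delta-14C and friends) are ignored.
#'
#' @param path Path to the file.
#' @param name Curve label; defaults to the file name.
#' @return A [cal_curve()].
#' @export
load_curve <- function(path, name = NULL) {
  if (!file.exists(path))
    stop("calibration curve file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  data_lines <- lines[keep]
  line_no <- seq_along(lines)[keep]
  if (length(data_lines) < 2L)
    stop("calibration curve file has fewer than two data rows: ", path,
         call. = FALSE)
  parse_row <- function(ln, no) {
    parts <- trimws(strsplit(ln, ",")[[1]])
    if (length(parts) < 3L)
      stop("malformed calibration curve row at line ", no, ": ", ln,
           call. = FALSE)
    vals <- suppressWarnings(as.numeric(parts[1:3]))
    if (anyNA(vals))
      stop("malformed calibration curve row at line ", no, ": ", ln,
           call. = FALSE)
    vals
  }
  m <- t(mapply(parse_row, data_lines, line_no))
  cal_curve(m[, 1], m[, 2], m[, 3],
            name = if (is.null(name)) basename(path) else name)
}

#' Interpolate a calibration curve onto a 1-year grid
#'
#' Linear interpolation of both the mean radiocarbon age and the curve error
#' onto an integer 1 calendar-year grid spanning the input range, oldest
#' first. Idempotent on curves already on that grid.
#'
#' @param curve A [cal_curve()].
#' @return A [cal_curve()] on a 1-year grid.
#' @export
interpolate_curve <- function(curve) {
  stopifnot(inherits(curve, "cal_curve"))
  grid <- seq(ceiling(max(curve$cal_bp)), floor(min(curve$cal_bp)), by = -1)
  c14 <- stats::approx(curve$cal_bp, curve$c14_age, xout = grid)$y
  sig <- stats::approx(curve$cal_bp, curve$sigma_curve, xout = grid)$y
  cal_curve(grid, c14, sig, name = curve$name)
}

#' Synthesize a calibration curve for testing and simulation
#'
#' Builds a curve c14(t) = t + A * sin(2 * pi * t / P) over a span of calendar
#' years with constant curve error. With `wiggle_amplitude = 0` this is the
#' identity curve, under which a measurement's calibrated mode falls at its
#' radiocarbon age. The construction is deterministic; `seed` is reserved for
#' optional knot noise.
#'
#' @param old_bp,young_bp Span of the curve in cal BP (`old_bp > young_bp`).
#' @param wiggle_amplitude Amplitude of the sinusoidal wiggle, years.
#' @param wiggle_period Period of the wiggle, years; must be positive when the
#'   amplitude is non-zero.
#' @param sigma Constant 1-sigma curve error, years.
#' @param noise_sd Optional Gaussian knot noise s.d.; 0 for none.
#' @param seed Integer seed used only when `noise_sd > 0`.
#' @return A [cal_curve()] on a 1-year grid.
#' @export
synth_curve <- function(old_bp, young_bp, wiggle_amplitude = 0,
                        wiggle_period = 500, sigma = 0, noise_sd = 0,
                        seed = 1L) {
  if (old_bp <= young_bp)
    stop("old_bp must exceed young_bp", call. = FALSE)
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  if (wiggle_amplitude != 0 && wiggle_period <= 0)
    stop("wiggle_period must be positive when wiggle_amplitude is non-zero",
         call. = FALSE)
  grid <- seq(old_bp, young_bp, by = -1)
  c14 <- grid
  if (wiggle_amplitude != 0)
    c14 <- c14 + wiggle_amplitude * sin(2 * pi * grid / wiggle_period)
  if (noise_sd > 0) {
    rng <- local_rng(seed)
    c14 <- c14 + rng(stats::rnorm(length(grid), 0, noise_sd))
  }
  cal_curve(grid, c14, rep(sigma, length(grid)), name = "synthetic")
}

# Evaluate curve mean / error at arbitrary cal BP (curve assumed 1-year grid,
# but approx handles any monotone knot set).
curve_at <- function(curve, cal_bp) {
  list(
    c14 = stats::approx(curve$cal_bp, curve$c14_age, xout = cal_bp,
                        rule = 1)$y,
    sigma = stats::approx(curve$cal_bp, curve$sigma_curve, xout = cal_bp,
                          rule = 1)$y
  )
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. Returns a function applied to its argument so the
# seeding wraps exactly one draw site.
local_rng <- function(seed) {
  function(expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
  }
}
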