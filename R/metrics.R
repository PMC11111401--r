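#' Resistance of a population downturn
#'
#' Depth of a downturn relative to baseline conditions:
#' `1 - 2|b - x| / (|b| + |b - x|)`, ranging from 1 (no change from
#' baseline) to 0 (total collapse).
#'
#' @param b Baseline SPD value at the start of the downturn (> 0).
#' @param x Minimum SPD value during the downturn (>= 0).
#' @return Resistance in `[0, 1]` (vectorized).
#' @export
resistance <- function(b, x) {
  if (any(b <= 0)) stop("baseline b must be positive", call. = FALSE)
  if (any(x < 0)) stop("minimum x must be non-negative", call. = FALSE)
  1 - 2 * abs(b - x) / (abs(b) + abs(b - x))
}

#' Resilience of a population downturn
#'
#' Rate of recovery to baseline conditions by the end of the downturn,
#' controlling for its maximum impact:
#' `2|b - x| / (|b - x| + |b - e|) - 1`. A value of 1 indicates full
#' recovery (`e = b`), 0 no recovery (`e = x`), and negative values that the
#' baseline was exceeded by the downturn's end. Undefined when `x = b` (no
#' drop occurred): returns `NA` with a warning so such rows can be flagged
#' and excluded from modelling.
#'
#' @param b Baseline SPD value (> 0).
#' @param x Minimum SPD value (`x < b` for a well-defined value).
#' @param e SPD value at the end of the downturn.
#' @return Resilience in `[-1, 1]` (vectorized), `NA` where `x = b`.
#' @export
resilience <- function(b, x, e) {
  if (any(b <= 0)) stop("baseline b must be positive", call. = FALSE)
  out <- 2 * abs(b - x) / (abs(b - x) + abs(b - e)) - 1
  und <- x == b
  if (any(und)) {
    warning("resilience undefined where x = b (no drop); returning NA",
            call. = FALSE)
    out[und] <- NA_real_
  }
  out
}

#' Relative pace of a downturn
#'
#' Time to the SPD minimum normalized by the downturn duration; higher
#' values reflect slower declines.
#'
#' @param time_to_min Years from downturn start to SPD minimum.
#' @param duration Downturn duration in years (> 0).
#' @return Pace in `[0, 1]` (vectorized).
#' @export
pace <- function(time_to_min, duration) {
  if (any(duration <= 0)) stop("duration must be positive", call. = FALSE)
  if (any(time_to_min < 0 | time_to_min > duration))
    stop("time_to_min must lie within [0, duration]", call. = FALSE)
  time_to_min / duration
}

#' Per-downturn frequency of downturns within a region
#'
#' The frequency of downturns is computed on a per-downturn basis: the k-th
#' downturn (counting oldest first) has frequency `k / elapsed * 1000`
#' events per millennium, where `elapsed` is the calendar time from the
#' start of the regional record to that downturn's end.
#'
#' @param downturns A `downturn_table` for one region, ordered oldest first.
#' @param region_start Calendar year BP of the start of the regional record;
#'   must be older than every downturn.
#' @return The input with columns `n_downturn`, `frequency` (events per
#'   millennium) and `log_frequency` (natural log) appended.
#' @export
downturn_frequency <- function(downturns, region_start) {
  if (nrow(downturns) == 0L) {
    downturns$n_downturn <- integer(0)
    downturns$frequency <- numeric(0)
    downturns$log_frequency <- numeric(0)
    return(downturns)
  }
  downturns <- downturns[order(-downturns$T_start), , drop = FALSE]
  if (region_start <= max(downturns$T_start))
    stop("region_start must be older than every downturn", call. = FALSE)
  k <- seq_len(nrow(downturns))
  elapsed <- region_start - downturns$T_end
  if (any(elapsed <= 0)) stop("zero elapsed record time", call. = FALSE)
  downturns$n_downturn <- k
  downturns$frequency <- k / elapsed * 1000
  downturns$log_frequency <- log(downturns$frequency)
  rownames(downturns) <- NULL
  downturns
}

#' Assemble the cross-regional study table
#'
#' Joins detected downturns (with their metrics) to the per-downturn
#' annotation table recording the disturbance category and type, dominant
#' land use and evidence of adaptive change. Annotations are matched on
#' region plus downturn start year within `tolerance`.
#'
#' @param downturns A `downturn_table` spanning one or more regions, with
#'   frequency columns from [downturn_frequency()].
#' @param annotations data.frame (or CSV path) with columns `region`,
#'   `T_start`, `category`, `dist_type`, `land_use`, `change`.
#' @param tolerance Match tolerance on `T_start` in years, default 10.
#' @return data.frame of class `study_table`: all downturn and metric
#'   columns (`resistance`, `resilience`, `pace`), annotations, and a
#'   `resilience_defined` flag.
#' @export
assemble_table <- function(downturns, annotations, tolerance = 10) {
  if (is.character(annotations))
    annotations <- utils::read.csv(annotations, stringsAsFactors = FALSE)
  need <- c("region", "T_start", "category", "dist_type", "land_use",
            "change")
  miss <- setdiff(need, names(annotations))
  if (length(miss))
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  dt <- as.data.frame(downturns)
  ann_idx <- vapply(seq_len(nrow(dt)), function(i) {
    cand <- which(annotations$region == dt$region[i] &
                    abs(annotations$T_start - dt$T_start[i]) <= tolerance)
    if (length(cand) == 0L)
      stop("no annotation for downturn in region '", dt$region[i],
           "' starting ", dt$T_start[i], " cal BP", call. = FALSE)
    cand[which.min(abs(annotations$T_start[cand] - dt$T_start[i]))]
  }, integer(1))
  dt$resistance <- resistance(dt$b, dt$x)
  dt$resilience <- suppressWarnings(resilience(dt$b, dt$x, dt$e))
  dt$resilience_defined <- !is.na(dt$resilience)
  dt$pace <- pace(dt$time_to_min, dt$duration)
  dt$category <- annotations$category[ann_idx]
  dt$dist_type <- annotations$dist_type[ann_idx]
  dt$land_use <- annotations$land_use[ann_idx]
  dt$change <- annotations$change[ann_idx]
  dt <- dt[order(dt$region, -dt$T_start), , drop = FALSE]
  rownames(dt) <- NULL
  class(dt) <- c("study_table", "data.frame")
  dt
}
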