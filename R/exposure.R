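#' Piecewise-constant exposure schedule
#'
#' Represents a water-renewal exposure regime: dissolved metal concentration
#' is held constant within each renewal interval and jumps at renewal times.
#' Interval `j` spans `[times[j], times[j + 1])` (half-open: an evaluation
#' exactly at a renewal time belongs to the interval that starts there); the
#' final interval ends at `horizon`.
#'
#' @param times Renewal times in days, strictly increasing; `times[1]` is the
#'   start of the exposure.
#' @param conc Dissolved concentration (ug/L) for each interval, same length
#'   as `times`, all nonnegative.
#' @param horizon Total duration end time (days), greater than the last
#'   renewal time. Defaults to extending the last interval by the median
#'   interval length (or 1 day for a single interval).
#' @return An object of class `exposure_schedule` with fields `times`,
#'   `conc`, `horizon`.
#' @export
#' @examples
#' sched <- exposure_schedule(times = seq(0, 33, by = 3),
#'                            conc = rep(80, 12), horizon = 36)
#' sched
exposure_schedule <- function(times, conc, horizon = NULL) {
  times <- as.numeric(times)
  conc <- as.numeric(conc)
  if (length(times) < 1L) stop("need at least one renewal time")
  if (any(!is.finite(times)) || any(!is.finite(conc)))
    stop("times and concentrations must be finite")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("renewal times must be strictly increasing")
  if (length(conc) != length(times))
    stop("need exactly one concentration per interval (lengths ",
         length(conc), " vs ", length(times), ")")
  if (any(conc < 0)) stop("concentrations must be nonnegative")
  if (is.null(horizon)) {
    step <- if (length(times) > 1L) stats::median(diff(times)) else 1
    horizon <- times[length(times)] + step
  }
  if (horizon <= times[length(times)])
    stop("horizon must exceed the last renewal time")
  structure(list(times = times, conc = conc, horizon = as.numeric(horizon)),
            class = "exposure_schedule")
}

#' @export
print.exposure_schedule <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("Exposure schedule: %d interval%s over [%g, %g] d\n",
              n, if (n == 1) "" else "s", x$times[1], x$horizon))
  cat(sprintf("  concentrations (ug/L): %s\n",
              paste(signif(x$conc, 4), collapse = ", ")))
  invisible(x)
}

#' @export
format.exposure_schedule <- function(x, ...) {
  sprintf("<exposure_schedule: %d intervals, [%g, %g] d>",
          length(x$times), x$times[1], x$horizon)
}

# index of the interval containing each time (half-open [T_j, T_{j+1}));
# t == horizon is assigned to the last interval so the endpoint is usable
.interval_index <- function(schedule, t) {
  if (any(t < schedule$times[1] - 1e-12) || any(t > schedule$horizon + 1e-12))
    stop("evaluation time outside the exposure horizon [",
         schedule$times[1], ", ", schedule$horizon, "]")
  idx <- findInterval(t, schedule$times)
  pmin(pmax(idx, 1L), length(schedule$times))
}

#' Refine an exposure schedule
#'
#' Splits every interval into `factor` equal sub-intervals carrying the same
#' concentration. The forcing function is unchanged, but solvers that sample
#' a coupled compartment once per interval (the parasite forcing of
#' [simulate_infected()]) become more accurate on the refined grid.
#'
#' @param schedule An [exposure_schedule()].
#' @param factor Integer number of sub-intervals per interval (>= 1).
#' @return A refined `exposure_schedule`.
#' @export
refine_schedule <- function(schedule, factor) {
  stopifnot(inherits(schedule, "exposure_schedule"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be a positive integer")
  if (factor == 1L) return(schedule)
  bounds <- c(schedule$times, schedule$horizon)
  new_times <- unlist(lapply(seq_along(schedule$times), function(j) {
    seq(bounds[j], bounds[j + 1], length.out = factor + 1L)[-(factor + 1L)]
  }))
  new_conc <- rep(schedule$conc, each = factor)
  exposure_schedule(new_times, new_conc, horizon = schedule$horizon)
}

#' Read an exposure schedule from CSV
#'
#' Expects columns `time_d` and at least one of `cw_before_ugL` (dissolved
#' concentration measured just before the renewal at `time_d`, i.e. at the
#' end of the preceding interval) and `cw_after_ugL` (measured just after
#' renewal, i.e. at the start of the interval beginning at `time_d`). A
#' trailing row holding only `cw_before_ugL` marks the horizon.
#'
#' When both columns are present, the per-interval concentration defaults to
#' the arithmetic mean of the post-renewal value at the interval start and
#' the pre-renewal value at the next renewal (`forcing = "mean"`);
#' `forcing = "post"` uses the post-renewal value alone.
#'
#' @param path CSV file path.
#' @param forcing Interval-concentration convention, `"mean"` or `"post"`.
#' @param horizon Optional horizon override (days).
#' @return An [exposure_schedule()].
#' @export
read_exposure_csv <- function(path, forcing = c("mean", "post"),
                              horizon = NULL) {
  forcing <- match.arg(forcing)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time_d" %in% names(df))
    stop("schema error in ", path, ": missing column 'time_d'")
  has_before <- "cw_before_ugL" %in% names(df)
  has_after <- "cw_after_ugL" %in% names(df)
  if (!has_before && !has_after)
    stop("schema error in ", path,
         ": need 'cw_before_ugL' and/or 'cw_after_ugL'")
  df <- df[order(df$time_d), , drop = FALSE]
  after <- if (has_after) df$cw_after_ugL else rep(NA_real_, nrow(df))
  before <- if (has_before) df$cw_before_ugL else rep(NA_real_, nrow(df))

  # a trailing boundary row (no post-renewal value) closes the last interval
  n <- nrow(df)
  terminal <- is.na(after[n]) && !is.na(before[n])
  starts <- if (terminal) df$time_d[-n] else df$time_d
  if (terminal && is.null(horizon)) horizon <- df$time_d[n]

  m <- length(starts)
  a <- after[seq_len(m)]
  b_next <- before[seq_len(m) + 1L]   # pre-renewal value at the next boundary
  cw <- switch(forcing,
    post = ifelse(is.na(a), b_next, a),
    mean = rowMeans(cbind(a, b_next), na.rm = TRUE)
  )
  if (any(is.na(cw)))
    stop("schema error in ", path, ": interval(s) ",
         paste(which(is.na(cw)), collapse = ", "),
         " have no usable concentration")
  exposure_schedule(starts, cw, horizon = horizon)
}

#' Write an exposure schedule to CSV
#'
#' @param schedule An [exposure_schedule()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_exposure_csv <- function(schedule, path) {
  stopifnot(inherits(schedule, "exposure_schedule"))
  df <- data.frame(time_d = c(schedule$times, schedule$horizon),
                   cw_after_ugL = c(schedule$conc, NA_real_),
                   cw_before_ugL = c(NA_real_, schedule$conc))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
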