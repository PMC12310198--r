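#' Rolling-window reorientation rate of one worm
#'
#' At each grid time `t` the rate is the number of events in the centred
#' window `[max(0, t - w/2), min(T, t + w/2))` divided by the *effective*
#' window length, so curves do not dip artificially at the recording
#' boundaries.
#'
#' @param x A `worm_trajectory`, or a numeric vector of event times (min).
#' @param window Window width `w` in minutes (default 2, the conventional
#'   smoothing for these recordings).
#' @param grid_step Spacing of the evaluation grid (min).
#' @param total_duration Recording length `T` (min); taken from the
#'   trajectory when available.
#' @return A `rate_curve`: data.frame with columns `time_min`, `rate`
#'   (events/min) and attribute `n_worms = 1`.
#' @examples
#' rolling_rate(c(10, 10.5, 11), total_duration = 45)
#' @export
rolling_rate <- function(x, window = 2, grid_step = 0.5,
                         total_duration = NULL) {
  stopifnot(window > 0, grid_step > 0)
  times <- if (inherits(x, "worm_trajectory")) x$event_times else as.numeric(x)
  if (is.null(total_duration)) {
    if (inherits(x, "worm_trajectory")) total_duration <- x$duration
    else stop("total_duration is required when x is a plain event vector")
  }
  grid <- time_grid(total_duration, grid_step)
  rate <- count_in_windows(times, grid, window, total_duration)
  new_rate_curve(grid, rate, n_worms = 1L)
}

#' Population mean and SD rate curve
#'
#' Pointwise mean and standard deviation across per-worm rolling-rate curves
#' evaluated on a shared grid.
#'
#' @param pop A `worm_population`, or a list of `worm_trajectory` objects.
#' @inheritParams rolling_rate
#' @return A `rate_curve` with columns `time_min`, `rate` (population mean),
#'   `sd` and attribute `n_worms`.
#' @examples
#' pop <- simulate_population(sim_params(n_worms = 20, seed = 2))
#' rc <- population_rate(pop)
#' head(as.data.frame(rc))
#' @export
population_rate <- function(pop, window = 2, grid_step = 0.5,
                            total_duration = NULL) {
  stopifnot(length(pop) >= 1L)
  if (is.null(total_duration)) {
    p <- attr(pop, "params")
    total_duration <- if (!is.null(p)) p$duration else pop[[1L]]$duration
  }
  grid <- time_grid(total_duration, grid_step)
  mat <- vapply(pop, function(tr) {
    times <- if (inherits(tr, "worm_trajectory")) tr$event_times
             else as.numeric(tr)
    count_in_windows(times, grid, window, total_duration)
  }, numeric(length(grid)))
  mat <- matrix(mat, nrow = length(grid))
  new_rate_curve(grid, rowMeans(mat),
                 sd = apply(mat, 1L, sd),
                 n_worms = length(pop))
}

# Events per minute in centred windows truncated at [0, total_duration).
# Window is half-open on the right: events with lo <= e < hi count.
count_in_windows <- function(times, grid, window, total_duration) {
  lo <- pmax(0, grid - window / 2)
  hi <- pmin(total_duration, grid + window / 2)
  if (length(times) == 0L) return(numeric(length(grid)))
  times <- sort(times)
  # findInterval(v, times) = #{e <= v}; left.open gives #{e < v}
  n_lt_hi <- findInterval(hi, times, left.open = TRUE)
  n_lt_lo <- findInterval(lo, times, left.open = TRUE)
  (n_lt_hi - n_lt_lo) / (hi - lo)
}

time_grid <- function(total_duration, grid_step) {
  grid <- seq(0, total_duration, by = grid_step)
  if (tail(grid, 1L) < total_duration) grid <- c(grid, total_duration)
  grid
}

new_rate_curve <- function(time_min, rate, sd = NULL, n_worms = 1L) {
  df <- data.frame(time_min = time_min, rate = rate)
  if (!is.null(sd)) df$sd <- sd
  structure(df, class = c("rate_curve", "data.frame"), n_worms = n_worms)
}

#' @export
print.rate_curve <- function(x, ...) {
  cat(sprintf("Rate curve: %d grid points over [%g, %g] min, %d worm(s)\n",
              nrow(x), min(x$time_min), max(x$time_min),
              attr(x, "n_worms")))
  cat(sprintf("  rate range [%.3f, %.3f] events/min\n",
              min(x$rate), max(x$rate)))
  invisible(x)
}

#' @export
plot.rate_curve <- function(x, ...) {
  plot(x$time_min, x$rate, type = "l", xlab = "time (min)",
       ylab = "reorientation rate (events/min)", ...)
  if (!is.null(x$sd)) {
    matlines(x$time_min, cbind(x$rate - x$sd, x$rate + x$sd),
             lty = 2, col = "grey50")
  }
  invisible(x)
}
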