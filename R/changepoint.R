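#' Cumulative reorientation curve on a uniform grid
#'
#' `omega(t)` = number of events at or before `t` (closed right boundary),
#' evaluated on a uniform grid from 0 to `total_duration`.
#'
#' @param x A `worm_trajectory` or numeric vector of event times (min).
#' @param grid_step Grid spacing (min).
#' @param total_duration Recording length (min); taken from the trajectory
#'   when available.
#' @return A `cumulative_curve`: data.frame with columns `time_min`, `omega`.
#' @examples
#' cumulative_curve(c(1, 2, 3), grid_step = 1, total_duration = 4)
#' @export
cumulative_curve <- function(x, grid_step = 0.5, total_duration = NULL) {
  stopifnot(grid_step > 0)
  times <- if (inherits(x, "worm_trajectory")) x$event_times else as.numeric(x)
  if (is.null(total_duration)) {
    if (inherits(x, "worm_trajectory")) total_duration <- x$duration
    else stop("total_duration is required when x is a plain event vector")
  }
  grid <- time_grid(total_duration, grid_step)
  omega <- if (length(times) == 0L) numeric(length(grid))
           else findInterval(grid, sort(times))  # counts e <= t
  structure(data.frame(time_min = grid, omega = omega),
            class = c("cumulative_curve", "data.frame"))
}

#' Two-segment linear-regression changepoint fit
#'
#' Splits a cumulative reorientation curve into two regions and fits an
#' independent ordinary-least-squares line to each; the split is chosen by
#' exhaustive search to minimise the summed residual squared error of the two
#' regressions (the analysis performed by MATLAB's `findchangepts` with two
#' linear segments).  The first segment covers grid points strictly before
#' the split, the second the split point onwards.  The transition time is the
#' intersection of the two unconstrained lines,
#' `t_trans = (b2 - b1) / (s1 - s2)`; when the slopes are exactly equal the
#' intersection is undefined and `t_trans` falls back to the split's grid
#' time with `degenerate = TRUE`.
#'
#' A large slope difference `s1 - s2` reads as an abrupt drop in
#' reorientation rate -- the signature previously interpreted as a discrete
#' local-to-global search decision.
#'
#' @param curve A `cumulative_curve`, or a data.frame with columns `time_min`
#'   and `omega`.
#' @param min_seg Minimum time span (min) each segment must cover; keeps both
#'   regressions well-posed.  Each segment always gets at least 2 points.
#' @return An object of class `changepoint_fit`: `s1`, `s2`, `slope_diff`,
#'   `t_trans`, `split_index`, `split_time`, `b1`, `b2`, `rss_total`,
#'   `degenerate`, plus the input `data`.
#' @examples
#' cv <- make_piecewise_fixture(s1 = 2, s2 = 0.5, t_break = 20)
#' two_segment_fit(cv)
#' @export
two_segment_fit <- function(curve, min_seg = 2) {
  df <- as.data.frame(curve)
  stopifnot(all(c("time_min", "omega") %in% names(df)), min_seg >= 0)
  x <- df$time_min
  y <- df$omega
  n <- length(x)
  ks <- admissible_splits(x, min_seg)
  if (length(ks) == 0L) {
    stop("curve too short for two segments of span >= min_seg")
  }
  # Independent OLS on [1, k) and [k, n] for every admissible k, via prefix
  # sums (O(n) overall); slopes/intercepts/RSS in closed form.
  cx <- cumsum(x); cy <- cumsum(y)
  cxx <- cumsum(x * x); cxy <- cumsum(x * y); cyy <- cumsum(y * y)
  seg_stats <- function(i, j) {  # vectorised over equal-length i, j
    m <- j - i + 1
    sx <- cx[j] - ifelse(i > 1, cx[i - 1], 0)
    sy <- cy[j] - ifelse(i > 1, cy[i - 1], 0)
    sxx <- cxx[j] - ifelse(i > 1, cxx[i - 1], 0)
    sxy <- cxy[j] - ifelse(i > 1, cxy[i - 1], 0)
    syy <- cyy[j] - ifelse(i > 1, cyy[i - 1], 0)
    vx <- sxx - sx * sx / m
    cvxy <- sxy - sx * sy / m
    vy <- syy - sy * sy / m
    slope <- cvxy / vx
    list(slope = slope, intercept = (sy - slope * sx) / m,
         rss = pmax(vy - slope * cvxy, 0))
  }
  one <- rep.int(1L, length(ks))
  left <- seg_stats(one, ks - 1L)
  right <- seg_stats(ks, rep.int(n, length(ks)))
  rss <- left$rss + right$rss
  best <- which.min(rss)  # first minimum on ties
  k <- ks[best]
  s1 <- left$slope[best];  b1 <- left$intercept[best]
  s2 <- right$slope[best]; b2 <- right$intercept[best]
  degenerate <- (s1 == s2)
  t_trans <- if (degenerate) x[k] else (b2 - b1) / (s1 - s2)
  structure(
    list(s1 = s1, s2 = s2, slope_diff = s1 - s2, t_trans = t_trans,
         split_index = k, split_time = x[k], b1 = b1, b2 = b2,
         rss_total = rss[best], degenerate = degenerate, data = df),
    class = "changepoint_fit")
}

# Admissible split indices k: segment 1 = points 1..k-1, segment 2 = k..n;
# each side spans >= min_seg minutes and holds >= 2 points.
admissible_splits <- function(x, min_seg) {
  n <- length(x)
  k <- seq_len(n)
  ok <- k >= 3L & k <= n - 1L &
    (x[pmax(k - 1L, 1L)] - x[1L]) >= min_seg &
    (x[n] - x) >= min_seg
  k[ok]
}

#' @export
print.changepoint_fit <- function(x, ...) {
  cat("Two-segment changepoint fit\n")
  cat(sprintf("  s1 = %.4f, s2 = %.4f events/min (slope diff %.4f)\n",
              x$s1, x$s2, x$slope_diff))
  cat(sprintf("  transition time = %.3f min (split at grid t = %g)%s\n",
              x$t_trans, x$split_time,
              if (x$degenerate) " [degenerate: equal slopes]" else ""))
  cat(sprintf("  total RSS = %.4g\n", x$rss_total))
  invisible(x)
}

#' @export
coef.changepoint_fit <- function(object, ...) {
  c(s1 = object$s1, b1 = object$b1, s2 = object$s2, b2 = object$b2)
}

#' @export
plot.changepoint_fit <- function(x, ...) {
  df <- x$data
  plot(df$time_min, df$omega, type = "s", xlab = "time (min)",
       ylab = "cumulative reorientations", ...)
  k <- x$split_index
  lines(df$time_min[1:(k - 1)], x$b1 + x$s1 * df$time_min[1:(k - 1)],
        col = "red", lwd = 2)
  lines(df$time_min[k:nrow(df)], x$b2 + x$s2 * df$time_min[k:nrow(df)],
        col = "blue", lwd = 2)
  abline(v = x$t_trans, lty = 2)
  invisible(x)
}

#' Changepoint analysis of a whole population
#'
#' Runs [cumulative_curve()] + [two_segment_fit()] on every worm and collects
#' the per-worm slope differences and transition times.  Degenerate fits
#' (exactly equal slopes) are retained and flagged.
#'
#' @param pop A `worm_population` or list of `worm_trajectory` objects.
#' @inheritParams cumulative_curve
#' @inheritParams two_segment_fit
#' @return A data.frame of class `changepoint_set` with columns `worm_id`,
#'   `s1`, `s2`, `slope_diff`, `t_trans`, `rss_total`, `degenerate` -- one
#'   row per worm, in input order.
#' @examples
#' pop <- simulate_population(sim_params(n_worms = 5, seed = 11))
#' population_changepoints(pop)
#' @export
population_changepoints <- function(pop, grid_step = 0.5, min_seg = 2,
                                    total_duration = NULL) {
  stopifnot(length(pop) >= 1L)
  if (is.null(total_duration)) {
    p <- attr(pop, "params")
    total_duration <- if (!is.null(p)) p$duration else pop[[1L]]$duration
  }
  rows <- lapply(seq_along(pop), function(i) {
    tr <- pop[[i]]
    cv <- cumulative_curve(tr, grid_step = grid_step,
                           total_duration = total_duration)
    f <- two_segment_fit(cv, min_seg = min_seg)
    id <- if (inherits(tr, "worm_trajectory")) tr$worm_id else i
    data.frame(worm_id = id, s1 = f$s1, s2 = f$s2,
               slope_diff = f$slope_diff, t_trans = f$t_trans,
               rss_total = f$rss_total, degenerate = f$degenerate)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("changepoint_set", "data.frame")
  out
}
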