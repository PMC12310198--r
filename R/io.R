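#' Write / read reorientation event streams
#'
#' The event CSV dialect is comma-separated UTF-8 with a mandatory header
#' `worm_id,event_time_min`, one row per reorientation, times in decimal
#' minutes.
#'
#' @param pop A `worm_population`, or a data.frame with columns `worm_id`,
#'   `event_time_min`.
#' @param path Output file path.
#' @return `write_events()` returns `path` invisibly.
#' @export
write_events <- function(pop, path) {
  df <- if (is.data.frame(pop)) pop else as.data.frame(pop)
  stopifnot(all(c("worm_id", "event_time_min") %in% names(df)))
  write.csv(format_events(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# >= 6 significant digits so event times keep sub-second resolution
format_events <- function(df) {
  df$event_time_min <- formatC(df$event_time_min, digits = 9,
                               format = "g")
  df
}

#' @rdname write_events
#' @param validate Check structure (header, numeric non-negative times,
#'   per-worm strictly increasing order)?  Violations raise an error naming
#'   the first offending row.
#' @return `read_events()` returns a data.frame with columns `worm_id`,
#'   `event_time_min`.
#' @export
read_events <- function(path, validate = TRUE) {
  df <- read.csv(path)
  if (!all(c("worm_id", "event_time_min") %in% names(df))) {
    stop("event CSV must have header 'worm_id,event_time_min': ", path)
  }
  if (validate) validate_events(df)
  df
}

validate_events <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  t <- suppressWarnings(as.numeric(df$event_time_min))
  if (anyNA(t)) {
    stop("non-numeric event time at row ", which(is.na(t))[1L])
  }
  if (any(t < 0)) stop("negative event time at row ", which(t < 0)[1L])
  for (id in unique(df$worm_id)) {
    tt <- t[df$worm_id == id]
    bad <- which(diff(tt) <= 0)
    if (length(bad) > 0L) {
      row <- which(df$worm_id == id)[bad[1L] + 1L]
      stop("non-increasing event times for worm ", id, " at row ", row)
    }
  }
  invisible(df)
}

#' Rebuild a population object from an event table
#'
#' Inverse of `as.data.frame()` on a `worm_population` (up to the `M` paths,
#' which an event stream does not carry): groups events by worm and wraps
#' them as trajectories so that all analysis functions apply to data read
#' from CSV.
#'
#' @param df Data.frame with columns `worm_id`, `event_time_min` (or a path
#'   to such a CSV).
#' @param duration Recording length in minutes.
#' @param worm_ids Optional vector of worm ids to include (default: all ids
#'   present, in order of first appearance); lets callers keep worms that
#'   produced zero events.
#' @return A `worm_population`.
#' @export
events_to_population <- function(df, duration, worm_ids = NULL) {
  if (is.character(df)) df <- read_events(df)
  stopifnot(duration > 0)
  if (is.null(worm_ids)) worm_ids <- unique(df$worm_id)
  trajs <- lapply(worm_ids, function(id) {
    ev <- sort(df$event_time_min[df$worm_id == id])
    new_trajectory(id, ev, data.frame(time_min = 0, M = NA_integer_),
                   NA_integer_, duration)
  })
  structure(trajs, class = "worm_population", params = NULL,
            duration = duration)
}

#' Write / read a population rate curve as CSV
#'
#' Columns: `time_min,mean_rate,sd_rate,n`.
#'
#' @param curve A `rate_curve`.
#' @param path File path.
#' @export
write_rate_curve <- function(curve, path) {
  df <- data.frame(time_min = curve$time_min, mean_rate = curve$rate,
                   sd_rate = if (is.null(curve$sd)) NA_real_ else curve$sd,
                   n = attr(curve, "n_worms"))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_rate_curve
#' @export
read_rate_curve <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("time_min", "mean_rate") %in% names(df)))
  new_rate_curve(df$time_min, df$mean_rate,
                 sd = if ("sd_rate" %in% names(df)) df$sd_rate else NULL,
                 n_worms = if ("n" %in% names(df)) df$n[1L] else 1L)
}

#' Write / read per-worm changepoint results as CSV
#'
#' Columns: `worm_id,s1,s2,slope_diff,t_trans,rss_total,degenerate`.
#'
#' @param cps A `changepoint_set` data.frame.
#' @param path File path.
#' @export
write_changepoints <- function(cps, path) {
  write.csv(cps, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_changepoints
#' @export
read_changepoints <- function(path) {
  df <- read.csv(path)
  need <- c("worm_id", "s1", "s2", "slope_diff", "t_trans")
  if (!all(need %in% names(df))) {
    stop("changepoint CSV must contain columns: ",
         paste(need, collapse = ", "))
  }
  class(df) <- c("changepoint_set", "data.frame")
  df
}

#' Write a decay fit as JSON
#'
#' @param fit A `decay_fit`.
#' @param path File path.
#' @export
write_decay_fit <- function(fit, path) {
  cf <- coef(fit)
  jsonlite::write_json(
    list(alpha = unname(cf["alpha"]), beta = unname(cf["beta"]),
         gamma = unname(cf["gamma"]), rss = fit$rss,
         converged = fit$converged),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Manifest with provenance: fully-resolved config, seed, package version and
# a content hash of the config.
write_manifest <- function(path, manifest) {
  manifest$config_hash <- config_hash(manifest)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

config_hash <- function(x) {
  x$config_hash <- NULL
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  # small stable polynomial checksum; avoids a digest dependency
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
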