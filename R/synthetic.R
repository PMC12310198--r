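#' Model of the initial reorientation-rate distribution
#'
#' Observed populations start at heterogeneous reorientation rates with a
#' mean near 1.5 events/min; simulations emulate this by drawing each worm's
#' target initial rate from a chosen family and converting it to an initial
#' `M` with [assign_initial_m()].  The default is a gamma distribution with
#' mean 1.5 events/min and SD 0.75 events/min (shape 4), a broad
#' right-skewed spread; a truncated normal and resampling from an empirical
#' rate vector (or CSV) are also available.
#'
#' @param mean_rate Mean initial rate (events/min).
#' @param sd Standard deviation of the family (events/min).  `sd = 0`
#'   degenerates to a point mass at `mean_rate`.
#' @param family `"gamma"`, `"truncated_normal"` (normal truncated at
#'   `floor`), or `"empirical"` (resample `rates` with replacement).
#' @param floor Minimum admissible rate (events/min); draws are clamped here.
#' @param rates For the empirical family: numeric vector of observed initial
#'   rates, or path to a CSV with a `rate0` column.
#' @return An object of class `initial_rate_model`.
#' @examples
#' m <- initial_rate_model()
#' mean(sample_initial_rates(m, 1000, seed = 1))
#' @export
initial_rate_model <- function(mean_rate = 1.5, sd = 0.75,
                               family = c("gamma", "truncated_normal",
                                          "empirical"),
                               floor = 0, rates = NULL) {
  family <- match.arg(family)
  stopifnot(mean_rate > 0, sd >= 0, floor >= 0)
  if (family == "empirical") {
    if (is.character(rates)) {
      df <- read.csv(rates)
      if (!"rate0" %in% names(df)) stop("empirical rate CSV needs a 'rate0' column")
      rates <- df$rate0
    }
    stopifnot(is.numeric(rates), length(rates) >= 1L, all(rates >= 0))
  }
  structure(list(mean_rate = mean_rate, sd = sd, family = family,
                 floor = floor, rates = rates),
            class = "initial_rate_model")
}

#' Draw initial reorientation rates
#'
#' `n` i.i.d. draws from an [initial_rate_model()], reproducible by seed.
#'
#' @param model An `initial_rate_model`.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return Numeric vector of length `n`, all values `>= model$floor`.
#' @export
sample_initial_rates <- function(model, n, seed = 1L) {
  stopifnot(inherits(model, "initial_rate_model"), n >= 1L)
  with_preserved_rng({
    set.seed(seed)
    r <- switch(model$family,
      gamma = {
        if (model$sd == 0) rep.int(model$mean_rate, n)
        else {
          shape <- (model$mean_rate / model$sd)^2
          rgamma(n, shape = shape, rate = shape / model$mean_rate)
        }
      },
      truncated_normal = {
        if (model$sd == 0) rep.int(model$mean_rate, n)
        else {
          # inverse-CDF sampling of N(mean, sd) truncated below at floor
          plo <- pnorm(model$floor, model$mean_rate, model$sd)
          u <- runif(n, plo, 1)
          qnorm(u, model$mean_rate, model$sd)
        }
      },
      empirical = model$rates[sample.int(length(model$rates), n,
                                         replace = TRUE)]
    )
    pmax(r, model$floor)
  })
}

#' Generate a surrogate "experimental" population
#'
#' Stands in for a curated tracking dataset: simulates a full population with
#' heterogeneous initial rates (drawn from `rate_model` and converted to
#' initial `M` values), and optionally writes the event CSV, the initial-rate
#' CSV and a manifest JSON recording every parameter and seed.  The surrogate
#' reproduces the statistical structure the downstream analysis assumes --
#' many worms, fixed-length recordings, broad initial-rate spread,
#' exponentially decaying mean rate -- but is fully synthetic.
#'
#' @param params A [sim_params()] object (defaults give 1631 worms, 45 min,
#'   the published kinetic constants).
#' @param rate_model An [initial_rate_model()].
#' @param seed Master seed; the rate draw uses `seed + 1` so it is decoupled
#'   from the simulation streams.
#' @param out_dir Optional directory; when given, writes `events.csv`,
#'   `initial_rates.csv` and `manifest.json` there.
#' @return Invisibly, a list with the `population` (a `worm_population`),
#'   `initial_rates`, `manifest`, and (if written) `paths`.
#' @export
make_surrogate_experiment <- function(params = sim_params(),
                                      rate_model = initial_rate_model(),
                                      seed = params$seed,
                                      out_dir = NULL) {
  params$seed <- as.integer(seed)
  rates <- sample_initial_rates(rate_model, params$n_worms, seed = seed + 1L)
  pop <- simulate_population(params, initial_rates = rates, record_m = FALSE)
  manifest <- list(
    generator = "wormforage::make_surrogate_experiment",
    synthetic = TRUE,
    params = unclass(params),
    rate_model = list(mean_rate = rate_model$mean_rate, sd = rate_model$sd,
                      family = rate_model$family, floor = rate_model$floor),
    seed = seed,
    package_version = as.character(utils::packageVersion("wormforage"))
  )
  out <- list(population = pop, initial_rates = rates, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(events = file.path(out_dir, "events.csv"),
                  rates = file.path(out_dir, "initial_rates.csv"),
                  manifest = file.path(out_dir, "manifest.json"))
    write_events(pop, paths$events)
    write.csv(data.frame(worm_id = seq_along(rates), rate0 = rates),
              paths$rates, row.names = FALSE)
    write_manifest(paths$manifest, manifest)
    out$paths <- paths
  }
  invisible(out)
}

#' Exact piecewise-linear cumulative curve
#'
#' Noiseless two-segment fixture: slope `s1` up to `t_break`, then slope
#' `s2`, continuous at the break.  [two_segment_fit()] must recover
#' `(s1, s2, t_break)` exactly on such input (when the segment slopes
#' differ).
#'
#' @param s1,s2 Segment slopes (events/min, non-negative).
#' @param t_break Break time, strictly inside `(0, duration)`.
#' @param duration Total span (min).
#' @param grid_step Grid spacing (min).
#' @return A `cumulative_curve` (here `omega` is real-valued, not an integer
#'   count).
#' @export
make_piecewise_fixture <- function(s1, s2, t_break, duration = 45,
                                   grid_step = 0.5) {
  stopifnot(s1 >= 0, s2 >= 0, t_break > 0, t_break < duration)
  t <- time_grid(duration, grid_step)
  omega <- ifelse(t <= t_break, s1 * t,
                  s1 * t_break + s2 * (t - t_break))
  structure(data.frame(time_min = t, omega = omega),
            class = c("cumulative_curve", "data.frame"))
}
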