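#' Load and validate a pipeline run configuration
#'
#' A run configuration is a named list (or a YAML/JSON file) with optional
#' global keys `seed`, `out_dir`, `log_level` and one sub-list per requested
#' stage: `simulate`, `synth`, `fit`, `changepoint`, `compare`, `sweep`.
#' Unknown keys anywhere are rejected, so typos fail loudly instead of being
#' silently ignored.
#'
#' @param config Named list, or path to a YAML (or JSON) file.
#' @return The validated config (class `run_config`) with defaults filled in.
#' @export
load_run_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  global <- c("seed", "out_dir", "log_level")
  stages <- c("simulate", "synth", "fit", "changepoint", "compare", "sweep")
  bad <- setdiff(names(config), c(global, stages))
  if (length(bad) > 0L) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  stage_keys <- list(
    simulate = c("alpha", "beta", "gamma", "m0", "duration", "n_worms",
                 "mode", "initial_rates", "seed"),
    synth = c("alpha", "beta", "gamma", "m0", "duration", "n_worms", "mode",
              "mean_rate", "sd", "family", "seed"),
    fit = c("events", "window", "grid_step"),
    changepoint = c("events", "grid_step", "min_seg", "duration"),
    compare = c("reference", "candidate", "bins"),
    sweep = c("reference", "m0_values", "n_replicates", "bins", "mean_rate",
              "sd", "family")
  )
  for (st in intersect(names(config), stages)) {
    extra <- setdiff(names(config[[st]]), stage_keys[[st]])
    if (length(extra) > 0L) {
      stop("unknown key(s) in stage '", st, "': ",
           paste(extra, collapse = ", "))
    }
  }
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$out_dir)) config$out_dir <- "."
  if (is.null(config$log_level)) config$log_level <- "info"
  structure(config, class = c("run_config", "list"))
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order
#' (`simulate`/`synth` -> `fit` + `changepoint` -> `compare`/`sweep`), each
#' stage reading and writing only the documented CSV/JSON formats under
#' `out_dir`.  A stage failure aborts with an error naming the stage.  Every
#' run writes a `manifest.json` echoing the fully-resolved configuration,
#' seed and package version, so artifacts carry their provenance.
#'
#' @param config A `run_config`, named list, or path (see
#'   [load_run_config()]).
#' @return Invisibly, a named list of artifact paths.
#' @examples
#' \donttest{
#' dir <- tempfile()
#' run_pipeline(list(seed = 7, out_dir = dir,
#'                   simulate = list(n_worms = 5, duration = 10),
#'                   fit = list(), changepoint = list()))
#' }
#' @export
run_pipeline <- function(config) {
  cfg <- load_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()
  log_msg <- function(...) {
    if (cfg$log_level != "quiet") message("[wormforage] ", sprintf(...))
  }
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  duration <- NULL
  if (!is.null(cfg$simulate) || !is.null(cfg$synth)) {
    st <- if (!is.null(cfg$synth)) "synth" else "simulate"
    artifacts$events <- run_stage(st, function() {
      opts <- cfg[[st]]
      seed <- if (!is.null(opts$seed)) opts$seed else cfg$seed
      rate_keys <- c("mean_rate", "sd", "family")
      p_opts <- opts[setdiff(names(opts),
                             c(rate_keys, "initial_rates", "seed"))]
      p <- as_sim_params(c(p_opts, list(seed = seed)))
      duration <<- p$duration
      log_msg("%s: %d worms, %g min, M0=%d, seed %d", st, p$n_worms,
              p$duration, p$m0, p$seed)
      if (st == "synth") {
        rm_opts <- opts[intersect(names(opts), rate_keys)]
        res <- make_surrogate_experiment(
          p, do.call(initial_rate_model, rm_opts), seed = seed,
          out_dir = cfg$out_dir)
        res$paths$events
      } else {
        rates <- opts$initial_rates
        if (is.character(rates)) rates <- read.csv(rates)$rate0
        pop <- simulate_population(p, initial_rates = rates,
                                   record_m = FALSE)
        write_events(pop, file.path(cfg$out_dir, "events.csv"))
      }
    })
  }

  events_for <- function(opts) {
    path <- if (!is.null(opts$events)) opts$events else artifacts$events
    if (is.null(path)) stop("no event CSV available (supply 'events' or run a simulate/synth stage)")
    read_events(path)
  }

  if (!is.null(cfg$fit)) {
    run_stage("fit", function() {
      opts <- cfg$fit
      ev <- events_for(opts)
      dur <- if (!is.null(duration)) duration else max(ev$event_time_min)
      pop <- events_to_population(ev, duration = dur)
      rc <- population_rate(pop,
        window = if (!is.null(opts$window)) opts$window else 2,
        grid_step = if (!is.null(opts$grid_step)) opts$grid_step else 0.5)
      fit <- fit_decay(rc)
      artifacts$rate_curve <<- write_rate_curve(
        rc, file.path(cfg$out_dir, "rate_curve.csv"))
      artifacts$fit <<- write_decay_fit(
        fit, file.path(cfg$out_dir, "decay_fit.json"))
      log_msg("fit: alpha=%.4f beta=%.4f gamma=%.4f (converged: %s)",
              coef(fit)["alpha"], coef(fit)["beta"], coef(fit)["gamma"],
              fit$converged)
    })
  }

  if (!is.null(cfg$changepoint)) {
    run_stage("changepoint", function() {
      opts <- cfg$changepoint
      ev <- events_for(opts)
      dur <- if (!is.null(opts$duration)) opts$duration
             else if (!is.null(duration)) duration else max(ev$event_time_min)
      pop <- events_to_population(ev, duration = dur)
      cps <- population_changepoints(pop,
        grid_step = if (!is.null(opts$grid_step)) opts$grid_step else 0.5,
        min_seg = if (!is.null(opts$min_seg)) opts$min_seg else 2)
      artifacts$changepoints <<- write_changepoints(
        cps, file.path(cfg$out_dir, "changepoints.csv"))
      log_msg("changepoint: %d worms, median slope diff %.3f", nrow(cps),
              median(cps$slope_diff))
    })
  }

  if (!is.null(cfg$compare)) {
    run_stage("compare", function() {
      opts <- cfg$compare
      ref <- read_changepoints(opts$reference)
      cand_path <- if (!is.null(opts$candidate)) opts$candidate
                   else artifacts$changepoints
      if (is.null(cand_path)) stop("no candidate changepoint CSV")
      cand <- read_changepoints(cand_path)
      bins <- if (!is.null(opts$bins)) opts$bins else 20L
      edges <- default_bin_edges(ref, bins = bins)
      p <- bin_distribution(ref, edges$edges_x, edges$edges_y)
      q <- bin_distribution(cand, edges$edges_x, edges$edges_y)
      report <- list(jsd = jsd(p, q),
                     jsd_marginals = as.list(jsd_marginals(p, q)),
                     bins = bins, n_reference = nrow(ref),
                     n_candidate = nrow(cand))
      artifacts$compare <<- file.path(cfg$out_dir, "compare.json")
      jsonlite::write_json(report, artifacts$compare, auto_unbox = TRUE,
                           digits = NA)
      log_msg("compare: JSD = %.4f nats", report$jsd)
    })
  }

  if (!is.null(cfg$sweep)) {
    run_stage("sweep", function() {
      opts <- cfg$sweep
      ref <- read_changepoints(opts$reference)
      base <- as_sim_params(c(
        cfg$simulate[intersect(names(cfg$simulate),
                               c("alpha", "beta", "gamma", "duration",
                                 "n_worms", "mode"))],
        list(seed = cfg$seed)))
      rm_opts <- opts[intersect(names(opts), c("mean_rate", "sd", "family"))]
      sw <- m0_sweep_study(
        ref, base,
        m0_values = if (!is.null(opts$m0_values)) opts$m0_values
                    else c(1000L, 100L, 10L, 1L),
        n_replicates = if (!is.null(opts$n_replicates)) opts$n_replicates
                       else 20L,
        rate_model = do.call(initial_rate_model, rm_opts),
        seed = cfg$seed,
        bins = if (!is.null(opts$bins)) opts$bins else 20L)
      artifacts$sweep <<- file.path(cfg$out_dir, "sweep.json")
      jsonlite::write_json(
        list(m0_values = sw$m0_values, n_replicates = sw$n_replicates,
             jsd = as.data.frame(sw$jsd),
             group_means = as.list(sw$group_means),
             group_sd = as.list(sw$group_sd),
             tukey = sw$tukey),
        artifacts$sweep, auto_unbox = TRUE, digits = NA)
      log_msg("sweep: group means %s",
              paste(sprintf("%s=%.3f", names(sw$group_means),
                            sw$group_means), collapse = ", "))
    })
  }

  write_manifest(file.path(cfg$out_dir, "manifest.json"),
                 list(config = unclass(cfg), seed = cfg$seed,
                      package_version =
                        as.character(utils::packageVersion("wormforage"))))
  artifacts$manifest <- file.path(cfg$out_dir, "manifest.json")
  invisible(artifacts)
}
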