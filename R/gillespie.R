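#' Propensities of the two-channel system at a given M
#'
#' The reorientation channel has propensity `a1 = (alpha / M0) * M + beta`
#' and the decay channel `a2 = gamma * M`.  `a2` is the magnitude of the
#' first-order decay rate of `M`; as a Gillespie propensity it is
#' non-negative (the sign convention of a deterministic rate equation
#' `dM/dt = -gamma * M` does not carry over).  In constant mode the
#' reorientation propensity is fixed at `alpha + beta` and the decay channel
#' is switched off.
#'
#' @param m Current count of the decaying factor `M` (integer,
#'   `0 <= m <= M0`).
#' @param params A [sim_params()] object.
#' @return A list of class `propensity_state` with components `a1`, `a2` and
#'   `a0 = a1 + a2` (all events/min).
#' @examples
#' p <- sim_params()
#' compute_propensities(1000, p)  # a1 = 1.6837, a2 = 110
#' compute_propensities(0, p)     # a1 = beta, a2 = 0
#' @export
compute_propensities <- function(m, params) {
  stopifnot(is.numeric(m), length(m) == 1L, m >= 0)
  if (params$mode == "constant") {
    a1 <- params$alpha + params$beta
    a2 <- 0
  } else {
    if (params$m0 == 0 && m > 0) {
      stop("invalid configuration: M0 = 0 in decaying mode with M > 0")
    }
    if (m > params$m0) stop("M exceeds M0")
    # evaluated as (alpha / M0) * M + beta to match the compiled core
    # bit-for-bit
    a1 <- if (params$m0 > 0) params$alpha / params$m0 * m + params$beta
          else params$beta
    a2 <- params$gamma * m
  }
  structure(list(a1 = a1, a2 = a2, a0 = a1 + a2),
            class = "propensity_state")
}

#' Waiting time to the next event
#'
#' Draws the Gillespie waiting time `tau = -log(r1) / a0` from the total
#' propensity `a0` and a uniform variate `r1` in `(0, 1]`.  `r1 = 1` gives
#' `tau = 0` (a measure-zero coincidence that is allowed); `r1 = 0` would
#' give an infinite wait and must be resampled by the caller.
#'
#' @param a0 Total propensity (events/min), strictly positive.
#' @param r1 Uniform variate in `(0, 1]`.
#' @return Waiting time in minutes (non-negative).
#' @examples
#' draw_interval(2, exp(-1))  # 0.5
#' draw_interval(4, 0.25)     # log(4)/4
#' @export
draw_interval <- function(a0, r1) {
  if (a0 <= 0) stop("a0 must be positive: no event can occur")
  if (r1 <= 0 || r1 > 1) stop("r1 must lie in (0, 1]; resample r1 = 0")
  -log(r1) / a0
}

#' Select which event fires
#'
#' Returns the smallest channel index `n` such that
#' `r2 * a0 <= a1 + ... + an`, so that channel `i` fires with probability
#' `ai / a0` over the ensemble of `r2`.
#'
#' @param props A `propensity_state` from [compute_propensities()].
#' @param r2 Uniform variate in `[0, 1)`.
#' @return `1L` (reorientation) or `2L` (decay of `M`).
#' @examples
#' p <- compute_propensities(500, sim_params())
#' select_event(p, 0)    # 1: boundary always picks the first channel
#' @export
select_event <- function(props, r2) {
  if (props$a0 <= 0) stop("a0 must be positive")
  if (r2 * props$a0 <= props$a1) 1L else 2L
}

#' Initial M for a worm drawn to match a target initial rate
#'
#' Inverts the propensity relation `a1 = (alpha / M0) * M + beta` at `t = 0`:
#' `M_j = M0 * (r - beta) / alpha`, rounded half-up to the nearest integer
#' and clamped to `[0, M0]`.  A draw below the baseline `beta` starts the
#' worm at `M = 0` (baseline rate only).
#'
#' @param r Target initial reorientation rate(s) (events/min); vectorised.
#' @param params A [sim_params()] object with `alpha > 0`.
#' @return Integer vector of initial `M` values.
#' @examples
#' p <- sim_params()
#' assign_initial_m(p$alpha + p$beta, p)  # M0
#' assign_initial_m(1.0, p)               # 541
#' @export
assign_initial_m <- function(r, params) {
  stopifnot(params$alpha > 0, is.numeric(r))
  m <- floor(params$m0 * (r - params$beta) / params$alpha + 0.5)
  as.integer(pmin(pmax(m, 0), params$m0))
}

new_trajectory <- function(worm_id, event_times, m_path, initial_m,
                           duration) {
  structure(
    list(worm_id = worm_id, event_times = event_times, m_path = m_path,
         initial_m = as.integer(initial_m), duration = duration),
    class = "worm_trajectory"
  )
}

#' Simulate one worm's reorientation event stream
#'
#' Runs the Gillespie algorithm for a single worm: repeatedly draw the
#' waiting time from the total propensity, advance the clock, select the
#' event (reorientation or decay of `M`) proportionally to the relative
#' propensities, and apply it, until the clock passes `duration`.  When both
#' propensities vanish (`M = 0` and `beta = 0`) no further event is possible
#' and the simulation jumps to `duration`.
#'
#' @param params A [sim_params()] object.
#' @param initial_m Initial `M` count (defaults to `M0`).
#' @param seed Integer seed for this worm's RNG stream (defaults to
#'   `params$seed`).  Ignored when `rng_state` is supplied.
#' @param rng_state Optionally, a full `.Random.seed` state vector (e.g. a
#'   L'Ecuyer-CMRG sub-stream) to draw from instead of seeding afresh.
#' @param record_m Keep the piecewise-constant path of `M`?  Setting `FALSE`
#'   saves memory in large sweeps.
#' @param worm_id Identifier stored in the result.
#' @return A `worm_trajectory`: `event_times` (strictly increasing, in
#'   `[0, duration]`), `m_path` (data.frame `time_min`, `M`, starting at
#'   `(0, initial_m)`), `initial_m`, `duration`.
#' @examples
#' tr <- simulate_worm(sim_params(n_worms = 1, seed = 7))
#' length(tr$event_times)
#' @export
simulate_worm <- function(params, initial_m = params$m0,
                          seed = params$seed, rng_state = NULL,
                          record_m = TRUE, worm_id = 1L) {
  stopifnot(initial_m >= 0)
  if (params$mode == "decaying") stopifnot(initial_m <= params$m0)
  run <- function() {
    gillespie_core(params$alpha, params$beta, params$gamma, params$m0,
                   params$duration, as.integer(initial_m),
                   params$mode == "constant", record_m)
  }
  res <- if (is.null(rng_state)) {
    with_preserved_rng({
      set.seed(seed)
      run()
    })
  } else {
    with_rng_state(rng_state, run())
  }
  m_path <- if (record_m) {
    data.frame(time_min = res$m_times, M = res$m_values)
  } else {
    data.frame(time_min = 0, M = as.integer(initial_m))
  }
  new_trajectory(worm_id, res$event_times, m_path, initial_m,
                 params$duration)
}

#' Simulate a population of worms
#'
#' One trajectory per worm.  Each worm draws from its own L'Ecuyer-CMRG
#' sub-stream, derived from the master seed by repeated
#' [parallel::nextRNGStream()]: worm `i` always gets the `i`-th sub-stream,
#' so enlarging the population does not reshuffle earlier worms, and any
#' single worm can be re-simulated in isolation.
#'
#' @param params A [sim_params()] object (`n_worms`, `seed` are taken from
#'   it).
#' @param initial_rates Optional numeric vector of length `n_worms` of target
#'   initial reorientation rates (events/min); each is converted to an
#'   initial `M` by [assign_initial_m()].  Default: all worms start at
#'   `M = M0` (rate `alpha + beta`).  Ignored in constant mode.
#' @param record_m Keep per-worm `M` paths?
#' @return A `worm_population`: a list of `worm_trajectory` objects with the
#'   parameters attached as attribute `params`.
#' @examples
#' pop <- simulate_population(sim_params(n_worms = 5, seed = 3))
#' sapply(pop, function(tr) length(tr$event_times))
#' @export
simulate_population <- function(params, initial_rates = NULL,
                                record_m = TRUE) {
  n <- params$n_worms
  if (is.null(initial_rates)) {
    init_m <- rep.int(params$m0, n)
  } else {
    stopifnot(length(initial_rates) == n)
    init_m <- assign_initial_m(initial_rates, params)
  }
  streams <- worm_rng_streams(params$seed, n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- simulate_worm(params, initial_m = init_m[i],
                              rng_state = streams[[i]],
                              record_m = record_m, worm_id = i)
  }
  structure(out, class = "worm_population", params = params)
}

# L'Ecuyer-CMRG sub-streams for worms 1..n under a master seed.  The user's
# RNG kind and state are untouched.
worm_rng_streams <- function(seed, n) {
  with_preserved_rng({
    suppressWarnings(RNGkind("L'Ecuyer-CMRG"))
    set.seed(seed)
    s <- get(".Random.seed", envir = globalenv())
    streams <- vector("list", n)
    for (i in seq_len(n)) {
      s <- parallel::nextRNGStream(s)
      streams[[i]] <- s
    }
    streams
  })
}

# Evaluate expr, then restore the caller's RNG state exactly.
with_preserved_rng <- function(expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  expr
}

# Evaluate expr with .Random.seed set to `state`, restoring afterwards.
with_rng_state <- function(state, expr) {
  with_preserved_rng({
    assign(".Random.seed", state, envir = globalenv())
    expr
  })
}

#' @export
print.worm_trajectory <- function(x, ...) {
  cat(sprintf(
    "Worm %s: %d reorientations in %g min (initial M = %d, final M = %d)\n",
    as.character(x$worm_id), length(x$event_times), x$duration,
    x$initial_m, tail(x$m_path$M, 1L)))
  invisible(x)
}

#' @export
print.worm_population <- function(x, ...) {
  p <- attr(x, "params")
  cnt <- vapply(x, function(tr) length(tr$event_times), integer(1))
  cat(sprintf("Population of %d worms (%s mode), %g min\n",
              length(x), p$mode, p$duration))
  cat(sprintf("  reorientations/worm: mean %.2f, range [%d, %d]\n",
              mean(cnt), min(cnt), max(cnt)))
  invisible(x)
}

#' @export
as.data.frame.worm_population <- function(x, ...) {
  n_ev <- vapply(x, function(tr) length(tr$event_times), integer(1))
  data.frame(
    worm_id = rep(vapply(x, function(tr) as.integer(tr$worm_id), integer(1)),
                  n_ev),
    event_time_min = unlist(lapply(x, `[[`, "event_times"), use.names = FALSE)
  )
}

#' @export
plot.worm_trajectory <- function(x, ...) {
  n <- length(x$event_times)
  plot(c(0, x$event_times, x$duration), c(0, seq_len(n), n), type = "s",
       xlab = "time (min)", ylab = expression(Omega ~ "(cumulative reorientations)"),
       main = paste("Worm", x$worm_id), ...)
  invisible(x)
}
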