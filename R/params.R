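#' Simulation parameters for the foraging reorientation model
#'
#' Bundles the kinetic constants and run settings of the two-channel
#' reorientation/decay system.  The defaults are the constants obtained by
#' fitting the exponential decay `alpha * exp(-gamma * t) + beta` to the
#' average reorientation rate of a population of 1631 worms tracked for
#' 45 minutes after removal from food: `alpha = 1.49`/min,
#' `beta = 0.1937`/min, `gamma = 0.11`/min, with `M0 = 1000` so that the
#' decay of the latent factor `M` is effectively continuous over the
#' recording.
#'
#' @param alpha Rate amplitude (events/min): the excess initial reorientation
#'   rate above baseline when `M = M0`.
#' @param beta Baseline reorientation rate (events/min), the rate as
#'   `t -> Inf`.
#' @param gamma First-order decay constant of `M` (1/min).
#' @param m0 Initial count of the decaying factor `M` (non-negative integer).
#'   `M0 = 1` makes the model a two-state system (rates `alpha + beta` or
#'   `beta`); large `M0` makes the rate decay effectively smooth.
#' @param duration Total simulated time (min).
#' @param n_worms Number of worms in a simulated population.
#' @param seed Master RNG seed (integer).  Per-worm sub-streams are derived
#'   from it; see [simulate_population()].
#' @param mode `"decaying"` for the full model, or `"constant"` for the
#'   control in which the reorientation propensity is fixed at
#'   `alpha + beta` for the whole run (no decay channel).
#'
#' @return An object of class `sim_params` (a named list).
#' @examples
#' sim_params(n_worms = 10, seed = 42)
#' sim_params(alpha = 1.5, beta = 0, mode = "constant", n_worms = 5)
#' @export
sim_params <- function(alpha = 1.49, beta = 0.1937, gamma = 0.11,
                       m0 = 1000, duration = 45, n_worms = 1631,
                       seed = 1L, mode = c("decaying", "constant")) {
  mode <- match.arg(mode)
  stopifnot(
    is.numeric(alpha), length(alpha) == 1L, alpha >= 0,
    is.numeric(beta), length(beta) == 1L, beta >= 0,
    is.numeric(gamma), length(gamma) == 1L, gamma >= 0,
    is.numeric(m0), length(m0) == 1L, m0 >= 0, m0 == floor(m0),
    is.numeric(duration), length(duration) == 1L, duration > 0,
    is.numeric(n_worms), length(n_worms) == 1L, n_worms >= 1,
    n_worms == floor(n_worms),
    is.numeric(seed), length(seed) == 1L, seed == floor(seed)
  )
  structure(
    list(alpha = alpha, beta = beta, gamma = gamma, m0 = as.integer(m0),
         duration = duration, n_worms = as.integer(n_worms),
         seed = as.integer(seed), mode = mode),
    class = "sim_params"
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Foraging simulation parameters (", x$mode, " mode)\n", sep = "")
  cat(sprintf("  alpha = %g /min, beta = %g /min, gamma = %g /min\n",
              x$alpha, x$beta, x$gamma))
  cat(sprintf("  M0 = %d, duration = %g min, n_worms = %d, seed = %d\n",
              x$m0, x$duration, x$n_worms, x$seed))
  invisible(x)
}

# Coerce a plain named list (e.g. parsed YAML/JSON config) to sim_params.
as_sim_params <- function(x) {
  if (inherits(x, "sim_params")) return(x)
  stopifnot(is.list(x))
  known <- c("alpha", "beta", "gamma", "m0", "duration", "n_worms",
             "seed", "mode")
  bad <- setdiff(names(x), known)
  if (length(bad) > 0L) {
    stop("unknown simulation parameter(s): ", paste(bad, collapse = ", "))
  }
  do.call(sim_params, x)
}
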