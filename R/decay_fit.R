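#' Fit the three-parameter exponential rate decay
#'
#' Least-squares fit of `rate(t) = alpha * exp(-gamma * t) + beta` to a rate
#' curve, with all three parameters bounded below by zero
#' (Levenberg-Marquardt via [minpack.lm::nlsLM()]).  The fit is ordinary
#' (unweighted) least squares on the mean curve.  Starting values are
#' scale-free and deterministic: `alpha0 = max(rate) - min(rate)`,
#' `beta0 = min(rate)`, `gamma0 = 3 / T`.
#'
#' @param curve A `rate_curve` (from [rolling_rate()] or
#'   [population_rate()]), or a data.frame with columns `time_min` and
#'   `rate`.  At least 4 points are required.
#' @param start Optional named numeric vector overriding the default starting
#'   values (`alpha`, `beta`, `gamma`).
#' @param maxiter Maximum Levenberg-Marquardt iterations.
#' @return An object of class `decay_fit` with components `coefficients`
#'   (named `alpha`, `beta`, `gamma`), `rss`, `converged`, `fitted.values`,
#'   `residuals` and `data`.  Supports `coef()`, `predict()`, `residuals()`,
#'   `fitted()`, `summary()`, `plot()` and [simulate()][simulate.decay_fit].
#' @examples
#' t <- seq(0, 45, 0.5)
#' curve <- data.frame(time_min = t, rate = 1.49 * exp(-0.11 * t) + 0.1937)
#' coef(fit_decay(curve))
#' @export
fit_decay <- function(curve, start = NULL, maxiter = 200L) {
  df <- as.data.frame(curve)
  stopifnot(all(c("time_min", "rate") %in% names(df)))
  if (nrow(df) < 4L) stop("need at least 4 grid points to fit 3 parameters")
  if (is.null(start)) {
    start <- c(alpha = max(df$rate) - min(df$rate),
               beta = min(df$rate),
               gamma = 3 / max(max(df$time_min), .Machine$double.eps))
  }
  # nlsLM errors rather than returning its best iterate on some degenerate
  # inputs (e.g. exactly constant curves); fall back to bounded Nelder-Mead
  # on the same loss so a best-effort iterate is always returned.
  fit <- tryCatch(
    minpack.lm::nlsLM(
      rate ~ alpha * exp(-gamma * time_min) + beta,
      data = df, start = as.list(start),
      lower = c(0, 0, 0),
      control = minpack.lm::nls.lm.control(maxiter = maxiter)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- coef(fit)[c("alpha", "beta", "gamma")]
    fitted_vals <- as.numeric(fitted(fit))
    converged <- isTRUE(fit$convInfo$isConv)
  } else {
    loss <- function(p) {
      p <- pmax(p, 0)
      sum((df$rate - (p[1] * exp(-p[3] * df$time_min) + p[2]))^2)
    }
    op <- optim(start, loss, method = "Nelder-Mead",
                control = list(maxit = 2000L))
    cf <- setNames(pmax(op$par, 0), c("alpha", "beta", "gamma"))
    fitted_vals <- cf["alpha"] * exp(-cf["gamma"] * df$time_min) + cf["beta"]
    converged <- FALSE
  }
  res <- df$rate - fitted_vals
  structure(
    list(coefficients = cf, rss = sum(res^2), converged = converged,
         fitted.values = fitted_vals, residuals = res, data = df,
         call = match.call()),
    class = "decay_fit")
}

#' Memory half-life of the decaying factor
#'
#' Time for the latent factor `M` (and hence the excess reorientation rate)
#' to halve: `log(2) / gamma`.  A decay constant of 0.07/min corresponds to a
#' half-life of about 10 minutes.
#'
#' @param x A decay constant `gamma` (1/min, positive), or a `decay_fit`.
#' @return Half-life in minutes.
#' @examples
#' half_life(0.07)  # ~9.9 min
#' half_life(0.11)  # ~6.3 min
#' @export
half_life <- function(x) UseMethod("half_life")

#' @export
half_life.default <- function(x) {
  stopifnot(is.numeric(x), length(x) == 1L)
  if (x <= 0) stop("half-life is undefined for gamma <= 0")
  log(2) / x
}

#' @export
half_life.decay_fit <- function(x) half_life(unname(coef(x)["gamma"]))

#' @export
coef.decay_fit <- function(object, ...) object$coefficients

#' @export
print.decay_fit <- function(x, ...) {
  cf <- coef(x)
  cat("Exponential decay fit: rate(t) = alpha * exp(-gamma t) + beta\n")
  cat(sprintf("  alpha = %.4f /min, beta = %.4f /min, gamma = %.4f /min\n",
              cf["alpha"], cf["beta"], cf["gamma"]))
  cat(sprintf("  RSS = %.4g over %d points; converged: %s\n",
              x$rss, nrow(x$data), x$converged))
  if (cf["gamma"] > 0)
    cat(sprintf("  half-life = %.2f min\n", half_life(x)))
  invisible(x)
}

#' @export
summary.decay_fit <- function(object, ...) {
  n <- nrow(object$data)
  out <- list(coefficients = coef(object), rss = object$rss,
              sigma = sqrt(object$rss / max(n - 3L, 1L)),
              n = n, converged = object$converged,
              half_life = if (coef(object)["gamma"] > 0)
                half_life(object) else NA_real_)
  class(out) <- "summary.decay_fit"
  out
}

#' @export
print.summary.decay_fit <- function(x, ...) {
  cat("Exponential decay fit summary\n")
  print(round(x$coefficients, 5))
  cat(sprintf("n = %d, RSS = %.4g, residual sigma = %.4g\n",
              x$n, x$rss, x$sigma))
  cat(sprintf("half-life = %.2f min; converged: %s\n", x$half_life,
              x$converged))
  invisible(x)
}

#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time_min
       else if (is.data.frame(newdata)) newdata$time_min
       else as.numeric(newdata)
  cf <- coef(object)
  unname(cf["alpha"] * exp(-cf["gamma"] * t) + cf["beta"])
}

#' @export
residuals.decay_fit <- function(object, ...) object$residuals

#' @export
fitted.decay_fit <- function(object, ...) object$fitted.values

#' @export
plot.decay_fit <- function(x, ...) {
  plot(x$data$time_min, x$data$rate, pch = 16, cex = 0.6,
       col = adjustcolor("black", 0.6), xlab = "time (min)",
       ylab = "reorientation rate (events/min)", ...)
  tt <- seq(min(x$data$time_min), max(x$data$time_min), length.out = 200)
  lines(tt, predict(x, tt), col = "red", lwd = 2)
  legend("topright", bty = "n",
         legend = sprintf("alpha=%.3f beta=%.3f gamma=%.3f",
                          coef(x)["alpha"], coef(x)["beta"],
                          coef(x)["gamma"]))
  invisible(x)
}

#' Simulate populations from a fitted decay model
#'
#' Uses the fitted `(alpha, beta, gamma)` as kinetic constants of the
#' stochastic reorientation model and simulates `nsim` independent
#' populations.
#'
#' @param object A `decay_fit`.
#' @param nsim Number of populations.
#' @param seed Master seed for the first population; population `k` uses
#'   `seed + k - 1`.
#' @param m0,duration,n_worms,mode Run settings passed to [sim_params()].
#' @param initial_rates Optional initial-rate vector forwarded to
#'   [simulate_population()].
#' @param ... Unused.
#' @return A list of `worm_population` objects (a single population if
#'   `nsim = 1`).
#' @export
simulate.decay_fit <- function(object, nsim = 1, seed = 1L, m0 = 1000,
                               duration = 45, n_worms = 100,
                               mode = "decaying", initial_rates = NULL,
                               ...) {
  cf <- coef(object)
  pops <- lapply(seq_len(nsim), function(k) {
    p <- sim_params(alpha = cf["alpha"], beta = cf["beta"],
                    gamma = cf["gamma"], m0 = m0, duration = duration,
                    n_worms = n_worms, seed = seed + k - 1L, mode = mode)
    simulate_population(p, initial_rates = initial_rates)
  })
  if (nsim == 1) pops[[1L]] else pops
}
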