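#' Shared bin edges for (slope difference, transition time) histograms
#'
#' Computes fixed edges from a reference changepoint set: `bins` equal-width
#' bins per axis spanning the central mass of the reference (0.5th to 99.5th
#' percentile by default).  Out-of-range observations are later clipped into
#' the end bins by [bin_distribution()], so any pair of distributions binned
#' with the same edges is comparable.
#'
#' @param reference A `changepoint_set` (or data.frame with `slope_diff`,
#'   `t_trans`).
#' @param bins Number of bins per axis.
#' @param clip Lower/upper quantiles defining the covered range.
#' @return List with numeric vectors `edges_x` (slope difference, events/min)
#'   and `edges_y` (transition time, min).
#' @export
default_bin_edges <- function(reference, bins = 20L,
                              clip = c(0.005, 0.995)) {
  stopifnot(nrow(reference) >= 1L, bins >= 2L)
  rng_x <- quantile(reference$slope_diff, clip, names = FALSE, na.rm = TRUE)
  rng_y <- quantile(reference$t_trans, clip, names = FALSE, na.rm = TRUE)
  widen <- function(r) if (diff(r) <= 0) r + c(-0.5, 0.5) else r
  rng_x <- widen(rng_x); rng_y <- widen(rng_y)
  list(edges_x = seq(rng_x[1L], rng_x[2L], length.out = bins + 1L),
       edges_y = seq(rng_y[1L], rng_y[2L], length.out = bins + 1L))
}

#' Joint binned distribution of slope difference and transition time
#'
#' 2-D histogram of per-worm `(slope_diff, t_trans)` pairs on fixed shared
#' edges, normalised to total probability 1.  Observations outside the edge
#' range are clipped into the nearest end bin, so no mass is lost and two
#' distributions binned on the same edges always share support structure.
#'
#' @param results A `changepoint_set` (or data.frame with columns
#'   `slope_diff`, `t_trans`); must be non-empty.
#' @param edges_x,edges_y Strictly increasing bin-edge vectors (see
#'   [default_bin_edges()]).
#' @return A `binned_distribution`: list with `edges_x`, `edges_y` and the
#'   probability matrix `probs` (rows = x bins, cols = y bins, sums to 1).
#' @export
bin_distribution <- function(results, edges_x, edges_y) {
  if (nrow(results) == 0L) stop("cannot bin an empty changepoint set")
  stopifnot(length(edges_x) >= 2L, all(diff(edges_x) > 0),
            length(edges_y) >= 2L, all(diff(edges_y) > 0))
  nx <- length(edges_x) - 1L
  ny <- length(edges_y) - 1L
  ix <- pmin(pmax(findInterval(results$slope_diff, edges_x,
                               rightmost.closed = TRUE), 1L), nx)
  iy <- pmin(pmax(findInterval(results$t_trans, edges_y,
                               rightmost.closed = TRUE), 1L), ny)
  counts <- matrix(0, nx, ny)
  for (k in seq_along(ix)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1
  structure(list(edges_x = edges_x, edges_y = edges_y,
                 probs = counts / sum(counts)),
            class = "binned_distribution")
}

#' Kullback-Leibler divergence between binned distributions
#'
#' `D(P || Q) = sum_x P(x) log(P(x) / Q(x))` in nats, summing over bins with
#' `P(x) > 0`.  Bins where `P(x) = 0` contribute nothing; a bin with
#' `P(x) > 0` but `Q(x) = 0` makes the divergence infinite (this cannot
#' happen inside [jsd()], where the second argument is the mixture).
#'
#' @param p,q `binned_distribution` objects on identical edges.
#' @return Divergence in nats (non-negative, possibly `Inf`).
#' @export
kl_divergence <- function(p, q) {
  check_shared_edges(p, q)
  pp <- as.numeric(p$probs)
  qq <- as.numeric(q$probs)
  pos <- pp > 0
  if (any(pos & qq == 0)) return(Inf)
  sum(pp[pos] * log(pp[pos] / qq[pos]))
}

#' Jensen-Shannon divergence between binned distributions
#'
#' `JSD(P || Q) = D(P || M)/2 + D(Q || M)/2` with the mixture
#' `M = (P + Q)/2`.  Symmetric, always finite, bounded by `log(2)` nats
#' (attained for disjoint supports).
#'
#' @inheritParams kl_divergence
#' @return Divergence in nats, in `[0, log(2)]`.
#' @examples
#' # via raw probability vectors:
#' p <- as_binned(c(1, 0)); q <- as_binned(c(0.5, 0.5))
#' jsd(p, q)  # 0.2157616
#' @export
jsd <- function(p, q) {
  check_shared_edges(p, q)
  mix <- p
  mix$probs <- (p$probs + q$probs) / 2
  0.5 * kl_divergence(p, mix) + 0.5 * kl_divergence(q, mix)
}

#' Wrap a bare probability array as a binned distribution
#'
#' Convenience for divergence computations on marginal or externally binned
#' probabilities; unit-width dummy edges are attached.
#'
#' @param probs Non-negative numeric vector or matrix summing to 1.
#' @return A `binned_distribution`.
#' @export
as_binned <- function(probs) {
  probs <- as.matrix(probs)
  stopifnot(all(probs >= 0), abs(sum(probs) - 1) < 1e-8)
  structure(list(edges_x = 0:nrow(probs), edges_y = 0:ncol(probs),
                 probs = probs),
            class = "binned_distribution")
}

#' Marginal Jensen-Shannon divergences
#'
#' JSD computed separately on the slope-difference and transition-time
#' marginals of two joint binned distributions.
#'
#' @inheritParams kl_divergence
#' @return Named numeric vector `c(slope_diff = ..., t_trans = ...)` (nats).
#' @export
jsd_marginals <- function(p, q) {
  check_shared_edges(p, q)
  marg <- function(b, dim) {
    pr <- if (dim == 1L) rowSums(b$probs) else colSums(b$probs)
    as_binned(pr)
  }
  c(slope_diff = jsd(marg(p, 1L), marg(q, 1L)),
    t_trans = jsd(marg(p, 2L), marg(q, 2L)))
}

check_shared_edges <- function(p, q) {
  stopifnot(inherits(p, "binned_distribution"),
            inherits(q, "binned_distribution"))
  if (!isTRUE(all.equal(p$edges_x, q$edges_x)) ||
      !isTRUE(all.equal(p$edges_y, q$edges_y))) {
    stop("distributions must share identical bin edges")
  }
  invisible(TRUE)
}

#' Best-correlated trajectory match
#'
#' Finds the candidate cumulative curve with the highest Pearson correlation
#' to a reference curve -- used to pair an observed worm with its most
#' similar simulated counterpart.  All curves must share the time grid.
#' Zero-variance candidates (no events) have undefined correlation and are
#' skipped with a message.
#'
#' @param reference_curve A `cumulative_curve`.
#' @param candidates List of `cumulative_curve` objects on the same grid.
#' @return List with `index` (position of the best candidate; ties go to the
#'   smallest index) and `correlation`.
#' @export
best_match <- function(reference_curve, candidates) {
  stopifnot(length(candidates) >= 1L)
  ref <- as.data.frame(reference_curve)
  if (sd(ref$omega) == 0) stop("reference curve has zero variance")
  cors <- vapply(seq_along(candidates), function(i) {
    cand <- as.data.frame(candidates[[i]])
    if (!isTRUE(all.equal(cand$time_min, ref$time_min))) {
      stop("candidate ", i, " is not on the reference time grid")
    }
    if (sd(cand$omega) == 0) {
      message("skipping zero-variance candidate ", i)
      return(NA_real_)
    }
    cor(ref$omega, cand$omega)
  }, numeric(1))
  if (all(is.na(cors))) stop("no candidate with defined correlation")
  idx <- which.max(cors)  # NAs never win; first maximum on ties
  list(index = idx, correlation = cors[idx])
}
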