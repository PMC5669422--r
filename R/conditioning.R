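# Conditioning the simulated |Omega| sample on a database count: importance
# weights (binomial probability of the observed count), effective sample
# size, weighted quantiles/mode, and a rejection-sampling cross-check.

#' Importance weights for conditioning on a database count
#'
#' For each simulated draw with match fraction `pi`, the probability of
#' observing exactly `m` copies of Q's profile in a database of size `n`
#' sampled randomly from the live males is approximated by the binomial
#' probability `choose(n, m) pi^m (1 - pi)^(n - m)`; these raw weights,
#' normalised to average one over the full simulation, convert the
#' unconditional `|Omega|` sample into the conditional one.  Weights are
#' computed in log space so that large `n` does not underflow.
#'
#' @param pis Numeric vector of match fractions `pi` in (0, 1\].
#' @param m Observed database count (non-negative integer, `m <= n`).
#' @param n Database size (non-negative integer).
#' @return Numeric weight vector averaging one.
#' @examples
#' importance_weights(c(0.001, 0.01), m = 0, n = 100)
#' @export
importance_weights <- function(pis, m, n) {
  stopifnot(is.numeric(pis), all(pis > 0), all(pis <= 1),
            length(m) == 1, length(n) == 1, m >= 0, n >= 0, m <= n,
            m == round(m), n == round(n))
  if (n == 0) return(rep(1, length(pis)))
  lw <- lchoose(n, m) + m * log(pis) + (n - m) * log1p(-pis)
  mx <- max(lw)
  if (!is.finite(mx)) {
    stop("all importance weights are zero for m = ", m, ", n = ", n,
         ": no simulated draw is compatible with this count; ",
         "run more simulations", call. = FALSE)
  }
  w <- exp(lw - mx)
  w / mean(w)
}

#' Effective sample size of a weighted sample
#'
#' `(sum(w))^2 / sum(w^2)`: the number of equally weighted draws carrying
#' the same information.  Equal weights give the number of draws; a single
#' non-zero weight gives 1.
#'
#' @param weights Non-negative weights, not all zero.
#' @return A positive real.
#' @examples
#' effective_sample_size(c(2, 1, 1))  # 16/6
#' @export
effective_sample_size <- function(weights) {
  stopifnot(is.numeric(weights), all(weights >= 0), any(weights > 0))
  sum(weights)^2 / sum(weights^2)
}

#' Weighted quantile of an integer sample
#'
#' Left-continuous inverse CDF: the smallest value whose normalised
#' weighted CDF reaches `level`.  With unit weights this is the ordinary
#' type-1 empirical quantile.
#'
#' @param values Numeric (typically integer) sample.
#' @param weights Non-negative weights, recycled if scalar.
#' @param level Probability level(s) in (0, 1).
#' @return Value(s) from `values`, one per level.
#' @examples
#' weighted_quantile(c(1, 2, 3), c(1, 1, 2), 0.5)  # 2
#' @export
weighted_quantile <- function(values, weights = 1, level) {
  if (length(weights) == 1) weights <- rep(weights, length(values))
  stopifnot(length(values) == length(weights),
            all(weights >= 0), any(weights > 0),
            all(level > 0), all(level < 1))
  o <- order(values)
  v <- values[o]
  cdf <- cumsum(weights[o]) / sum(weights)
  vapply(level, function(p) v[which(cdf >= p - 1e-12)[1]], values[1])
}

#' Weighted mode of an integer sample
#'
#' The value carrying the largest total weight; ties broken toward the
#' smaller value.
#'
#' @inheritParams weighted_quantile
#' @return A single value.
#' @export
weighted_mode <- function(values, weights = 1) {
  if (length(weights) == 1) weights <- rep(weights, length(values))
  stopifnot(length(values) == length(weights))
  tot <- vapply(split(weights, values), sum, numeric(1))
  vals <- as.numeric(names(tot))
  o <- order(vals)
  tot <- tot[o]; vals <- vals[o]
  vals[which.max(tot)]
}

#' Condition a simulated |Omega| sample on a database count
#'
#' Reweights the unconditional draws by [importance_weights()] and
#' summarises the conditional distribution of `|Omega|` given `m` copies of
#' Q's profile observed in a random database of size `n`.  A warning is
#' issued when the effective sample size falls below 5 percent of the draws, the
#' regime in which the importance-sampling approximation degrades (in
#' practice for counts above about 3).
#'
#' @param x A `ylineage_sim` object (see [ylineage_sim()]) or a numeric
#'   vector of `|Omega|` values (in which case `pis` must be supplied).
#' @param m,n Database count and size.
#' @param levels Quantile levels to report.
#' @param pis Match fractions, required when `x` is a plain vector.
#' @param ... Unused.
#' @return An object of class `ylineage_cond`: list with `m`, `n`,
#'   `weights`, `ess`, `quantiles`, `median`, `mode`, `n_draws`.
#' @export
condition_on_count <- function(x, m, n, levels = c(0.5, 0.95, 0.99), ...) {
  UseMethod("condition_on_count")
}

#' @rdname condition_on_count
#' @export
condition_on_count.default <- function(x, m, n, levels = c(0.5, 0.95, 0.99),
                                       pis, ...) {
  stopifnot(is.numeric(x), length(x) == length(pis))
  w <- importance_weights(pis, m, n)
  ess <- effective_sample_size(w)
  if (ess < 0.05 * length(w)) {
    warning("effective sample size ", round(ess, 1), " is below 5% of ",
            length(w), " draws; conditional summaries for m = ", m,
            " may be unreliable", call. = FALSE)
  }
  qs <- weighted_quantile(x, w, levels)
  names(qs) <- paste0("q", format(100 * levels, trim = TRUE))
  structure(
    list(m = m, n = n, weights = w, ess = ess, quantiles = qs,
         median = weighted_quantile(x, w, 0.5),
         mode = weighted_mode(x, w),
         n_draws = length(w)),
    class = "ylineage_cond"
  )
}

#' @rdname condition_on_count
#' @export
condition_on_count.ylineage_sim <- function(x, m, n,
                                            levels = c(0.5, 0.95, 0.99),
                                            ...) {
  condition_on_count(x$omega, m = m, n = n, levels = levels, pis = x$pi)
}

#' @export
print.ylineage_cond <- function(x, ...) {
  cat("conditional distribution of |Omega| given m =", x$m,
      "in a database of n =", x$n, "\n")
  cat("draws:", x$n_draws, "| ESS:", round(x$ess, 1),
      sprintf("(%.1f%%)", 100 * x$ess / x$n_draws), "\n")
  cat("median:", x$median, "| mode:", x$mode, "\n")
  cat("quantiles:", paste(names(x$quantiles), x$quantiles,
                          sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Conditioning by rejection sampling (cross-check)
#'
#' The direct Monte Carlo alternative to importance weighting: for every
#' simulated draw, a database of size `n` is sampled *without replacement*
#' from the live males and the draw is retained iff exactly `m` members of
#' its Omega are included.  Inefficient for `m > 1` but unbiased, so it
#' serves as the oracle against which the importance-sampling weights are
#' verified.  (The binomial weight of [importance_weights()] is the
#' `n << live_count` approximation to this without-replacement scheme.)
#'
#' @param x A `ylineage_sim` object, or a list of [match_set()] results.
#' @param m,n Database count and size (`n` at most the live count).
#' @param live For a list of match results: the vector of live ids.
#' @param ... Unused.
#' @return List with `accepted` (the retained `|Omega|` values, possibly
#'   empty), `acceptance_rate` and `n_tried`.
#' @export
condition_by_rejection <- function(x, m, n, ...) {
  UseMethod("condition_by_rejection")
}

#' @rdname condition_by_rejection
#' @export
condition_by_rejection.list <- function(x, m, n, live, ...) {
  stopifnot(n <= length(live), m <= n)
  keep <- vapply(x, function(mr) {
    db <- live[sample.int(length(live), n)]
    sum(db %in% mr$omega_ids) == m
  }, logical(1))
  acc <- vapply(x, function(mr) mr$omega_size, integer(1))[keep]
  list(accepted = acc, acceptance_rate = mean(keep), n_tried = length(x))
}

#' @rdname condition_by_rejection
#' @export
condition_by_rejection.ylineage_sim <- function(x, m, n, ...) {
  stopifnot(all(n <= x$live_count), m <= n)
  # sampling n live ids without replacement and intersecting with a fixed
  # subset of size |Omega| depends only on |Omega| and the live count, so
  # membership can be tested against the first |Omega| positions
  keep <- vapply(seq_along(x$omega), function(i) {
    sum(sample.int(x$live_count[i], n) <= x$omega[i]) == m
  }, logical(1))
  list(accepted = x$omega[keep], acceptance_rate = mean(keep),
       n_tried = length(x$omega))
}
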