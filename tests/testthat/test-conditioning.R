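test_that("importance weights are normalised binomial probabilities", {
  pis <- c(0.001, 0.01, 0.05)
  w <- importance_weights(pis, m = 0, n = 100)
  expect_equal(mean(w), 1)
  # m = 0: raw weight (1-pi)^n, so larger pi is downweighted
  expect_true(all(diff(w) < 0))
  raw <- (1 - pis)^100
  expect_equal(w, raw / mean(raw))

  # pi = 1 with m < n is impossible, weight 0
  w2 <- importance_weights(c(0.5, 1), m = 1, n = 10)
  expect_equal(w2[2], 0)

  # empty database: conditioning is vacuous
  expect_equal(importance_weights(pis, m = 0, n = 0), rep(1, 3))

  # log-space computation survives scales that underflow naively
  w3 <- importance_weights(c(1e-8, 2e-8), m = 2, n = 1e6)
  expect_true(all(is.finite(w3)))
  expect_equal(mean(w3), 1)

  # no compatible draw at all is a hard error
  expect_error(importance_weights(c(1, 1), m = 0, n = 5), "more simulations")
})

test_that("effective sample size follows (sum w)^2 / sum w^2", {
  expect_equal(effective_sample_size(rep(0.3, 50)), 50)
  expect_equal(effective_sample_size(c(0, 0, 7)), 1)
  expect_equal(effective_sample_size(c(2, 1, 1)), 16 / 6)
})

test_that("weighted quantiles are the left-continuous inverse CDF", {
  expect_equal(weighted_quantile(c(1, 2, 3), c(1, 1, 2), 0.5), 2)
  # unit weights reproduce the type-1 empirical quantile
  set.seed(11)
  x <- rpois(500, 8)
  for (p in c(0.25, 0.5, 0.95)) {
    expect_equal(weighted_quantile(x, 1, p),
                 as.vector(quantile(x, p, type = 1)))
  }
  # monotone in the level
  w <- runif(500)
  expect_gte(weighted_quantile(x, w, 0.99), weighted_quantile(x, w, 0.95))

  # weighted mode: maximal total weight, ties to the smaller value
  expect_equal(weighted_mode(c(1, 2, 3), c(2, 1, 2)), 1)
  expect_equal(weighted_mode(c(5, 5, 9), c(1, 2, 1)), 5)
})

test_that("rejection sampling acceptance matches hypergeometric odds", {
  # 2000 identical draws with |Omega| = 5 among 50 live males, n = 10
  live <- 1:50
  omega <- 1:5
  draws <- replicate(2000, list(omega_ids = omega, omega_size = 5L),
                     simplify = FALSE)
  set.seed(21)
  for (m in 0:2) {
    res <- condition_by_rejection(draws, m = m, n = 10, live = live)
    p <- dhyper(m, 5, 45, 10)
    se <- sqrt(p * (1 - p) / 2000)
    expect_lt(abs(res$acceptance_rate - p), 4 * se)
    expect_true(all(res$accepted == 5))
  }
  # m = 0 with the whole live set in the database is impossible: |Omega| >= 1
  res <- condition_by_rejection(draws, m = 0, n = 50, live = live)
  expect_length(res$accepted, 0)
})

test_that("importance sampling agrees with the rejection oracle", {
  sim <- reference_sim_deltas()
  set.seed(22)
  for (m in 0:1) {
    rej <- condition_by_rejection(sim, m = m, n = 1000)
    expect_gt(length(rej$accepted), 200)
    cc <- condition_on_count(sim, m = m, n = 1000)
    expect_lte(abs(cc$median - median(rej$accepted)), 3)
    q95_rej <- quantile(rej$accepted, 0.95, type = 1)
    expect_lt(abs(cc$quantiles[["q95"]] - q95_rej) / q95_rej, 0.15)
  }
})

test_that("conditional |Omega| is stochastically increasing in m and the
           weights degrade as m grows", {
  sim <- reference_sim_large()
  cond <- lapply(0:3, function(m) {
    suppressWarnings(condition_on_count(sim, m = m, n = 1000))
  })
  med <- vapply(cond, function(x) x$median, numeric(1))
  q95 <- vapply(cond, function(x) x$quantiles[["q95"]], numeric(1))
  ess <- vapply(cond, function(x) x$ess, numeric(1))
  expect_true(all(diff(med) > 0))
  expect_true(all(diff(q95) > 0))
  expect_true(all(diff(ess) < 0))

  # conditioning on a zero count in a larger database pulls |Omega| down
  c_small <- condition_on_count(sim, m = 0, n = 100)
  c_big <- condition_on_count(sim, m = 0, n = 10000)
  expect_lt(c_big$quantiles[["q95"]], c_small$quantiles[["q95"]])
  expect_lte(c_big$median, c_small$median)

  # an ESS below 5% of the draws triggers the reliability warning
  expect_warning(condition_on_count(sim, m = 6, n = 1000), "unreliable")
})
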