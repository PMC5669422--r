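# toy three-generation pedigree used throughout:
#   founder 1 -> gen2: 2, 3 -> gen3: 4, 5 (sons of 2), 6, 7 (sons of 3)
# single locus; a mutation on the 1 -> 3 meiosis gives id 3 allele 1,
# inherited by 6 and 7 except a back-mutation on 3 -> 7
toy_matching <- function() {
  ped <- manual_pedigree(sizes = c(1, 2, 4),
                         father = list(c(1, 1), c(1, 1, 2, 2)),
                         live_generations = 3)
  hap <- manual_haplotypes(ped, list(
    matrix(0L, 1, 1),
    matrix(c(0L, 1L), 2, 1),
    matrix(c(0L, 0L, 1L, 0L), 4, 1)
  ))
  list(ped = ped, hap = hap)
}

test_that("live males are the final generations", {
  ped <- simulate_pedigree(sim_config(N = 100, generations = 10, seed = 1))
  expect_length(live_males(ped), 300)
  expect_length(live_males(ped, live_generations = 11), sum(ped$sizes))

  gped <- simulate_pedigree(sim_config(N = 1000, growth = 1.02,
                                       generations = 2, seed = 2))
  # live males are exactly the final three generation sizes summed
  expect_length(live_males(gped), sum(gped$sizes))
  expect_equal(gped$sizes[3], 1000L)
  expect_error(live_males(ped, live_generations = 12))
})

test_that("Q is drawn uniformly with replacement", {
  live <- 101:110
  set.seed(3)
  q1 <- sample_q(live, 5)
  set.seed(3)
  expect_identical(sample_q(live, 5), q1)
  expect_identical(sample_q(42L), 42L)

  set.seed(4)
  draws <- sample_q(live, 1e4)
  expect_true(all(draws %in% live))
  chisq <- sum((table(draws) - 1e3)^2 / 1e3)
  expect_lt(chisq, qchisq(1 - 1e-5, df = 9))
})

test_that("match sets and meiotic distances agree with hand enumeration", {
  toy <- toy_matching()
  live <- live_males(toy$ped)
  expect_identical(live, 1:7)

  # allele-0 class: {1, 2, 4, 5, 7}; allele-1 class: {3, 6}
  ms <- match_set(toy$hap, toy$ped, q = 4)
  expect_identical(ms$omega_ids, c(1L, 2L, 4L, 5L, 7L))
  expect_equal(ms$omega_size, 5)
  expect_equal(ms$live_count, 7)
  expect_equal(ms$match_fraction, 5 / 7)
  # distances from 4: founder 2, father 1, brother 2, cousin 7 -> 4
  expect_identical(ms$deltas, c(2L, 1L, 2L, 4L))
  expect_equal(ms$cross_founder, 0)

  ms6 <- match_set(toy$hap, toy$ped, q = 6)
  expect_identical(ms6$omega_ids, c(3L, 6L))
  expect_identical(ms6$deltas, 1L)

  # two live males with different haplotypes exclude each other
  expect_false(6 %in% ms$omega_ids)
  expect_false(4 %in% ms6$omega_ids)
  expect_error(match_set(toy$hap, toy$ped, q = 99), "not a live male")
})

test_that("meiotic distance counts father-son steps to the MRCA", {
  toy <- toy_matching()
  ped <- toy$ped
  expect_equal(meioses_between(ped, 4, 4), 0)
  expect_equal(meioses_between(ped, 4, 2), 1)   # father
  expect_equal(meioses_between(ped, 2, 4), 1)   # symmetric
  expect_equal(meioses_between(ped, 4, 5), 2)   # brothers
  expect_equal(meioses_between(ped, 4, 3), 3)   # uncle
  expect_equal(meioses_between(ped, 4, 6), 4)   # cousin
  expect_equal(meioses_between(ped, 4, 1), 2)   # grandfather

  # two founders: descendants of different founders are unrelated
  ped2 <- manual_pedigree(sizes = c(2, 2), father = list(c(1, 2)),
                          live_generations = 2)
  expect_true(is.na(meioses_between(ped2, 3, 4)))
  expect_equal(meioses_between(ped2, 3, 1), 1)
})

test_that("matching is an equivalence and Omega is Q's class", {
  ped <- simulate_pedigree(sim_config(N = 200, generations = 30, vrs = 0.2,
                                      seed = 6))
  set.seed(7)
  hap <- assign_haplotypes(ped, rates = rep(0.03, 5))
  live <- live_males(ped)
  q <- sample_q(live)
  ms <- match_set(hap, ped, q)
  # every member's match set is the same set of ids
  for (other in sample(ms$omega_ids, min(5, ms$omega_size))) {
    expect_identical(match_set(hap, ped, other)$omega_ids, ms$omega_ids)
  }
})

test_that("sampling Q size-biases the match-class distribution", {
  ped <- simulate_pedigree(sim_config(N = 80, generations = 15, vrs = 0,
                                      seed = 8))
  set.seed(9)
  hap <- assign_haplotypes(ped, rates = rep(0.05, 4))
  live <- live_males(ped)
  # enumerate |Omega| for every possible Q: each class of size s
  # contributes s draws of value s
  sizes_by_q <- vapply(live, function(q) match_set(hap, ped, q)$omega_size,
                       integer(1))
  class_sizes <- table(sizes_by_q)  # value s appears s * (#classes of size s)
  for (s in as.integer(names(class_sizes))) {
    expect_equal(as.integer(class_sizes[[as.character(s)]]) %% s, 0)
  }
  expect_equal(sum(sizes_by_q == 1), sum(table(
    do.call(paste, c(as.data.frame(live_haplotypes(hap)), sep = ","))
  ) == 1))
})
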