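test_that("mutate_child applies the symmetric single-step model", {
  p <- c(3L, -2L, 0L)
  expect_identical(mutate_child(p, rates = rep(0, 3)), p)

  set.seed(41)
  forced <- mutate_child(p, rates = rep(1, 3))
  expect_true(all(abs(forced - p) == 1L))

  # rate 0.5: about half the meioses mutate, signs balanced
  set.seed(42)
  kids <- vapply(seq_len(2e4), function(i) mutate_child(0L, 0.5), integer(1))
  expect_lt(abs(mean(kids != 0L) - 0.5), 3 * 0.5 / sqrt(2e4))
  expect_lt(abs(mean(kids[kids != 0L] == 1L) - 0.5), 3 * 0.5 / sqrt(1e4))
})

test_that("founders are all-zero and steps are at most one per meiosis", {
  ped <- simulate_pedigree(sim_config(N = 60, generations = 8, vrs = 0.2,
                                      seed = 51))
  set.seed(52)
  hap <- assign_haplotypes(ped, rates = rep(0.2, 5), keep = "all")
  expect_true(all(hap$alleles[[1]] == 0L))
  for (g in 2:length(ped$sizes)) {
    step <- hap$alleles[[g]] - hap$alleles[[g - 1]][ped$father[[g]], ]
    expect_true(all(step %in% c(-1L, 0L, 1L)))
  }
})

test_that("zero rates propagate the founder haplotype to everyone", {
  ped <- simulate_pedigree(sim_config(N = 50, generations = 6, seed = 53))
  hap <- assign_haplotypes(ped, rates = rep(0, 4))
  expect_true(all(vapply(hap$alleles, function(a) all(a == 0L), logical(1))))
  q <- live_males(ped)[1]
  ms <- match_set(hap, ped, q)
  expect_equal(ms$omega_size, ms$live_count)
  expect_equal(ms$match_fraction, 1)
})

test_that("mutations accumulate as a lazy random walk along lineages", {
  ped <- parallel_chains_pedigree(chains = 1e4, G = 100)
  set.seed(61)
  hap <- assign_haplotypes(ped, rates = 0.1, keep = "all")
  final <- hap$alleles[[101]][, 1]

  # changes per chain ~ Binomial(G, r): mean G*r = 10
  changes <- Reduce(`+`, lapply(2:101, function(g) {
    hap$alleles[[g]][, 1] != hap$alleles[[g - 1]][, 1]
  }))
  expect_lt(abs(mean(changes) - 10) / 10, 0.05)

  # allele variance ~ G*r; marginal symmetric about the founder state
  expect_lt(abs(var(final) - 10) / 10, 0.1)
  expect_lt(abs(mean(final)), 3 * sd(final) / sqrt(1e4))
})

test_that("whole-generation overlay matches the per-meiosis loop", {
  ped <- simulate_pedigree(sim_config(N = 40, generations = 6, seed = 71))
  rates <- c(0.3, 0.05)
  loop_changes <- function() {
    tot <- 0L
    H <- matrix(0L, ped$sizes[1], 2)
    for (g in 2:7) {
      Hg <- t(vapply(seq_len(ped$sizes[g]), function(i) {
        mutate_child(H[ped$father[[g]][i], ], rates)
      }, integer(2)))
      tot <- tot + sum(Hg != H[ped$father[[g]], ])
      H <- Hg
    }
    tot
  }
  vec_changes <- function() {
    hap <- assign_haplotypes(ped, rates, keep = "all")
    sum(vapply(2:7, function(g) {
      sum(hap$alleles[[g]] != hap$alleles[[g - 1]][ped$father[[g]], ])
    }, numeric(1)))
  }
  set.seed(72)
  a <- replicate(150, loop_changes())
  b <- replicate(150, vec_changes())
  # both are Binomial(240 * 6, mean rate) counts; compare means
  se <- sqrt(var(a) / 150 + var(b) / 150)
  expect_lt(abs(mean(a) - mean(b)), 4 * se)
})

test_that("pruned live-only overlay agrees with the full overlay", {
  ped <- simulate_pedigree(sim_config(N = 300, generations = 40, vrs = 0.2,
                                      seed = 81))
  rates <- rep(0.05, 6)
  set.seed(82)
  sum_full <- replicate(40, {
    h <- assign_haplotypes(ped, rates, keep = "all")
    mean(abs(live_haplotypes(h)))
  })
  sum_live <- replicate(40, {
    h <- assign_haplotypes(ped, rates, keep = "live")
    mean(abs(live_haplotypes(h)))
  })
  se <- sqrt(var(sum_full) / 40 + var(sum_live) / 40)
  expect_lt(abs(mean(sum_full) - mean(sum_live)), 4 * se)

  # and the live matrices have identical shape either way
  h1 <- assign_haplotypes(ped, rates, keep = "all")
  h2 <- assign_haplotypes(ped, rates, keep = "live")
  expect_identical(dim(live_haplotypes(h1)), dim(live_haplotypes(h2)))
})

test_that("founder-to-live lineages almost never escape mutation at
           modern-kit rates over 250 generations", {
  rates <- posterior_mean_rates(ystr_kit("yfiler_plus"))
  ped <- parallel_chains_pedigree(chains = 500, G = 250)
  set.seed(91)
  hap <- assign_haplotypes(ped, rates, keep = "all")
  changed <- Reduce(`+`, lapply(2:251, function(g) {
    rowSums(hap$alleles[[g]] != hap$alleles[[g - 1]]) > 0
  }))
  expect_lt(mean(changed == 0), 0.01)
})

test_that("live haplotypes export to CSV", {
  ped <- simulate_pedigree(sim_config(N = 20, generations = 4, seed = 95))
  set.seed(96)
  kit <- ystr_kit("yfiler")
  hap <- assign_haplotypes(ped, sample_rates(kit))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_live_haplotypes(hap, ped, path)
  df <- read.csv(path, check.names = FALSE)
  expect_equal(nrow(df), length(live_males(ped)))
  expect_equal(names(df), c("id", kit$locus))
})
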