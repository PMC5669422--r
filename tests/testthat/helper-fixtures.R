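# Shared fixtures.  The expensive reference simulations are computed once
# per test run and memoised; all fixtures are generated in code.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, fn) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, fn(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# desk-scale grid over the three kits and three VRS values, constant N
reference_grid <- function() {
  cached_fixture("grid", function() {
    run_grid(kits = c("yfiler", "ppy23", "yfiler_plus"),
             vrs_values = c(0, 0.2, 1), growth_rates = 1,
             N = 1e4, genealogies = 2, mutation_runs = 20, q_draws = 500,
             seed = 42)
  })
}

grid_sim <- function(kit, vrs) {
  g <- reference_grid()
  attr(g, "sims")[[which(g$kit == kit & g$vrs == vrs)]]
}

# constant N = 1e5 ensemble matching the demography of the conditional
# (database-count) result tables
reference_sim_large <- function() {
  cached_fixture("large", function() {
    ylineage_sim("yfiler_plus", config = sim_config(N = 1e5, vrs = 0.2),
                 genealogies = 2, mutation_runs = 10, q_draws = 1000,
                 seed = 11)
  })
}

# reference run with meiotic distances recorded
reference_sim_deltas <- function() {
  cached_fixture("deltas", function() {
    ylineage_sim("yfiler_plus", config = sim_config(N = 1e4, vrs = 0.2),
                 genealogies = 1, mutation_runs = 10, q_draws = 500,
                 seed = 5, record_deltas = TRUE)
  })
}

# a one-locus kit with given mutation/non-mutation counts
toy_kit <- function(x, y, prior_a = 1.5, prior_b = 200) {
  out <- data.frame(locus = paste0("L", seq_along(x)), x = x, y = y,
                    prior_a = prior_a, prior_b = prior_b,
                    stringsAsFactors = FALSE)
  attr(out, "kit_name") <- "toy"
  class(out) <- c("ystr_kit", "data.frame")
  out
}

# hand-built pedigree: sizes is the per-generation size vector, father a
# list of father-index vectors (father[[g]] indexes generation g-1)
manual_pedigree <- function(sizes, father, live_generations = 3,
                            vrs = 0) {
  sizes <- as.integer(sizes)
  cfg <- sim_config(N = sizes[length(sizes)], generations = length(sizes) - 1,
                    vrs = vrs,
                    live_generations = min(live_generations, length(sizes)))
  structure(
    list(sizes = sizes,
         father = c(list(NULL), lapply(father, as.integer)),
         offsets = c(0L, cumsum(sizes))[seq_along(sizes)],
         config = cfg),
    class = "pedigree"
  )
}

# hand-built haplotype assignment on a manual pedigree; alleles is a list
# of integer matrices, one per generation
manual_haplotypes <- function(ped, alleles) {
  structure(
    list(alleles = lapply(alleles, function(a) {
           m <- as.matrix(a); storage.mode(m) <- "integer"; m
         }),
         rates = rep(0, ncol(as.matrix(alleles[[1]]))),
         keep = "all", sizes = ped$sizes, config = ped$config,
         locus_names = NULL),
    class = "haplotypes"
  )
}

# a chain-of-parallel-lineages pedigree: `chains` independent father-son
# chains of `G` transitions (used for mutation-accumulation checks)
parallel_chains_pedigree <- function(chains, G) {
  manual_pedigree(rep(chains, G + 1),
                  replicate(G, seq_len(chains), simplify = FALSE),
                  live_generations = 1)
}
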