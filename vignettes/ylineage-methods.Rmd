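---
title: "Simulating the number of males with a matching Y-STR profile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the number of males with a matching Y-STR profile}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(ylineage)
```

## Why simulate |Ω|?

Y-STR haplotypes are transmitted without recombination, so all the loci of
a profile behave as one allele.  Modern kits mutate fast enough (profile
mutation rates near or above 0.1 per meiosis) that matching profiles are
essentially confined to patrilineal clans spanning at most a few tens of
meioses, while being far too dispersed to enumerate as "known relatives".
The quantity this package estimates — the distribution of |Ω|, the number
of live males carrying the same profile as a queried male Q — is largely
invariant to the (ill-defined) population size, which is exactly what
makes it communicable to a court where a match probability is not.

## The simulation model

**Genealogy.**  Only males are modelled.  A pedigree is G + 1 generations
(founders first); each male of generation g draws his father independently
from generation g − 1 with probability proportional to that generation's
paternity weights.  Weights are mean-one and drawn fresh each generation
from a symmetric Dirichlet with parameter α = 1/VRS (persistent lifetime
weights would induce cross-generation correlation the model does not
intend).  For generations of at least 1000 men the Dirichlet draw is
realised as i.i.d. Gamma(α, rate α) variables without renormalisation: the
Dirichlet normalising sum concentrates at 1 at these sizes, and the two
constructions agree in distribution to well below Monte Carlo resolution;
below 1000 the exact normalised construction is used.  A paternity weight
w gives an offspring-count distribution close to Poisson(w), so the
offspring-count variance is ≈ 1 + VRS — the mixed-Poisson signature tested
in the suite, and the link between α = 5 and the observed offspring-count
SD ≈ 1.1 of modern populations.

**Demography.**  Two regimes: constant size N, and 2% growth per
generation.  Growth sizes are anchored at the *final* generation and
divided backwards (`round(N / 1.02^(G - g))`), since the final population
is the quantity with an empirical anchor; for N = 10^6 over 250
generations this yields 7,079 founders.  Configurations whose founder
generation would drop below 2 males are rejected as degenerate.

**Mutation.**  Founders are all-zero; each meiosis mutates each locus
entry independently with its locus rate, stepping ±1 with equal
probability.  Alleles are unbounded signed integers relative to the
founder state — the single-step model has no boundary, and only net allele
differences matter for matching.  Per-locus rates come from mutation-count
data: x mutations in x + y meioses combine with a Beta(1.5, 200) prior to
a Beta(x + 1.5, y + 200) posterior, and rates are resampled from their
posteriors once per mutation run (not per genealogy and not per meiosis),
so rate uncertainty is propagated at the replication level where it
belongs.  Duplicated loci (DYS385, DYF387S1) are split into a/b entries
sharing one count model but sampled and mutated independently; a reported
odd mutation count is halved to a half-integer Beta update rather than
rounded, conserving the information exactly (Beta parameters need not be
integers).

**Matching.**  The final three generations are "live".  Q is uniform over
live males, which size-biases the sampled match class — intentionally: the
queried person is a random *person*, not a random *class*.  Ω is Q's exact
whole-haplotype equivalence class among live males.  Meiotic distances Δ
are computed by an ancestor-path walk with depth alignment; a match
between descendants of distinct founders has no within-pedigree distance
and is flagged "unrelated" rather than given an arbitrary value.  Such
cross-founder matches are an artefact of all founders sharing the zero
haplotype; the audit in the test suite confirms none occur at Yfiler Plus
rates in reference runs.

**Database conditioning.**  Given m copies of Q's profile in a database of
size n sampled randomly from the live males, the unconditional draws are
importance-reweighted by the binomial probability
C(n, m) π^m (1 − π)^(n−m), where π is that draw's match fraction, computed
in log space and normalised to average one.  The binomial form is the
n ≪ live-count approximation to the exact without-replacement
(hypergeometric) probability; the package also implements the honest
rejection sampler — sample a database, keep the draw iff exactly m members
of Ω are included — which the tests use as an oracle.  At the published
(m, n) scales with a live population of ~3 × 10^5 the two agree to within
Monte Carlo error.  Conditioning quality is diagnosed by the effective
sample size (Σw)²/Σw²; a warning fires below 5% of draws, the regime
(roughly m > 3) where conditional summaries become unreliable.  Note that
π depends on the live count, so conditional results for a given (m, n) are
*not* N-invariant: published-scale scenarios should be conditioned on
N = 10^5 simulations, while unconditional summaries are stable for
N above ~10^3.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `N` | 10^4 (desk) / 10^5 (conditional work) | final-generation male population |
| `growth` | 1 | per-generation growth factor (1.02 = 2%) |
| `generations` | 250 | father-son transitions; enough that unmutated founder-to-live lineages are vanishingly rare |
| `vrs` | 0.2 | variance of mean-one paternity weights |
| `live_generations` | 3 | generations counted as contemporary |
| `prior_a`, `prior_b` | 1.5, 200 | Beta prior on each locus rate |
| `genealogies × mutation_runs × q_draws` | 2 × 20 × 500 | replication hierarchy (desk scale); 5 × 100 × 1000 at full scale |

The desk-scale default (2 × 10^4 |Ω| draws at N = 10^4) reproduces the
full-scale unconditional quantiles to within a few percent in about half a
minute per kit/VRS combination on one CPU; the test suite runs the whole
three-kit × three-VRS grid at this scale.  Heavier profiles are a flag
away (`run_grid(..., genealogies = 5, mutation_runs = 100, q_draws = 1000,
N = 1e5)`).

## Numerical and design choices

* **Summary conventions** — match counts are integers, so the median is
  the lower middle order statistic, quantiles are type-1 (left-continuous
  inverse CDF), and the mode breaks ties toward the smaller value.  All
  summary paths route through the same weighted-quantile code (unit
  weights = unconditional).
* **Pruned overlay** — only lineages ancestral to the live generations
  receive haplotypes in the default runner; for a constant N = 10^4
  population this cuts the per-run work ~20-fold and is exactly
  distribution-preserving for live haplotypes (non-ancestral lineages
  cannot influence them).  The whole-generation vectorised mutation step
  is verified against a per-meiosis reference loop in the tests.
* **Hierarchical seeding** — a master seed spawns per-genealogy seeds,
  which spawn per-mutation-run seeds, so any sub-experiment can be
  reproduced in isolation and adding replicates does not disturb earlier
  ones.
* **Degenerate inputs** — zero mutation rates make Ω the whole live
  population (π = 1); an empty database (n = 0) leaves weights at 1; a
  conditioning request incompatible with every draw (all raw weights zero)
  is a hard error asking for more simulations rather than a silent NaN.
* **Mixtures** — for two-contributor mixtures the per-locus allele sets
  are presence/absence only (no peak heights), pairs are sampled uniformly
  among distinct live males, and duplicated-locus halves are compared
  positionally; the real-world unordered-pair ambiguity of duplicated loci
  is acknowledged but not modelled, consistent with the single-source
  matching.

## What the synthetic mutation counts do and do not show

The bundled count table is synthetic: per-locus rates are set to widely
published point estimates for the 27 kit loci, with realistic meiosis
totals, giving posterior-mean profile rates of ≈ 0.044 (Yfiler), ≈ 0.084
(PowerPlex Y23) and ≈ 0.134 (Yfiler Plus).  Because the |Ω| distribution
is driven almost entirely by the profile mutation rate and the demography,
results with these counts track published values closely; a user with an
authoritative count table (e.g. a current YHRD export) should pass it via
`load_mutation_counts()` and will get correspondingly updated posteriors.

More broadly, the simulation emulates neutral patrilineal demography with
exchangeable reproductive success.  It does not model geographic or social
clustering of clans, non-random database ascertainment, age structure,
migration, or population isolates — all of which push real databases away
from the random-sampling ideal, and all of which make the database-count
conditioning here an *optimistic* bound on the value of database
information.  Passing tests therefore validate the model's internal
consistency and its published-scale summaries, not the realism of any
particular census population.

## Known limitations

* The single-step symmetric mutation model ignores multi-step and
  length-dependent mutation; this matters only for matches with
  intervening cancelling mutations, a small minority.
* Cross-founder matches are possible in principle because founders share
  one haplotype; they are flagged and audited rather than silently
  counted.
* Importance-sampling summaries degrade rapidly for m > 3 (ESS collapse);
  the rejection sampler remains unbiased but slow there.
* The live population is a fixed window of three generations; fractional
  generation overlap is not modelled.
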