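Package: ylineage
Title: Simulation of Y-STR Haplotype Match Counts in Male Lineages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time Wright-Fisher simulation of patrilineal
    genealogies with variable reproductive success and population growth,
    overlaid with a neutral symmetric single-step mutation process at the
    Y-STR loci of common forensic profiling kits (Yfiler, PowerPlex Y23,
    Yfiler Plus). Approximates the distribution of the number of living
    males whose Y-chromosome profile matches that of a queried male,
    together with the meiotic distances separating matching males.
    Includes Bayesian (Beta posterior) uncertainty in locus mutation
    rates, importance-sampling reweighting to condition on a profile
    count in a randomly sampled database (with effective-sample-size
    diagnostics and a rejection-sampling cross-check), random-database
    haplotype-frequency summaries, and two-contributor mixture inclusion
    counts.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
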