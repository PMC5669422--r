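# The central Monte Carlo runner: replicated genealogies x mutation runs x
# Q draws, producing the sample of |Omega| values that all summaries are
# built from, plus the experiment grid over kits / VRS / growth models.

# integer-sample conventions used throughout the summary tables:
# median = lower middle order statistic (so the summary of an integer
# sample is an integer); quantiles are type-1 (left-continuous inverse
# CDF); mode = most frequent value, ties to the smaller.
.int_median <- function(x) sort(x)[floor((length(x) + 1) / 2)]

.int_quantile <- function(x, p) {
  as.vector(stats::quantile(x, p, type = 1, names = FALSE))
}

# hierarchical sub-seeding: one call consumes the current stream to produce
# n child seeds, so any sub-experiment can be re-run independently
.child_seeds <- function(n) sample.int(.Machine$integer.max - 1L, n)

#' Simulate the distribution of the number of matching live males
#'
#' The main entry point.  Replicates the full hierarchy: `genealogies`
#' independent pedigrees; for each pedigree, `mutation_runs` mutation
#' overlays, each starting by resampling every locus mutation rate from its
#' Beta posterior; and for each overlay, `q_draws` uniform selections of the
#' queried male Q, recording `|Omega|` (the number of live males with Q's
#' haplotype, Q included) and the match fraction `pi`.  With
#' `record_deltas = TRUE` the meiotic distances from Q to each other member
#' of Omega are recorded too, along with a count of cross-founder matches
#' (members unrelated to Q within the pedigree).
#'
#' Seeding is hierarchical: the master seed spawns one seed per genealogy,
#' each genealogy seed spawns one per mutation run, so sub-experiments are
#' independently reproducible.
#'
#' @param kit A [ystr_kit()] object or kit name.
#' @param config A [sim_config()] object (defaults to a constant population
#'   of `N = 1e4` over 250 generations with VRS 0.2, a scale at which the
#'   `|Omega|` distribution has stabilised in `N`).
#' @param genealogies,mutation_runs,q_draws Replication counts.  The
#'   default desk-scale profile 2 x 20 x 500 yields 2e4 draws; the full
#'   published-scale profile is 5 x 100 x 1000.
#' @param seed Master seed (integer) for the whole hierarchy.
#' @param record_deltas Record meiotic distances (costlier; needed for
#'   distance summaries and the cross-founder audit).
#' @return An object of class `ylineage_sim`: list with `omega` (integer
#'   vector of `|Omega|` draws), `pi`, `live_count`, `genealogy` and `run`
#'   indices per draw, `deltas` (integer vector pooled over draws, or
#'   `NULL`), `cross_founder` (count, or `NA`), `kit_name`, `config`,
#'   `call`.  Methods: `print`, `summary`, `quantile`, `plot`,
#'   [condition_on_count()], [condition_by_rejection()].
#' @examples
#' \donttest{
#' sim <- ylineage_sim("yfiler_plus",
#'                     config = sim_config(N = 2000, generations = 100,
#'                                         vrs = 0.2),
#'                     genealogies = 1, mutation_runs = 3, q_draws = 100,
#'                     seed = 1)
#' summary(sim)
#' }
#' @export
ylineage_sim <- function(kit = "yfiler_plus",
                         config = sim_config(N = 1e4, vrs = 0.2),
                         genealogies = 2, mutation_runs = 20,
                         q_draws = 500, seed = NULL,
                         record_deltas = FALSE) {
  if (!inherits(kit, "ystr_kit")) kit <- ystr_kit(kit)
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  gseeds <- .child_seeds(genealogies)
  total <- genealogies * mutation_runs * q_draws
  omega <- integer(total)
  pis <- numeric(total)
  livec <- integer(total)
  gidx <- integer(total)
  ridx <- integer(total)
  deltas <- if (record_deltas) vector("list", genealogies * mutation_runs)
  cross_founder <- if (record_deltas) 0L else NA_integer_
  k <- 0L
  for (i in seq_len(genealogies)) {
    set.seed(gseeds[i])
    ped <- .prune_pedigree(simulate_pedigree(config))
    live <- live_males(ped)
    nlive <- length(live)
    rseeds <- .child_seeds(mutation_runs)
    for (j in seq_len(mutation_runs)) {
      set.seed(rseeds[j])
      rates <- sample_rates(kit)
      hap <- assign_haplotypes(ped, rates, keep = "live")
      mc <- .match_classes(live_haplotypes(hap))
      qpos <- sample.int(nlive, q_draws, replace = TRUE)
      os <- mc$sizes[mc$cls[qpos]]
      rows <- k + seq_len(q_draws)
      omega[rows] <- os
      pis[rows] <- os / nlive
      livec[rows] <- nlive
      gidx[rows] <- i
      ridx[rows] <- j
      if (record_deltas) {
        dl <- vector("list", q_draws)
        for (d in seq_len(q_draws)) {
          if (os[d] > 1L) {
            members <- live[mc$cls == mc$cls[qpos[d]]]
            others <- members[members != live[qpos[d]]]
            dd <- .delta_to_members(ped, live[qpos[d]], others)
            cross_founder <- cross_founder + sum(is.na(dd))
            dl[[d]] <- dd[!is.na(dd)]
          }
        }
        deltas[[(i - 1L) * mutation_runs + j]] <-
          unlist(dl, use.names = FALSE)
      }
      k <- k + q_draws
    }
  }
  structure(
    list(omega = omega, pi = pis, live_count = livec,
         genealogy = gidx, run = ridx,
         deltas = if (record_deltas) unlist(deltas, use.names = FALSE),
         cross_founder = cross_founder,
         kit_name = attr(kit, "kit_name"),
         config = config,
         n_draws = total,
         call = match.call()),
    class = "ylineage_sim"
  )
}

#' Summary row of an unconditional |Omega| sample
#'
#' Median (lower middle order statistic), mode (most frequent value, ties
#' to the smaller) and the type-1 95th and 99th percentiles; the integer
#' conventions used in the result tables.  With unit weights this agrees
#' with [weighted_quantile()].
#'
#' @param draws Integer vector of `|Omega|` values, or a `ylineage_sim`
#'   object.
#' @return Named numeric vector `median`, `mode`, `q95`, `q99`.
#' @examples
#' summarize_unconditional(c(1, 1, 2, 5))
#' @export
summarize_unconditional <- function(draws) {
  if (inherits(draws, "ylineage_sim")) draws <- draws$omega
  stopifnot(is.numeric(draws), length(draws) >= 1)
  c(median = .int_median(draws),
    mode = weighted_mode(draws),
    q95 = .int_quantile(draws, 0.95),
    q99 = .int_quantile(draws, 0.99))
}

#' @export
print.ylineage_sim <- function(x, ...) {
  cat("simulated distribution of |Omega| (matching live males)\n")
  cat("kit:", x$kit_name, "| N =", x$config$N,
      "| growth =", x$config$growth, "| VRS =", x$config$vrs, "\n")
  cat("draws:", x$n_draws, "\n")
  s <- summarize_unconditional(x)
  cat("median:", s["median"], "| mode:", s["mode"],
      "| 95%:", s["q95"], "| 99%:", s["q99"], "\n")
  invisible(x)
}

#' @export
summary.ylineage_sim <- function(object, ...) {
  out <- list(
    kit_name = object$kit_name,
    config = object$config,
    n_draws = object$n_draws,
    unconditional = summarize_unconditional(object),
    delta_summary = if (!is.null(object$deltas) && length(object$deltas)) {
      c(median = .int_median(object$deltas),
        q95 = .int_quantile(object$deltas, 0.95),
        max = max(object$deltas),
        frac_below_50 = mean(object$deltas < 50))
    },
    cross_founder = object$cross_founder
  )
  class(out) <- "summary.ylineage_sim"
  out
}

#' @export
print.summary.ylineage_sim <- function(x, ...) {
  cat("kit:", x$kit_name, "| N =", x$config$N, "| growth =",
      x$config$growth, "| VRS =", x$config$vrs,
      "| draws:", x$n_draws, "\n")
  u <- x$unconditional
  cat("|Omega|: median", u["median"], "mode", u["mode"],
      "q95", u["q95"], "q99", u["q99"], "\n")
  if (!is.null(x$delta_summary)) {
    d <- x$delta_summary
    cat("Delta (meioses): median", d["median"], "q95", d["q95"],
        "max", d["max"],
        sprintf("(%.2f%% < 50)", 100 * d["frac_below_50"]), "\n")
    cat("cross-founder matches:", x$cross_founder, "\n")
  }
  invisible(x)
}

#' @export
quantile.ylineage_sim <- function(x, probs = c(0.5, 0.95, 0.99), ...) {
  stats::setNames(.int_quantile(x$omega, probs),
                  paste0("q", format(100 * probs, trim = TRUE)))
}

#' @export
plot.ylineage_sim <- function(x, ...) {
  graphics::hist(x$omega, breaks = seq(0.5, max(x$omega) + 0.5, by = 1),
                 main = paste0("|Omega| (", x$kit_name, ", VRS ",
                               x$config$vrs, ", growth ", x$config$growth,
                               ")"),
                 xlab = "number of matching live males", ...)
  invisible(x)
}

#' Count of cross-founder matches
#'
#' Matches between Q and a live male with no common patrilineal ancestor
#' within the pedigree are an artefact of all founders sharing the zero
#' haplotype; at realistic modern-kit rates over 250 generations they are
#' not expected to occur.  Requires a simulation run with
#' `record_deltas = TRUE`.
#'
#' @param sim A `ylineage_sim` object (or a list of them).
#' @return Integer count (`NA` if distances were not recorded).
#' @export
cross_founder_match_audit <- function(sim) {
  if (inherits(sim, "ylineage_sim")) return(sim$cross_founder)
  sum(vapply(sim, function(s) s$cross_founder, integer(1)))
}

#' Run an experiment grid over kits, VRS values and growth models
#'
#' One [ylineage_sim()] per combination, summarised as one row each
#' (the layout of the unconditional results tables).
#'
#' @param kits Character vector of kit names.
#' @param vrs_values Numeric vector of VRS values.
#' @param growth_rates Numeric vector of growth factors.
#' @param N Final-generation population size.
#' @param generations,live_generations Passed to [sim_config()].
#' @param genealogies,mutation_runs,q_draws Replication profile per
#'   combination.
#' @param seed Master seed; each combination gets its own child seed.
#' @param record_deltas Record meiotic distances for every combination.
#' @param counts Mutation-count table used for every kit.
#' @return A data frame of class `ylineage_grid` with columns `kit`,
#'   `growth`, `vrs`, `median`, `mode`, `q95`, `q99`, `n_draws` and, when
#'   distances are recorded, `delta_q95` and `cross_founder`; the
#'   underlying `ylineage_sim` objects are in `attr(, "sims")`.
#' @examples
#' \donttest{
#' g <- run_grid(kits = "yfiler_plus", vrs_values = c(0, 0.2),
#'               growth_rates = 1, N = 2000, generations = 100,
#'               genealogies = 1, mutation_runs = 3, q_draws = 200,
#'               seed = 1)
#' g
#' }
#' @export
run_grid <- function(kits = c("yfiler", "ppy23", "yfiler_plus"),
                     vrs_values = c(0, 0.2, 1),
                     growth_rates = 1,
                     N = 1e4, generations = 250, live_generations = 3,
                     genealogies = 2, mutation_runs = 20, q_draws = 500,
                     seed = NULL, record_deltas = FALSE,
                     counts = synthetic_mutation_counts()) {
  combos <- expand.grid(kit = kits, growth = growth_rates,
                        vrs = vrs_values, stringsAsFactors = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cseeds <- .child_seeds(nrow(combos))
  sims <- vector("list", nrow(combos))
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    cfg <- sim_config(N = N, growth = combos$growth[i],
                      generations = generations, vrs = combos$vrs[i],
                      live_generations = live_generations)
    sim <- ylineage_sim(ystr_kit(combos$kit[i], counts = counts),
                        config = cfg,
                        genealogies = genealogies,
                        mutation_runs = mutation_runs,
                        q_draws = q_draws, seed = cseeds[i],
                        record_deltas = record_deltas)
    sims[[i]] <- sim
    s <- summarize_unconditional(sim)
    row <- data.frame(kit = combos$kit[i], growth = combos$growth[i],
                      vrs = combos$vrs[i],
                      median = s[["median"]], mode = s[["mode"]],
                      q95 = s[["q95"]], q99 = s[["q99"]],
                      n_draws = sim$n_draws)
    if (record_deltas) {
      row$delta_q95 <- if (length(sim$deltas))
        .int_quantile(sim$deltas, 0.95) else NA_integer_
      row$cross_founder <- sim$cross_founder
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  attr(out, "sims") <- sims
  class(out) <- c("ylineage_grid", "data.frame")
  out
}

#' @export
print.ylineage_grid <- function(x, ...) {
  cat("|Omega| summaries per kit / growth / VRS combination\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
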