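# Random databases drawn from the simulated live population and their
# haplotype-frequency summaries (singleton/doubleton fractions, top counts).

#' Sample a random profile database from the live males
#'
#' Draws `n` live males uniformly without replacement and tabulates their
#' haplotypes.
#'
#' @param hap A [assign_haplotypes()] object.
#' @param n Database size, at most the number of live males.
#' @return A named integer vector of class `profile_counts`: one entry per
#'   distinct haplotype (name = comma-separated allele vector), counts
#'   summing to `n`, sorted decreasing.
#' @examples
#' ped <- simulate_pedigree(sim_config(N = 50, generations = 5, seed = 3))
#' hap <- assign_haplotypes(ped, rates = rep(0.05, 4))
#' sample_database(hap, n = 20)
#' @export
sample_database <- function(hap, n) {
  stopifnot(inherits(hap, "haplotypes"), n >= 1, n == round(n))
  H <- live_haplotypes(hap)
  if (n > nrow(H)) {
    stop("database size n = ", n, " exceeds the ", nrow(H),
         " live males", call. = FALSE)
  }
  H <- H[sample.int(nrow(H), n), , drop = FALSE]
  key <- do.call(paste, c(as.data.frame(H), sep = ","))
  counts <- sort(table(key), decreasing = TRUE)
  structure(stats::setNames(as.integer(counts), names(counts)),
            class = "profile_counts")
}

#' @export
print.profile_counts <- function(x, ...) {
  cat("profile database:", sum(x), "profiles,", length(x), "distinct\n")
  invisible(x)
}

#' Summarise a profile database
#'
#' Singleton fraction (profiles seen exactly once), doubleton fraction
#' (exactly twice) and the counts of the two most common profiles.  By
#' default the fractions are relative to the number of *distinct* profiles
#' in the database; `denominator = "database"` divides by the database size
#' `n` instead.
#'
#' @param counts A [sample_database()] result (or any named/plain integer
#'   count vector).
#' @param denominator `"profiles"` (default) or `"database"`.
#' @return An object of class `database_summary`: list with `n`,
#'   `n_profiles`, `singleton_fraction`, `doubleton_fraction`,
#'   `top_counts` (two largest counts, zero-padded) and `denominator`.
#' @examples
#' summarize_database(c(A = 1L, B = 1L, C = 2L))
#' @export
summarize_database <- function(counts, denominator = c("profiles",
                                                       "database")) {
  denominator <- match.arg(denominator)
  counts <- as.integer(counts)
  stopifnot(length(counts) >= 1, all(counts >= 1))
  n <- sum(counts)
  denom <- if (denominator == "profiles") length(counts) else n
  top <- sort(counts, decreasing = TRUE)
  structure(
    list(n = n,
         n_profiles = length(counts),
         singleton_fraction = sum(counts == 1L) / denom,
         doubleton_fraction = sum(counts == 2L) / denom,
         top_counts = c(top, 0L, 0L)[1:2],
         denominator = denominator),
    class = "database_summary"
  )
}

#' @export
print.database_summary <- function(x, ...) {
  cat("database of", x$n, "profiles,", x$n_profiles, "distinct\n")
  cat(sprintf("singletons: %.3f  doubletons: %.3f  (per %s)\n",
              x$singleton_fraction, x$doubleton_fraction, x$denominator))
  cat("two most common profile counts:", x$top_counts[1], "and",
      x$top_counts[2], "\n")
  invisible(x)
}

#' Replicated random-database summaries
#'
#' Emulates the replication scheme used to characterise simulated
#' databases: for each of several genealogies, several mutation-rate
#' draws, and several databases per draw, sample a database of size `n`
#' and summarise it.
#'
#' @param kit A [ystr_kit()] object or kit name.
#' @param config A [sim_config()] object.
#' @param n Database size.
#' @param genealogies,mutation_runs,databases Replication counts
#'   (10 x 10 x 10 = 1000 summaries at full scale).
#' @param denominator Passed to [summarize_database()].
#' @param seed Optional master seed.
#' @return A data frame with one row per database: replication indices,
#'   `singleton_fraction`, `doubleton_fraction`, `top1`, `top2`.
#' @export
replicate_database_summaries <- function(kit, config, n,
                                         genealogies = 10,
                                         mutation_runs = 10,
                                         databases = 10,
                                         denominator = "profiles",
                                         seed = NULL) {
  if (!inherits(kit, "ystr_kit")) kit <- ystr_kit(kit)
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", genealogies * mutation_runs * databases)
  k <- 0L
  for (i in seq_len(genealogies)) {
    ped <- .prune_pedigree(simulate_pedigree(config))
    for (j in seq_len(mutation_runs)) {
      hap <- assign_haplotypes(ped, sample_rates(kit), keep = "live")
      for (b in seq_len(databases)) {
        s <- summarize_database(sample_database(hap, n), denominator)
        k <- k + 1L
        rows[[k]] <- data.frame(
          genealogy = i, mutation_run = j, database = b,
          singleton_fraction = s$singleton_fraction,
          doubleton_fraction = s$doubleton_fraction,
          top1 = s$top_counts[1], top2 = s$top_counts[2]
        )
      }
    }
  }
  do.call(rbind, rows)
}
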