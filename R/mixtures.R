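# Two-contributor mixtures: live males whose haplotype consists entirely of
# alleles present in the mixed profile of two contributors cannot be
# excluded as a source; they split into exact matches of a contributor and
# "other included" males.

#' Mixed profile of two contributors
#'
#' The per-locus allele sets of a two-person mixture: at each locus entry
#' the set of the two contributors' alleles (size 1 or 2).  No dosage
#' information is modelled (presence/absence only).
#'
#' @param h1,h2 Integer haplotypes on the same kit (equal length).
#' @return Integer matrix with two rows (`lo`, `hi`) and one column per
#'   locus entry; equal rows denote a single-allele locus.
#' @examples
#' mixture_profile(c(0L, 0L), c(0L, 1L))
#' @export
mixture_profile <- function(h1, h2) {
  stopifnot(length(h1) == length(h2))
  rbind(lo = pmin(h1, h2), hi = pmax(h1, h2))
}

#' Count live males included in a two-contributor mixture
#'
#' A live male is *included* iff at every locus entry his allele lies in
#' the mixture's allele set; included males partition into exact matches of
#' contributor 1 or 2 and "other included" (included but matching neither
#' contributor exactly).  Both contributors are themselves exact matches.
#' Duplicated-locus halves are compared positionally, consistent with the
#' simulation treating them as independent loci.
#'
#' @param hap A [assign_haplotypes()] object.
#' @param ped The pedigree the haplotypes were assigned on.
#' @param contributors Two distinct live-male ids.
#' @return An object of class `mixture_result`: list with
#'   `contributor_ids`, `exact_match_count`, `other_included_count`,
#'   `included_count` (= exact + other).
#' @examples
#' ped <- simulate_pedigree(sim_config(N = 40, generations = 5, seed = 4))
#' hap <- assign_haplotypes(ped, rates = rep(0.05, 4))
#' live <- live_males(ped)
#' count_included(hap, ped, contributors = sample_q(live, 2))
#' @export
count_included <- function(hap, ped, contributors) {
  stopifnot(inherits(hap, "haplotypes"), inherits(ped, "pedigree"),
            length(contributors) == 2,
            contributors[1] != contributors[2])
  live <- live_males(ped)
  pos <- match(contributors, live)
  if (anyNA(pos)) {
    stop("contributors must be live males", call. = FALSE)
  }
  H <- live_haplotypes(hap)
  h1 <- H[pos[1], ]
  h2 <- H[pos[2], ]
  in1 <- H == matrix(h1, nrow(H), ncol(H), byrow = TRUE)
  in2 <- H == matrix(h2, nrow(H), ncol(H), byrow = TRUE)
  included <- rowSums(in1 | in2) == ncol(H)
  exact <- rowSums(in1) == ncol(H) | rowSums(in2) == ncol(H)
  structure(
    list(contributor_ids = contributors,
         exact_match_count = sum(exact),
         other_included_count = sum(included & !exact),
         included_count = sum(included)),
    class = "mixture_result"
  )
}

#' @export
print.mixture_result <- function(x, ...) {
  cat("two-contributor mixture (ids", x$contributor_ids[1], "and",
      x$contributor_ids[2], ")\n")
  cat("exact matches:", x$exact_match_count,
      "| other included:", x$other_included_count,
      "| total included:", x$included_count, "\n")
  invisible(x)
}

#' Distribution of mixture inclusion counts
#'
#' Repeatedly samples a uniform pair of distinct live males as mixture
#' contributors and records the exact-match and other-included counts,
#' across replicated genealogies and mutation runs.
#'
#' @param kit A [ystr_kit()] object or kit name.
#' @param config A [sim_config()] object.
#' @param genealogies,mutation_runs,draws Replication counts: `draws`
#'   contributor pairs per mutation run.
#' @param seed Optional master seed.
#' @return A data frame with one row per pair: replication indices,
#'   `exact`, `other_included`, `included`.
#' @export
sample_mixture_counts <- function(kit, config, genealogies = 2,
                                  mutation_runs = 10, draws = 100,
                                  seed = NULL) {
  if (!inherits(kit, "ystr_kit")) kit <- ystr_kit(kit)
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", genealogies * mutation_runs * draws)
  k <- 0L
  for (i in seq_len(genealogies)) {
    ped <- .prune_pedigree(simulate_pedigree(config))
    live <- live_males(ped)
    for (j in seq_len(mutation_runs)) {
      hap <- assign_haplotypes(ped, sample_rates(kit), keep = "live")
      for (d in seq_len(draws)) {
        pair <- live[sample.int(length(live), 2)]
        mr <- count_included(hap, ped, pair)
        k <- k + 1L
        rows[[k]] <- data.frame(
          genealogy = i, mutation_run = j, draw = d,
          exact = mr$exact_match_count,
          other_included = mr$other_included_count,
          included = mr$included_count
        )
      }
    }
  }
  do.call(rbind, rows)
}
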