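# Neutral symmetric single-step mutation overlay: every founder starts at
# the all-zero haplotype and each meiosis mutates each locus independently
# with its own rate, stepping the allele by +1 or -1 with equal probability.
# Alleles are unbounded signed integers relative to the founder state.

#' Mutate one child's haplotype from his father's
#'
#' Per locus, with probability `rates[i]` the allele moves one repeat unit
#' up or down with equal probability; otherwise it is copied.  Loci mutate
#' independently (the two halves of a duplicated locus are separate
#' entries and mutate independently).
#'
#' @param parent_alleles Integer vector, one allele per kit locus entry.
#' @param rates Per-locus mutation rates, same length.
#' @return Integer vector of the child's alleles.
#' @examples
#' mutate_child(c(0L, 0L, 0L), rates = c(0, 0, 0))  # identical copy
#' @export
mutate_child <- function(parent_alleles, rates) {
  stopifnot(length(parent_alleles) == length(rates),
            all(rates >= 0), all(rates <= 1))
  L <- length(rates)
  mut <- stats::runif(L) < rates
  step <- ifelse(stats::runif(L) < 0.5, -1L, 1L)
  as.integer(parent_alleles + ifelse(mut, step, 0L))
}

# one whole-generation step, vectorised: P is the parent-generation allele
# matrix, map gives each child's parent row
.mutate_generation <- function(P, map, rates) {
  H <- P[map, , drop = FALSE]
  k <- nrow(H)
  L <- length(rates)
  if (k == 0) return(H)
  mut <- matrix(stats::runif(k * L), k, L) <
    matrix(rates, k, L, byrow = TRUE)
  if (any(mut)) {
    step <- ifelse(stats::runif(sum(mut)) < 0.5, -1L, 1L)
    H[mut] <- H[mut] + step
  }
  H
}

#' Assign haplotypes to every individual in a pedigree
#'
#' Founders receive the all-zero haplotype; each non-founder is derived from
#' his father by the single-step mutation process, one whole generation at a
#' time.  With `keep = "live"` only the lineages ancestral to the live
#' generations are simulated and only the live generations' haplotypes are
#' stored, which is distributionally identical to the full overlay
#' restricted to those individuals (non-ancestral lineages cannot affect
#' them) and is the memory-efficient path used by [ylineage_sim()].
#'
#' @param ped A [simulate_pedigree()] pedigree.
#' @param rates Per-locus mutation rates (one per kit locus entry), e.g.
#'   from [sample_rates()].
#' @param keep `"all"` to store every generation's alleles, `"live"` to
#'   store the final `live_generations` only.
#' @return An object of class `haplotypes`: a list with `alleles` (a list
#'   of integer matrices per generation, `NULL` where not kept), `rates`,
#'   `keep` and the pedigree's `sizes`/`config`.
#' @examples
#' ped <- simulate_pedigree(sim_config(N = 20, generations = 4, seed = 1))
#' hap <- assign_haplotypes(ped, rates = rep(0.1, 3))
#' hap$alleles[[1]][1, ]  # founder: all zero
#' @export
assign_haplotypes <- function(ped, rates, keep = c("all", "live")) {
  stopifnot(inherits(ped, "pedigree"), is.numeric(rates),
            all(rates >= 0), all(rates <= 1))
  keep <- match.arg(keep)
  L <- length(rates)
  T <- length(ped$sizes)
  live_from <- T - ped$config$live_generations + 1L
  alleles <- vector("list", T)
  if (keep == "all") {
    P <- matrix(0L, ped$sizes[1], L)
    alleles[[1]] <- P
    for (g in 2:T) {
      P <- .mutate_generation(P, ped$father[[g]], rates)
      alleles[[g]] <- P
    }
  } else {
    ped <- .prune_pedigree(ped)
    P <- matrix(0L, length(ped$active[[1]]), L)
    if (live_from == 1L) alleles[[1]] <- P
    for (g in 2:T) {
      P <- .mutate_generation(P, ped$amap[[g]], rates)
      if (g >= live_from) alleles[[g]] <- P
    }
  }
  structure(
    list(alleles = alleles, rates = rates, keep = keep,
         sizes = ped$sizes, config = ped$config,
         locus_names = names(rates)),
    class = "haplotypes"
  )
}

#' @export
print.haplotypes <- function(x, ...) {
  cat("haplotype assignment:", length(x$rates), "loci,",
      length(x$sizes), "generations (stored:", x$keep, ")\n")
  cat("profile mutation rate:",
      signif(profile_mutation_rate(x$rates), 4), "\n")
  invisible(x)
}

#' Haplotypes of the live males
#'
#' Stacks the allele matrices of the final `live_generations` generations,
#' in generation order, with rows aligned to [live_males()] ids.
#'
#' @param hap A [assign_haplotypes()] object.
#' @return Integer matrix, one row per live male.
#' @export
live_haplotypes <- function(hap) {
  stopifnot(inherits(hap, "haplotypes"))
  T <- length(hap$sizes)
  gens <- (T - hap$config$live_generations + 1L):T
  do.call(rbind, hap$alleles[gens])
}

#' Export live haplotypes as CSV
#'
#' One row per live male (column `id` holds the global individual id), one
#' column per kit locus entry; plain-text interchange with
#' haplotype-frequency tooling.
#'
#' @param hap A [assign_haplotypes()] object.
#' @param ped The pedigree the haplotypes were assigned on.
#' @param path Output CSV path.
#' @export
write_live_haplotypes <- function(hap, ped, path) {
  H <- live_haplotypes(hap)
  colnames(H) <- if (!is.null(hap$locus_names)) hap$locus_names else
    paste0("locus", seq_len(ncol(H)))
  df <- data.frame(id = live_males(ped), H, check.names = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
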