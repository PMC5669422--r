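# Live population, the queried male Q, the match set Omega and meiotic
# distances Delta.

#' Global ids of the live males
#'
#' The males of the final `live_generations` generations are treated as the
#' contemporary ("live") population of potential profile sources.
#'
#' @param ped A [simulate_pedigree()] pedigree.
#' @param live_generations Number of final generations; defaults to the
#'   value in the pedigree's configuration.
#' @return Integer vector of global individual ids, generation order.
#' @export
live_males <- function(ped, live_generations = ped$config$live_generations) {
  stopifnot(inherits(ped, "pedigree"),
            live_generations >= 1, live_generations <= length(ped$sizes))
  T <- length(ped$sizes)
  gens <- (T - live_generations + 1L):T
  unlist(lapply(gens, function(g) ped$offsets[g] + seq_len(ped$sizes[g])),
         use.names = FALSE)
}

#' Sample the queried male Q
#'
#' Uniform draw among the live males; repeated draws are with replacement.
#'
#' @param live Integer vector of live ids (see [live_males()]).
#' @param n Number of draws.
#' @return Integer vector of sampled ids.
#' @export
sample_q <- function(live, n = 1) {
  stopifnot(length(live) >= 1, n >= 1)
  live[sample.int(length(live), n, replace = TRUE)]
}

# match-class labels and sizes for a live haplotype matrix; whole-haplotype
# exact equality over the ordered locus entries
.match_classes <- function(H) {
  key <- do.call(paste, c(as.data.frame(H), sep = ","))
  cls <- match(key, key[!duplicated(key)])
  list(cls = cls, sizes = tabulate(cls))
}

#' Meiotic distance between two males
#'
#' The number of father-son steps from `a` up to the most recent common
#' patrilineal ancestor plus the steps from `b` up to it; 0 iff `a == b`.
#' Males descending from distinct founders have no common ancestor within
#' the pedigree and yield `NA` ("unrelated").
#'
#' @param ped A pedigree.
#' @param a,b Global individual ids.
#' @return Non-negative integer, or `NA_integer_` if unrelated.
#' @examples
#' ped <- simulate_pedigree(sim_config(N = 10, generations = 3, seed = 1))
#' meioses_between(ped, 35, father_of(ped, 35))  # 1
#' @export
meioses_between <- function(ped, a, b) {
  stopifnot(inherits(ped, "pedigree"), length(a) == 1, length(b) == 1)
  if (a == b) return(0L)
  .delta_to_members(ped, a, b)
}

# Vectorised meiotic distances from q to each id in `members`.
# Walks ancestor paths with depth alignment; NA for cross-founder pairs.
.delta_to_members <- function(ped, q, members) {
  gq <- .id_generation(ped, q)
  # ancestor chain of q: qanc[g] = index of q's ancestor in generation g
  qanc <- integer(gq)
  qanc[gq] <- .id_index(ped, q, gq)
  if (gq > 1) {
    for (g in (gq - 1L):1L) qanc[g] <- ped$father[[g + 1L]][qanc[g + 1L]]
  }
  curg <- .id_generation(ped, members)
  cur <- .id_index(ped, members, curg)
  d <- integer(length(members))
  delta <- rep(NA_integer_, length(members))
  # bring members below q's generation level first
  while (any(curg > gq)) {
    i <- which(curg > gq)
    for (g in unique(curg[i])) {
      j <- i[curg[i] == g]
      cur[j] <- ped$father[[g]][cur[j]]
    }
    curg[i] <- curg[i] - 1L
    d[i] <- d[i] + 1L
  }
  active <- seq_along(members)
  repeat {
    hit <- active[cur[active] == qanc[curg[active]]]
    if (length(hit)) {
      delta[hit] <- d[hit] + (gq - curg[hit])
      active <- setdiff(active, hit)
    }
    if (!length(active)) break
    stop_ids <- active[curg[active] == 1L]
    if (length(stop_ids)) active <- setdiff(active, stop_ids)  # unrelated
    if (!length(active)) break
    for (g in unique(curg[active])) {
      j <- active[curg[active] == g]
      cur[j] <- ped$father[[g]][cur[j]]
    }
    curg[active] <- curg[active] - 1L
    d[active] <- d[active] + 1L
  }
  delta
}

#' Match set of a live male
#'
#' Finds Omega, the set of live males whose haplotype is identical (exact
#' integer equality at every kit locus entry) to that of `q`, including `q`
#' himself, together with the meiotic distance Delta from `q` to each other
#' member.  Cross-founder matches (possible in principle because all
#' founders share the zero haplotype) are reported with `NA` distance and
#' counted in `cross_founder`.
#'
#' @param hap A [assign_haplotypes()] object.
#' @param ped The pedigree the haplotypes were assigned on.
#' @param q Global id of a live male.
#' @return An object of class `match_result`: list with `q_id`,
#'   `omega_ids`, `omega_size`, `deltas` (length `omega_size - 1`),
#'   `cross_founder`, `live_count` and `match_fraction`
#'   (`omega_size / live_count`).
#' @examples
#' ped <- simulate_pedigree(sim_config(N = 30, generations = 5, seed = 2))
#' hap <- assign_haplotypes(ped, rates = rep(0.05, 4))
#' match_set(hap, ped, q = sample_q(live_males(ped)))
#' @export
match_set <- function(hap, ped, q) {
  stopifnot(inherits(hap, "haplotypes"), inherits(ped, "pedigree"))
  live <- live_males(ped)
  pos <- match(q, live)
  if (is.na(pos)) stop("q = ", q, " is not a live male", call. = FALSE)
  H <- live_haplotypes(hap)
  mc <- .match_classes(H)
  members <- live[mc$cls == mc$cls[pos]]
  others <- members[members != q]
  deltas <- if (length(others)) .delta_to_members(ped, q, others) else
    integer(0)
  structure(
    list(q_id = q,
         omega_ids = members,
         omega_size = length(members),
         deltas = deltas[!is.na(deltas)],
         cross_founder = sum(is.na(deltas)),
         live_count = length(live),
         match_fraction = length(members) / length(live)),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat("match set of live male", x$q_id, "\n")
  cat("|Omega| =", x$omega_size, "of", x$live_count,
      "live males (pi =", signif(x$match_fraction, 3), ")\n")
  if (length(x$deltas)) {
    cat("meiotic distances: min", min(x$deltas), "median",
        stats::median(x$deltas), "max", max(x$deltas), "\n")
  }
  if (x$cross_founder > 0) {
    cat("cross-founder matches (unrelated to Q):", x$cross_founder, "\n")
  }
  invisible(x)
}
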