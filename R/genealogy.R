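# Patrilineal Wright-Fisher pedigrees with variable reproductive success
# (symmetric Dirichlet paternity weights) and optional exponential growth.

#' Simulation configuration
#'
#' Collects the demographic parameters of a male-lineage simulation.
#' `vrs` is the variance of the mean-one relative paternity probabilities;
#' `vrs = 0` recovers the standard Wright-Fisher model (all weights equal),
#' while `vrs > 0` corresponds to a symmetric Dirichlet with parameter
#' `alpha = 1 / vrs` (alpha 5 for VRS 0.2, alpha 1 for VRS 1).
#'
#' @param N Final-generation population size (number of males).
#' @param growth Per-generation growth factor, `>= 1` (1 = constant size,
#'   1.02 = 2 percent growth).
#' @param generations Number of father-son transitions `G`; the pedigree has
#'   `G + 1` generations including the founders.  Default 250, enough that
#'   essentially every founder-to-present lineage carries several profile
#'   mutations at realistic kit rates.
#' @param vrs Variance in reproductive success (non-negative).
#' @param live_generations Number of final generations treated as "live"
#'   (contemporary, potential sources of a crime-scene profile); default 3,
#'   capped at `generations + 1` for very short simulations.
#' @param seed Optional integer seed stored with the configuration and
#'   applied by [simulate_pedigree()].
#' @return An object of class `sim_config`.
#' @examples
#' sim_config(N = 1000, growth = 1.02, generations = 10, vrs = 0.2)
#' @export
sim_config <- function(N, growth = 1, generations = 250, vrs = 0,
                       live_generations = min(3, generations + 1),
                       seed = NULL) {
  stopifnot(
    is.numeric(N), length(N) == 1, N >= 2, N == round(N),
    is.numeric(growth), length(growth) == 1, growth >= 1,
    is.numeric(generations), length(generations) == 1,
    generations >= 1, generations == round(generations),
    is.numeric(vrs), length(vrs) == 1, vrs >= 0,
    is.numeric(live_generations), live_generations >= 1,
    live_generations <= generations + 1
  )
  structure(
    list(N = as.integer(N), growth = growth,
         generations = as.integer(generations), vrs = vrs,
         dirichlet_param = if (vrs > 0) 1 / vrs else Inf,
         live_generations = as.integer(live_generations),
         seed = if (!is.null(seed)) as.integer(seed) else NULL),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("male-lineage simulation config: N =", x$N,
      "| growth =", x$growth,
      "| G =", x$generations,
      "| VRS =", x$vrs,
      "| live generations =", x$live_generations, "\n")
  invisible(x)
}

#' Per-generation population sizes
#'
#' Constant model: `G + 1` copies of `N`.  Growth model: sizes are anchored
#' at the final generation and divided backwards,
#' `s_g = round(N / growth^(G - g))` for `g = 0..G`, so the final generation
#' has exactly `N` males.
#'
#' @param config A [sim_config()] object.
#' @return Integer vector of length `generations + 1`, founders first.
#' @examples
#' generation_sizes(sim_config(N = 1000, growth = 1.02, generations = 1))
#' @export
generation_sizes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  G <- config$generations
  if (config$growth == 1) {
    sizes <- rep(config$N, G + 1L)
  } else {
    sizes <- as.integer(round(config$N / config$growth^(G - 0:G)))
  }
  if (sizes[1] < 2) {
    stop("initial generation size ", sizes[1],
         " < 2: degenerate pedigree (increase N or reduce growth/generations)",
         call. = FALSE)
  }
  sizes
}

#' Relative paternity weights under variable reproductive success
#'
#' Draws mean-one relative paternity probabilities for the `size` men of a
#' generation.  With `vrs = 0` all weights are exactly 1.  With `vrs > 0`
#' the weights are `size` times a symmetric Dirichlet(`1/vrs`) draw; for
#' large generations this is realised as i.i.d. Gamma(`alpha`, rate
#' `alpha`) draws without renormalisation (the Dirichlet normalising sum
#' concentrates at 1), while below 1000 men the exact Dirichlet
#' construction (normalised Gamma) is used.
#'
#' @param size Number of men in the generation.
#' @param vrs Variance in reproductive success.
#' @return Numeric vector of length `size` with mean (approximately) one.
#' @examples
#' draw_paternity_weights(4, vrs = 0)   # all ones
#' set.seed(1); w <- draw_paternity_weights(1e4, vrs = 0.2)
#' var(w)  # close to 0.2
#' @export
draw_paternity_weights <- function(size, vrs) {
  stopifnot(is.numeric(size), length(size) == 1, size >= 1,
            is.numeric(vrs), length(vrs) == 1, vrs >= 0)
  size <- as.integer(size)
  if (vrs == 0) return(rep(1, size))
  alpha <- 1 / vrs
  if (size < 1000) {
    g <- stats::rgamma(size, shape = alpha, rate = 1)
    size * g / sum(g)
  } else {
    stats::rgamma(size, shape = alpha, rate = alpha)
  }
}

#' Simulate a patrilineal pedigree
#'
#' Wright-Fisher simulation of fathers only: for each generation
#' `g = 1..G`, every male independently draws his father from generation
#' `g - 1` with probability proportional to that generation's paternity
#' weights; weights are redrawn independently for each generation.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `pedigree`: a list with elements `sizes`
#'   (per-generation sizes, founders first), `father` (for each generation
#'   `g >= 2`, the integer index of each male's father within generation
#'   `g - 1`), `offsets` (global-id offsets per generation) and `config`.
#'   Individuals are identified globally by `offsets[g] + index`.
#' @examples
#' ped <- simulate_pedigree(sim_config(N = 50, generations = 5, seed = 1))
#' ped
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  sizes <- generation_sizes(config)
  T <- length(sizes)
  father <- vector("list", T)
  for (g in 2:T) {
    w <- draw_paternity_weights(sizes[g - 1], config$vrs)
    father[[g]] <- sample.int(sizes[g - 1], sizes[g], replace = TRUE,
                              prob = w)
  }
  structure(
    list(sizes = sizes,
         father = father,
         offsets = c(0L, cumsum(sizes))[seq_len(T)],
         config = config),
    class = "pedigree"
  )
}

#' @export
print.pedigree <- function(x, ...) {
  cat("patrilineal pedigree:", length(x$sizes), "generations,",
      format(sum(x$sizes), big.mark = ","), "males",
      "(founders", x$sizes[1], "-> final", x$sizes[length(x$sizes)], ")\n")
  invisible(x)
}

#' @export
summary.pedigree <- function(object, ...) {
  T <- length(object$sizes)
  off <- tabulate(object$father[[T]], nbins = object$sizes[T - 1])
  out <- list(
    generations = T,
    n_individuals = sum(object$sizes),
    sizes_range = range(object$sizes),
    final_offspring_mean = mean(off),
    final_offspring_sd = stats::sd(off)
  )
  class(out) <- "summary.pedigree"
  out
}

#' @export
print.summary.pedigree <- function(x, ...) {
  cat("generations:", x$generations,
      "| individuals:", format(x$n_individuals, big.mark = ","), "\n")
  cat("generation sizes:", x$sizes_range[1], "-", x$sizes_range[2], "\n")
  cat("final-transition offspring count: mean",
      round(x$final_offspring_mean, 3),
      "sd", round(x$final_offspring_sd, 3), "\n")
  invisible(x)
}

# generation of a global id
.id_generation <- function(ped, id) {
  findInterval(id - 0.5, c(0, cumsum(ped$sizes)))
}

# within-generation index of a global id
.id_index <- function(ped, id, gen = .id_generation(ped, id)) {
  as.integer(id - ped$offsets[gen])
}

.global_id <- function(ped, gen, index) {
  ped$offsets[gen] + as.integer(index)
}

#' Father of an individual
#'
#' @param ped A [simulate_pedigree()] object.
#' @param id Global individual id.
#' @return Global id of the father, or `NA` for founders.
#' @export
father_of <- function(ped, id) {
  g <- .id_generation(ped, id)
  out <- rep(NA_integer_, length(id))
  nf <- g > 1
  out[nf] <- .global_id(ped, g[nf] - 1L,
                        mapply(function(gg, ii) ped$father[[gg]][ii],
                               g[nf], .id_index(ped, id[nf], g[nf])))
  out
}

#' Export / import a pedigree as TSV plus JSON metadata
#'
#' Writes a two-column TSV (`individual_id`, `father_id`, founders `NA`) and
#' a JSON sidecar (`<path>.json`) holding the generation sizes and the
#' configuration, sufficient to reconstruct the object exactly.
#'
#' @param ped A pedigree.
#' @param path Output TSV path.
#' @return `write_pedigree` returns `path` invisibly; `read_pedigree`
#'   returns a `pedigree` object.
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  ids <- seq_len(sum(ped$sizes))
  df <- data.frame(individual_id = ids, father_id = father_of(ped, ids))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(sizes = ped$sizes, config = unclass(ped$config))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- do.call(sim_config, c(
    meta$config[c("N", "growth", "generations", "vrs", "live_generations")],
    list(seed = meta$config$seed)
  ))
  df <- utils::read.delim(path)
  sizes <- as.integer(meta$sizes)
  offsets <- c(0L, cumsum(sizes))[seq_along(sizes)]
  father <- vector("list", length(sizes))
  for (g in seq_along(sizes)[-1]) {
    rows <- offsets[g] + seq_len(sizes[g])
    father[[g]] <- as.integer(df$father_id[rows] - offsets[g - 1])
  }
  structure(list(sizes = sizes, father = father, offsets = offsets,
                 config = cfg),
            class = "pedigree")
}

# Mark, for every generation, which individuals are ancestors of (or in) the
# live generations; returns the pedigree augmented with $active (indices per
# generation) and $amap (for g >= 2, position of each active individual's
# father within active[[g-1]]).  Used to restrict the mutation overlay to
# lineages that can reach a live male.
.prune_pedigree <- function(ped) {
  if (!is.null(ped$active)) return(ped)
  T <- length(ped$sizes)
  live_from <- T - ped$config$live_generations + 1L
  active <- vector("list", T)
  active[[T]] <- seq_len(ped$sizes[T])
  for (g in T:2) {
    anc <- unique(ped$father[[g]][active[[g]]])
    if (g - 1L >= live_from) anc <- union(anc, seq_len(ped$sizes[g - 1]))
    active[[g - 1L]] <- sort(anc)
  }
  amap <- vector("list", T)
  for (g in 2:T) {
    amap[[g]] <- match(ped$father[[g]][active[[g]]], active[[g - 1L]])
  }
  ped$active <- active
  ped$amap <- amap
  ped
}
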