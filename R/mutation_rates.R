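# Kit definitions, mutation-count data and the Beta posterior over
# per-locus mutation rates.

# Canonical (split) locus entries per kit.  Duplicated loci (DYS385,
# DYF387S1) appear as two entries sharing one mutation-count model.
.kit_loci <- list(
  yfiler = c(
    "DYS19", "DYS389I", "DYS389II", "DYS390", "DYS391", "DYS392", "DYS393",
    "DYS437", "DYS438", "DYS439", "DYS448", "DYS456", "DYS458", "DYS635",
    "YGATAH4", "DYS385a", "DYS385b"
  ),
  ppy23 = c(
    "DYS19", "DYS389I", "DYS389II", "DYS390", "DYS391", "DYS392", "DYS393",
    "DYS437", "DYS438", "DYS439", "DYS448", "DYS456", "DYS458", "DYS635",
    "YGATAH4", "DYS385a", "DYS385b",
    "DYS481", "DYS533", "DYS549", "DYS570", "DYS576", "DYS643"
  ),
  yfiler_plus = c(
    "DYS19", "DYS389I", "DYS389II", "DYS390", "DYS391", "DYS392", "DYS393",
    "DYS437", "DYS438", "DYS439", "DYS448", "DYS456", "DYS458", "DYS635",
    "YGATAH4", "DYS385a", "DYS385b",
    "DYS481", "DYS533", "DYS570", "DYS576",
    "DYS449", "DYS460", "DYS518", "DYS627", "DYF387S1a", "DYF387S1b"
  )
)

.duplicated_loci <- c("DYS385", "DYF387S1")

.canon_locus <- function(x) toupper(gsub("[^A-Za-z0-9]", "", x))

.canon_kit <- function(kit) {
  key <- tolower(gsub("[^A-Za-z0-9]", "", kit))
  out <- switch(key,
    yfiler = "yfiler",
    ppy23 = , powerplexy23 = , py23 = "ppy23",
    yfilerplus = "yfiler_plus",
    NULL
  )
  if (is.null(out)) {
    stop("unknown kit '", kit,
         "'; use one of 'yfiler', 'ppy23', 'yfiler_plus'", call. = FALSE)
  }
  out
}

#' Synthetic per-locus mutation-count table
#'
#' A stand-in for an aggregated father-son mutation-count table of the kind
#' curated by YHRD: for each of the 27 loci used by the Yfiler, PowerPlex Y23
#' and Yfiler Plus kits it lists a number of observed meioses and the number
#' of those in which a mutation occurred.  The counts are *synthetic*: they
#' are constructed so that the implied per-locus rates match widely published
#' point estimates (slow loci such as DYS392 and DYS438 near 3--5 x 10^-4,
#' rapidly mutating loci such as DYS518 and DYS576 above 10^-2), with meiosis
#' totals of realistic magnitude (larger for the long-established Yfiler
#' loci).  Duplicated loci (DYS385, DYF387S1) are reported as a single row;
#' the count and meioses are halved when the row is split into the a/b
#' entries (see [load_mutation_counts()]).
#'
#' @return A data frame with columns `locus`, `mutations`, `meioses`.
#' @seealso [load_mutation_counts()], [ystr_kit()]
#' @examples
#' head(synthetic_mutation_counts())
#' @export
synthetic_mutation_counts <- function() {
  data.frame(
    locus = c(
      "DYS19", "DYS389I", "DYS389II", "DYS390", "DYS391", "DYS392", "DYS393",
      "DYS385", "DYS437", "DYS438", "DYS439", "DYS448", "DYS456", "DYS458",
      "DYS635", "YGATAH4", "DYS481", "DYS533", "DYS549", "DYS570", "DYS576",
      "DYS643", "DYS449", "DYS460", "DYS518", "DYS627", "DYF387S1"
    ),
    mutations = c(
      120L, 115L, 162L, 110L, 127L, 24L, 55L,
      78L, 40L, 12L, 223L, 61L, 158L, 248L,
      122L, 95L, 74L, 62L, 60L, 214L, 247L,
      13L, 113L, 67L, 146L, 102L, 79L
    ),
    meioses = c(
      52000L, 46000L, 45000L, 50000L, 49000L, 47000L, 46000L,
      60000L, 40000L, 40000L, 42000L, 38000L, 36000L, 37000L,
      33000L, 34000L, 16000L, 15000L, 14000L, 17000L, 17500L,
      14000L, 9000L, 12000L, 8000L, 8000L, 10000L
    ),
    stringsAsFactors = FALSE
  )
}

# Validate a raw counts table and split duplicated loci into a/b entries.
# Returns a data.frame with columns locus (entry name), x (mutations),
# y (non-mutations); x and y may be half-integers for duplicated loci with
# odd reported counts (Beta parameters need not be integers, and fractional
# halving conserves the reported information exactly).
.split_mutation_counts <- function(counts) {
  need <- c("locus", "mutations")
  if (!all(need %in% names(counts))) {
    stop("mutation-count table must have columns 'locus' and 'mutations'",
         call. = FALSE)
  }
  mutations <- counts$mutations
  if ("meioses" %in% names(counts)) {
    total <- counts$meioses
  } else if ("non_mutations" %in% names(counts)) {
    total <- counts$mutations + counts$non_mutations
  } else {
    stop("mutation-count table needs a 'meioses' or 'non_mutations' column",
         call. = FALSE)
  }
  bad <- !is.finite(mutations) | !is.finite(total) |
    mutations < 0 | total < 0 | mutations != round(mutations) |
    total != round(total) | mutations > total
  if (any(bad)) {
    stop("invalid counts for locus ",
         paste(counts$locus[bad], collapse = ", "),
         ": counts must be non-negative integers with mutations <= meioses",
         call. = FALSE)
  }
  locus <- as.character(counts$locus)
  if (anyDuplicated(.canon_locus(locus))) {
    stop("duplicated locus rows in mutation-count table", call. = FALSE)
  }
  out_locus <- character(0)
  out_x <- numeric(0)
  out_y <- numeric(0)
  for (i in seq_along(locus)) {
    if (.canon_locus(locus[i]) %in% .canon_locus(.duplicated_loci)) {
      nm <- .duplicated_loci[.canon_locus(.duplicated_loci) ==
                               .canon_locus(locus[i])]
      out_locus <- c(out_locus, paste0(nm, c("a", "b")))
      out_x <- c(out_x, rep(mutations[i] / 2, 2))
      out_y <- c(out_y, rep((total[i] - mutations[i]) / 2, 2))
    } else {
      out_locus <- c(out_locus, locus[i])
      out_x <- c(out_x, mutations[i])
      out_y <- c(out_y, total[i] - mutations[i])
    }
  }
  data.frame(locus = out_locus, x = out_x, y = out_y,
             stringsAsFactors = FALSE)
}

#' Load a per-locus mutation-count table
#'
#' Reads a tab-separated table with a header row and columns `locus`,
#' `mutations` and either `meioses` (total meioses observed) or
#' `non_mutations`.  Duplicated loci (DYS385, DYF387S1) may be given as a
#' single row, in which case both the mutation count and the meioses are
#' halved to form the two independent a/b entries; an odd count yields
#' half-integer Beta updates rather than being rounded, which conserves the
#' reported information exactly.
#'
#' @param path Path to a TSV file.
#' @return A data frame with one row per (split) locus entry and columns
#'   `locus`, `x` (meioses with a mutation) and `y` (meioses without).
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' write.table(synthetic_mutation_counts(), tsv, sep = "\t",
#'             row.names = FALSE, quote = FALSE)
#' head(load_mutation_counts(tsv))
#' @export
load_mutation_counts <- function(path) {
  counts <- utils::read.delim(path, stringsAsFactors = FALSE)
  .split_mutation_counts(counts)
}

#' Construct a profiling-kit definition
#'
#' Selects the locus entries belonging to one of the three Y-STR profiling
#' kits and attaches mutation-count data and the Beta prior over each
#' locus's mutation rate.  After splitting duplicated loci into their a/b
#' halves, Yfiler has 17 entries, PowerPlex Y23 has 23 and Yfiler Plus
#' has 27.  The posterior for a locus with `x` mutations in `x + y` meioses
#' is Beta(`x + prior_a`, `y + prior_b`); both halves of a duplicated locus
#' share one count model but are sampled independently.
#'
#' @param kit Kit name: `"yfiler"`, `"ppy23"` (PowerPlex Y23) or
#'   `"yfiler_plus"` (case and punctuation insensitive).
#' @param counts A raw mutation-count table as returned by
#'   [synthetic_mutation_counts()], or an already split table from
#'   [load_mutation_counts()].
#' @param prior_a,prior_b Shape parameters of the Beta prior on each
#'   per-locus rate (default Beta(1.5, 200), a prior centred near typical
#'   Y-STR mutation rates).
#' @return An object of class `ystr_kit`: a data frame with columns
#'   `locus`, `x`, `y`, `prior_a`, `prior_b` and attribute `kit_name`.
#' @examples
#' kit <- ystr_kit("yfiler_plus")
#' nrow(kit)  # 27
#' @export
ystr_kit <- function(kit = c("yfiler", "ppy23", "yfiler_plus"),
                     counts = synthetic_mutation_counts(),
                     prior_a = 1.5, prior_b = 200) {
  if (length(kit) > 1) kit <- kit[1]
  kit <- .canon_kit(kit)
  stopifnot(is.numeric(prior_a), prior_a > 0, is.numeric(prior_b), prior_b > 0)
  if (!all(c("x", "y") %in% names(counts))) {
    counts <- .split_mutation_counts(counts)
  }
  entries <- .kit_loci[[kit]]
  idx <- match(.canon_locus(entries), .canon_locus(counts$locus))
  if (anyNA(idx)) {
    stop("mutation counts missing for locus ",
         paste(entries[is.na(idx)], collapse = ", "),
         " required by kit '", kit, "'", call. = FALSE)
  }
  out <- data.frame(
    locus = entries,
    x = counts$x[idx],
    y = counts$y[idx],
    prior_a = prior_a,
    prior_b = prior_b,
    stringsAsFactors = FALSE
  )
  attr(out, "kit_name") <- kit
  class(out) <- c("ystr_kit", "data.frame")
  out
}

#' @export
print.ystr_kit <- function(x, ...) {
  cat("Y-STR kit '", attr(x, "kit_name"), "' with ", nrow(x),
      " locus entries\n", sep = "")
  cat("posterior mean profile mutation rate:",
      signif(profile_mutation_rate(posterior_mean_rates(x)), 4), "\n")
  invisible(x)
}

#' Posterior mean mutation rate per locus entry
#'
#' @param kit A [ystr_kit()] object.
#' @return Named numeric vector of posterior means
#'   `(x + prior_a) / (x + y + prior_a + prior_b)`.
#' @export
posterior_mean_rates <- function(kit) {
  stopifnot(inherits(kit, "ystr_kit"))
  r <- (kit$x + kit$prior_a) / (kit$x + kit$y + kit$prior_a + kit$prior_b)
  names(r) <- kit$locus
  r
}

#' Sample per-locus mutation rates from their posteriors
#'
#' Draws one rate per kit locus entry from its Beta posterior
#' Beta(`x + prior_a`, `y + prior_b`).  The two halves of a duplicated locus
#' share the same posterior but are drawn independently.
#'
#' @param kit A [ystr_kit()] object.
#' @return Named numeric vector of rates in (0, 1).
#' @examples
#' set.seed(1)
#' rates <- sample_rates(ystr_kit("yfiler"))
#' @export
sample_rates <- function(kit) {
  stopifnot(inherits(kit, "ystr_kit"))
  r <- stats::rbeta(nrow(kit), kit$x + kit$prior_a, kit$y + kit$prior_b)
  names(r) <- kit$locus
  r
}

#' Whole-profile mutation rate
#'
#' The per-meiosis probability that a son's profile differs from his
#' father's anywhere, `1 - prod(1 - rates)`.  The simple sum of the
#' per-locus rates -- the usual first-order approximation -- is available
#' with `method = "sum"`.
#'
#' @param rates Numeric vector of per-locus rates in \[0, 1\].
#' @param method `"complement"` (default, exact under independence) or
#'   `"sum"`.
#' @return A single probability (or rate sum).
#' @examples
#' profile_mutation_rate(c(0.05, 0.05))  # 0.0975
#' @export
profile_mutation_rate <- function(rates, method = c("complement", "sum")) {
  method <- match.arg(method)
  stopifnot(is.numeric(rates), all(rates >= 0), all(rates <= 1))
  if (method == "sum") sum(rates) else 1 - prod(1 - rates)
}
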