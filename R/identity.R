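#' Detect synonym groups (identical multilocus genotypes)
#'
#' Two individuals are synonymous when the number of nuclear loci at which
#' both are typed and their genotypes differ is at most `max_mismatch`; with
#' the default `max_mismatch = 0` this is identity at every co-typed locus.
#' Synonymy is closed transitively into groups. Individuals typed at fewer
#' than `min_typed_frac` of the nuclear loci carry too little information to
#' match safely; they are flagged and never grouped.
#'
#' The implementation hashes complete multilocus genotypes (exact grouping in
#' linear time) and falls back to pairwise comparison only for individuals
#' with missing calls or when `max_mismatch > 0`; both paths feed a single
#' union-find closure.
#'
#' @param gm a [genotype_matrix()] with at least one nuclear locus.
#' @param max_mismatch maximum number of differing co-typed loci tolerated
#'   within a synonym group (default 0, i.e. exact identity).
#' @param min_typed_frac minimum fraction of typed nuclear loci an individual
#'   needs to take part in matching (default 0.5).
#' @return An object of class `synonym_partition`: list with `groups` (list
#'   of member-name vectors, each of size >= 2, ordered by first occurrence),
#'   `representatives` (first member of each group), `unique_individuals`
#'   (input order, non-representative members removed), `flagged`
#'   (under-typed names), `n_input` and `n_unique`.
#' @examples
#' nuc <- array(rep(c(150L, 152L), each = 3), dim = c(3, 1, 2))
#' gm <- genotype_matrix(c("A", "B", "C"), nuclear = nuc)
#' find_synonym_groups(gm)$n_unique  # all three share one genotype -> 1
#' @export
find_synonym_groups <- function(gm, max_mismatch = 0L, min_typed_frac = 0.5) {
  stopifnot(max_mismatch >= 0)
  n <- n_individuals(gm)
  loci <- nuclear_loci(gm)
  if (n == 0) {
    return(new_synonym_partition(list(), character(0), character(0), 0L))
  }
  if (length(loci) == 0) stop("at least one nuclear locus is required")
  nm <- individual_names(gm)

  # integer genotype codes per (individual, locus); NA = missing call
  key <- paste(gm$nuclear[, , 1], gm$nuclear[, , 2], sep = "/")
  code <- matrix(match(key, unique(key)), n, length(loci))
  code[is.na(gm$nuclear[, , 1])] <- NA_integer_

  n_typed <- rowSums(!is.na(code))
  eligible <- n_typed >= min_typed_frac * length(loci)
  flagged <- nm[!eligible]

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  # attach the larger root to the smaller so representatives follow input order
  link <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
    invisible(NULL)
  }

  elig_idx <- which(eligible)
  complete <- eligible & n_typed == length(loci)

  if (max_mismatch == 0 && any(complete)) {
    # hash path: identical complete genotypes collapse in one pass
    hashes <- apply(code[complete, , drop = FALSE], 1, paste, collapse = "|")
    for (grp in split(which(complete), hashes)) {
      if (length(grp) > 1) for (j in grp[-1]) link(grp[1], j)
    }
    pairwise_pool <- which(eligible & !complete)
    # incomplete individuals must be compared against everyone eligible
    for (i in pairwise_pool) {
      for (j in elig_idx) {
        if (j >= i && j %in% pairwise_pool) next
        if (i == j) next
        if (synonym_compatible(code, i, j, max_mismatch)) link(i, j)
      }
    }
  } else {
    for (a in seq_along(elig_idx)) {
      i <- elig_idx[a]
      for (b in seq_len(a - 1L)) {
        j <- elig_idx[b]
        if (synonym_compatible(code, i, j, max_mismatch)) link(i, j)
      }
    }
  }

  roots <- vapply(seq_len(n), find, 1L)
  comp <- split(seq_len(n), roots)
  comp <- comp[vapply(comp, length, 1L) > 1]
  comp <- comp[order(vapply(comp, min, 1L))]
  groups <- lapply(comp, function(i) nm[sort(i)])
  reps <- vapply(groups, `[[`, "", 1L)
  drop <- unlist(lapply(groups, `[`, -1L), use.names = FALSE)
  uniq <- nm[!nm %in% drop]
  new_synonym_partition(groups, reps, uniq, n, flagged)
}

# co-typed loci only; at least one co-typed locus is required to declare a match
synonym_compatible <- function(code, i, j, max_mismatch) {
  co <- !is.na(code[i, ]) & !is.na(code[j, ])
  if (!any(co)) return(FALSE)
  sum(code[i, co] != code[j, co]) <= max_mismatch
}

new_synonym_partition <- function(groups, reps, uniq, n_input,
                                  flagged = character(0)) {
  structure(list(groups = unname(groups), representatives = unname(reps),
                 unique_individuals = uniq, flagged = flagged,
                 n_input = n_input, n_unique = length(uniq)),
            class = "synonym_partition")
}

#' @export
print.synonym_partition <- function(x, ...) {
  cat("synonym_partition: ", length(x$groups), " groups covering ",
      sum(lengths(x$groups)), " of ", x$n_input, " individuals; ",
      x$n_unique, " unique genotypes\n", sep = "")
  for (i in seq_along(x$groups)) {
    cat(sprintf("  Syn-%d: %s\n", i, paste(x$groups[[i]], collapse = ", ")))
  }
  if (length(x$flagged)) {
    cat("  flagged (under-typed, not matched): ",
        paste(x$flagged, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Drop duplicate genotypes, keeping one representative per synonym group
#'
#' @param gm a [genotype_matrix()].
#' @param partition a [find_synonym_groups()] result computed from `gm`;
#'   computed on the fly when `NULL`.
#' @return A `genotype_matrix` retaining, in input order, the first-occurring
#'   member of each synonym group plus every ungrouped individual.
#' @export
dedupe <- function(gm, partition = NULL) {
  if (is.null(partition)) partition <- find_synonym_groups(gm)
  if (!inherits(partition, "synonym_partition")) {
    stop("`partition` must come from find_synonym_groups()")
  }
  missing_names <- setdiff(unlist(partition$groups), individual_names(gm))
  if (length(missing_names)) {
    stop("stale partition: individual(s) not in the matrix: ",
         paste(missing_names, collapse = ", "))
  }
  subset(gm, individuals = partition$unique_individuals)
}

#' Probability of identity at one locus
#'
#' The probability that two individuals drawn at random from a population in
#' Hardy-Weinberg proportions share the same single-locus genotype:
#' \deqn{PI = \sum_i p_i^4 + \sum_{i<j} (2 p_i p_j)^2 = 2 a_2^2 - a_4}
#' with \eqn{a_k = \sum_i p_i^k} (Paetkau et al. 1995). The small-sample
#' bias-corrected variant of Waits, Luikart & Taberlet (2001), with the
#' sample size taken in gene copies, is available with `unbiased = TRUE`;
#' the naive form is the default and the headline statistic.
#'
#' @param freqs an [allele_frequencies()] result with `n_genes > 0`.
#' @param unbiased use the bias-corrected estimator.
#' @return PI in (0, 1].
#' @export
pi_locus <- function(freqs, unbiased = FALSE) {
  p <- freqs$freqs
  if (length(p) == 0) stop("empty frequency table: locus has no typed copies")
  a2 <- sum(p^2); a3 <- sum(p^3); a4 <- sum(p^4)
  naive <- 2 * a2^2 - a4
  if (!unbiased) return(naive)
  n <- freqs$n_genes # sample size in gene copies
  if (n < 4) stop("unbiased PI needs at least 4 sampled gene copies")
  (n^3 * (2 * a2^2 - a4) - 2 * n^2 * (a3 + 2 * a2) +
      n * (9 * a2 + 2) - 6) / ((n - 1) * (n - 2) * (n - 3))
}

#' Probability of identity over a nuclear SSR panel
#'
#' Per-locus PI from the selected individuals' allele frequencies, the
#' arithmetic mean across loci, and the cumulative product across loci (the
#' discrimination power of the whole panel under locus independence). Loci
#' with no typed copies in the selection are excluded with a warning.
#'
#' @inheritParams allele_frequencies
#' @inheritParams pi_locus
#' @return An object of class `pi_result`: list with `per_locus` (data.frame
#'   locus/pi), `mean_pi` and `cumulative_pi`.
#' @export
pi_panel <- function(gm, individuals = NULL, groups = NULL, unbiased = FALSE) {
  gm <- subset(gm, individuals = individuals, groups = groups)
  loci <- nuclear_loci(gm)
  if (length(loci) == 0) stop("at least one nuclear locus is required")
  pis <- numeric(0)
  kept <- character(0)
  for (l in loci) {
    fr <- allele_frequencies(gm, l)
    if (fr$n_genes == 0) {
      warning("locus ", l, " has no typed copies; excluded from PI")
      next
    }
    pis <- c(pis, pi_locus(fr, unbiased = unbiased))
    kept <- c(kept, l)
  }
  if (!length(pis)) stop("no locus with typed copies")
  structure(list(per_locus = data.frame(locus = kept, pi = pis,
                                        stringsAsFactors = FALSE),
                 mean_pi = mean(pis), cumulative_pi = prod(pis)),
            class = "pi_result")
}

#' @export
print.pi_result <- function(x, ...) {
  rng <- range(x$per_locus$pi)
  cat(sprintf(
    "PI over %d loci: per-locus %.3f-%.3f (mean %.3f), cumulative %.3g\n",
    nrow(x$per_locus), rng[1], rng[2], x$mean_pi, x$cumulative_pi))
  invisible(x)
}
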