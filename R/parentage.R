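#' Role placeholders used in parentage records
#'
#' `PARENT_UNKNOWN` marks a role that could not be determined;
#' `PARENT_AMBIGUOUS` marks a seed/pollen call the chloroplast data cannot
#' decide (both candidate parents match the child's haplotype, or neither
#' does).
#' @export
PARENT_UNKNOWN <- "UNKNOWN"

#' @rdname PARENT_UNKNOWN
#' @export
PARENT_AMBIGUOUS <- "AMBIGUOUS"

# unordered diploid pairs at every nuclear locus for one individual
pair_of <- function(gm, who) {
  i <- match(who, individual_names(gm))
  if (is.na(i)) stop("unknown individual: ", who)
  cbind(gm$nuclear[i, , 1], gm$nuclear[i, , 2])
}

#' Loci excluding a parent-offspring relationship between two individuals
#'
#' A nuclear locus is a mismatch when both individuals are typed there and
#' share no allele (a true parent passes one allele to its offspring at
#' every locus). Loci with a missing call in either individual are excluded
#' from the comparison, not counted as mismatches.
#'
#' @param gm a [genotype_matrix()].
#' @param a,b individual names (`a != b`).
#' @return Character vector of mismatching locus names (possibly empty).
#' @export
pairwise_mismatches <- function(gm, a, b) {
  if (identical(a, b)) stop("`a` and `b` must differ")
  pa <- pair_of(gm, a)
  pb <- pair_of(gm, b)
  co <- !is.na(pa[, 1]) & !is.na(pb[, 1])
  share <- pa[, 1] == pb[, 1] | pa[, 1] == pb[, 2] |
    pa[, 2] == pb[, 1] | pa[, 2] == pb[, 2]
  nuclear_loci(gm)[which(co & !share)]
}

#' Screen single candidate parents by exclusion
#'
#' Retains the candidates whose mismatch count against the child is at most
#' `tol`. The customary tolerance of one locus absorbs genotyping errors,
#' null alleles and mutation.
#'
#' @param gm a [genotype_matrix()].
#' @param child child individual name.
#' @param candidates character vector of candidate parent names (must not
#'   contain the child).
#' @param tol maximum mismatching loci (default 1).
#' @return data.frame with columns `candidate`, `n_mismatch` and
#'   `mismatch_loci` (list column), sorted by mismatch count then name.
#' @export
find_candidate_parents <- function(gm, child, candidates, tol = 1L) {
  if (child %in% candidates) stop("`child` must not be among the candidates")
  if (!length(candidates)) {
    return(data.frame(candidate = character(0), n_mismatch = integer(0)))
  }
  mm <- lapply(candidates, function(p) pairwise_mismatches(gm, child, p))
  n_mm <- lengths(mm)
  keep <- n_mm <= tol
  ord <- order(n_mm[keep], candidates[keep])
  out <- data.frame(candidate = candidates[keep][ord],
                    n_mismatch = n_mm[keep][ord],
                    stringsAsFactors = FALSE)
  out$mismatch_loci <- I(mm[keep][ord])
  out
}

# loci where the child's two alleles cannot be drawn one from each parent
trio_incompatible_loci <- function(gm, child, p1, p2) {
  pc <- pair_of(gm, child)
  pa <- pair_of(gm, p1)
  pb <- pair_of(gm, p2)
  co <- !is.na(pc[, 1]) & !is.na(pa[, 1]) & !is.na(pb[, 1])
  in_a1 <- pc[, 1] == pa[, 1] | pc[, 1] == pa[, 2]
  in_a2 <- pc[, 2] == pa[, 1] | pc[, 2] == pa[, 2]
  in_b1 <- pc[, 1] == pb[, 1] | pc[, 1] == pb[, 2]
  in_b2 <- pc[, 2] == pb[, 1] | pc[, 2] == pb[, 2]
  ok <- (in_a1 & in_b2) | (in_a2 & in_b1)
  nuclear_loci(gm)[which(co & !ok)]
}

#' Screen candidate parent pairs by trio exclusion
#'
#' Over all unordered pairs of pairwise-compatible candidates (each with at
#' most `tol` pairwise mismatches against the child), a locus is
#' trio-incompatible when the child's two alleles cannot be produced by
#' taking one allele from each parent. Pairs with at most `tol`
#' trio-incompatible loci are returned. Self-pairs are excluded by default
#' (outcrossing species are self-incompatible).
#'
#' @inheritParams find_candidate_parents
#' @param allow_self also consider selfing pairs (p, p).
#' @return data.frame with columns `parent_1`, `parent_2`,
#'   `n_trio_incompatible` and `trio_incompatible_loci` (list column),
#'   sorted by incompatibility count then names.
#' @export
find_parent_pairs <- function(gm, child, candidates, tol = 1L,
                              allow_self = FALSE) {
  singles <- find_candidate_parents(gm, child, candidates, tol = tol)
  empty <- data.frame(parent_1 = character(0), parent_2 = character(0),
                      n_trio_incompatible = integer(0))
  cand <- singles$candidate
  prs <- if (length(cand) >= 2) combn(cand, 2, simplify = FALSE) else list()
  if (allow_self) prs <- c(prs, lapply(cand, function(p) c(p, p)))
  if (!length(prs)) return(empty)
  bad <- lapply(prs, function(pr)
    trio_incompatible_loci(gm, child, pr[1], pr[2]))
  n_bad <- lengths(bad)
  keep <- which(n_bad <= tol)
  if (!length(keep)) return(empty)
  p1 <- vapply(prs[keep], `[[`, "", 1L)
  p2 <- vapply(prs[keep], `[[`, "", 2L)
  ord <- order(n_bad[keep], p1, p2)
  out <- data.frame(parent_1 = p1[ord], parent_2 = p2[ord],
                    n_trio_incompatible = n_bad[keep][ord],
                    stringsAsFactors = FALSE)
  out$trio_incompatible_loci <- I(bad[keep][ord])
  out
}

#' Assign seed and pollen roles from chloroplast haplotypes
#'
#' The chloroplast is maternally inherited, so the parent whose haplotype
#' equals the child's is the seed parent and the other is the pollen parent.
#' When both candidate parents match the child's haplotype, or neither does,
#' the roles are ambiguous. A single-parent hypothesis gets a role only when
#' the comparison is decisive: match = seed parent, mismatch = pollen
#' parent. Any missing haplotype leaves both roles unknown.
#'
#' @param child child individual name.
#' @param parents character vector of one or two parent names.
#' @param haplotypes a [assign_haplotypes()] result covering child and
#'   parents.
#' @return list with `seed_parent` and `pollen_parent`: an individual name,
#'   [PARENT_AMBIGUOUS] or [PARENT_UNKNOWN].
#' @export
assign_roles <- function(child, parents, haplotypes) {
  stopifnot(length(parents) %in% 1:2)
  h <- haplotypes$haplotype
  need <- c(child, parents)
  if (!all(need %in% names(h)) || anyNA(h[need])) {
    return(list(seed_parent = PARENT_UNKNOWN, pollen_parent = PARENT_UNKNOWN))
  }
  hc <- h[[child]]
  match_par <- vapply(parents, function(p) h[[p]] == hc, TRUE)
  if (length(parents) == 2) {
    if (sum(match_par) == 1) {
      list(seed_parent = parents[match_par],
           pollen_parent = parents[!match_par])
    } else {
      list(seed_parent = PARENT_AMBIGUOUS, pollen_parent = PARENT_AMBIGUOUS)
    }
  } else {
    if (match_par) {
      list(seed_parent = parents, pollen_parent = PARENT_UNKNOWN)
    } else {
      list(seed_parent = PARENT_UNKNOWN, pollen_parent = parents)
    }
  }
}

#' Exclusion parentage over a set of children
#'
#' For each child, candidate parent pairs are screened first
#' ([find_parent_pairs()]); if at least one pair survives the best pair
#' (fewest trio-incompatible loci) is reported, otherwise the best surviving
#' single candidate ([find_candidate_parents()]), otherwise no parent. Seed
#' and pollen roles are taken from chloroplast haplotypes when provided.
#'
#' @param gm a [genotype_matrix()].
#' @param children character vector of child names.
#' @param candidates character vector of candidate parent names; for each
#'   child the child itself is dropped from its candidate set.
#' @param tol mismatch tolerance (default 1) applied to both pairwise and
#'   trio counts.
#' @param haplotypes optional [assign_haplotypes()] result for role
#'   assignment.
#' @return data.frame with one row per child: `child`, `parent_1`,
#'   `parent_2`, `seed_parent`, `pollen_parent`, `n_mismatch` (pairwise sum
#'   for a pair, single count otherwise), `n_trio_incompatible` and
#'   `n_alternative_pairs`.
#' @export
parentage_analysis <- function(gm, children, candidates, tol = 1L,
                               haplotypes = NULL) {
  rows <- lapply(children, function(ch) {
    cand <- setdiff(candidates, ch)
    pairs <- find_parent_pairs(gm, ch, cand, tol = tol)
    singles <- find_candidate_parents(gm, ch, cand, tol = tol)
    p1 <- PARENT_UNKNOWN; p2 <- PARENT_UNKNOWN
    n_mm <- NA_integer_; n_tri <- NA_integer_
    n_alt <- 0L
    if (nrow(pairs)) {
      p1 <- pairs$parent_1[1]; p2 <- pairs$parent_2[1]
      n_tri <- pairs$n_trio_incompatible[1]
      n_mm <- sum(singles$n_mismatch[singles$candidate %in% c(p1, p2)])
      n_alt <- nrow(pairs) - 1L
    } else if (nrow(singles)) {
      p1 <- singles$candidate[1]
      n_mm <- singles$n_mismatch[1]
    }
    roles <- list(seed_parent = PARENT_UNKNOWN, pollen_parent = PARENT_UNKNOWN)
    pars <- setdiff(c(p1, p2), PARENT_UNKNOWN)
    if (!is.null(haplotypes) && length(pars)) {
      roles <- assign_roles(ch, pars, haplotypes)
      roles <- lapply(roles, paste, collapse = "") # 1-element guarantees
    }
    data.frame(child = ch, parent_1 = p1, parent_2 = p2,
               seed_parent = roles$seed_parent,
               pollen_parent = roles$pollen_parent,
               n_mismatch = n_mm, n_trio_incompatible = n_tri,
               n_alternative_pairs = n_alt, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
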