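#' Observed heterozygosity
#'
#' Per nuclear locus, the fraction of typed individuals carrying two
#' distinct alleles; the mean is taken over loci with at least one typed
#' individual.
#'
#' @param gm a [genotype_matrix()].
#' @param individuals,groups optional selectors
#'   (see [subset.genotype_matrix()]).
#' @return list with `per_locus` (named numeric, `NA` for untyped loci) and
#'   `mean`.
#' @export
observed_het <- function(gm, individuals = NULL, groups = NULL) {
  gm <- subset(gm, individuals = individuals, groups = groups)
  loci <- nuclear_loci(gm)
  per <- vapply(loci, function(l) {
    a <- gm$nuclear[, l, 1]; b <- gm$nuclear[, l, 2]
    typed <- !is.na(a)
    if (!any(typed)) return(NA_real_)
    mean(a[typed] != b[typed])
  }, 1.0)
  list(per_locus = per, mean = mean(per, na.rm = TRUE))
}

#' Expected heterozygosity (Nei's gene diversity)
#'
#' Per locus, \eqn{H_E = 1 - \sum_i p_i^2} from the selection's allele
#' frequencies. `unbiased = TRUE` applies the small-sample correction
#' \eqn{2n/(2n - 1)} (n = typed individuals); the uncorrected form is the
#' default.
#'
#' @inheritParams observed_het
#' @param unbiased apply the small-sample correction.
#' @return list with `per_locus` (named numeric) and `mean`.
#' @export
expected_het <- function(gm, individuals = NULL, groups = NULL,
                         unbiased = FALSE) {
  gm <- subset(gm, individuals = individuals, groups = groups)
  loci <- nuclear_loci(gm)
  per <- vapply(loci, function(l) {
    fr <- allele_frequencies(gm, l)
    if (fr$n_genes == 0) return(NA_real_)
    he <- 1 - sum(fr$freqs^2)
    if (unbiased) he <- he * fr$n_genes / (fr$n_genes - 1)
    he
  }, 1.0)
  list(per_locus = per, mean = mean(per, na.rm = TRUE))
}

#' Fixation index from aligned per-locus heterozygosities
#'
#' Per locus \eqn{F = (H_E - H_O)/H_E} for loci with \eqn{H_E > 0};
#' monomorphic loci are excluded. The headline value is the mean of the
#' per-locus ratios; the pooled form
#' \eqn{(\bar H_E - \bar H_O)/\bar H_E} is also returned.
#'
#' @param ho,he per-locus numeric vectors (same loci, same order, e.g. the
#'   `per_locus` components of [observed_het()] and [expected_het()]).
#' @return list with `per_locus`, `mean` (NA with a warning when every locus
#'   is monomorphic) and `pooled`.
#' @export
fixation_index <- function(ho, he) {
  if (length(ho) != length(he)) stop("`ho` and `he` must be aligned")
  f <- ifelse(!is.na(he) & he > 0, (he - ho) / he, NA_real_)
  names(f) <- names(he)
  if (all(is.na(f))) {
    warning("all loci monomorphic: fixation index undefined")
    m <- NA_real_
  } else {
    m <- mean(f, na.rm = TRUE)
  }
  pooled <- if (mean(he, na.rm = TRUE) > 0) {
    (mean(he, na.rm = TRUE) - mean(ho, na.rm = TRUE)) / mean(he, na.rm = TRUE)
  } else NA_real_
  list(per_locus = f, mean = m, pooled = pooled)
}

#' Rarefaction allelic richness
#'
#' The expected number of distinct alleles in a random draw of
#' `g = 2 * n_ref` gene copies from the typed copies at a locus
#' (El Mousadik & Petit 1996; Hurlbert 1971):
#' \deqn{AR = \sum_i \left[1 - \binom{N - N_i}{g} / \binom{N}{g}\right]}
#' with N typed copies and N_i copies of allele i. Binomial coefficients are
#' evaluated in log space. Loci with fewer than `g` typed copies in the
#' selection are excluded with a warning.
#'
#' @inheritParams observed_het
#' @param n_ref rarefaction size in diploid individuals (default 9, i.e.
#'   g = 18 gene copies).
#' @return list with `per_locus` (named numeric, `NA` for excluded loci),
#'   `mean` and `g`.
#' @export
allelic_richness <- function(gm, individuals = NULL, groups = NULL,
                             n_ref = 9L) {
  gm <- subset(gm, individuals = individuals, groups = groups)
  g <- 2L * n_ref
  loci <- nuclear_loci(gm)
  per <- vapply(loci, function(l) {
    fr <- allele_frequencies(gm, l)
    if (fr$n_genes < g) return(NA_real_)
    rarefied_allele_count(fr$counts, g)
  }, 1.0)
  dropped <- names(per)[is.na(per)]
  if (length(dropped)) {
    warning("locus/loci with fewer than ", g, " typed gene copies excluded: ",
            paste(dropped, collapse = ", "))
  }
  list(per_locus = per, mean = mean(per, na.rm = TRUE), g = g)
}

# closed-form rarefaction; lchoose(N - Ni, g) = -Inf when N - Ni < g
rarefied_allele_count <- function(counts, g) {
  N <- sum(counts)
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}

#' Per-group diversity summary
#'
#' One row per qualifying group (at least `min_group_size` members):
#' number of cultivars, mean observed and expected heterozygosity, mean
#' rarefaction allelic richness and mean fixation index. Non-qualifying
#' groups are omitted with a message.
#'
#' @param gm a [genotype_matrix()].
#' @param groups group codes to consider (default: all groups in `gm`).
#' @param min_group_size smallest group size reported (default 9).
#' @param n_ref rarefaction size in individuals (see [allelic_richness()]).
#' @param unbiased_he use the small-sample-corrected expected
#'   heterozygosity.
#' @return data.frame with columns `group`, `n`, `Ho`, `He`, `AR`, `F`.
#' @export
group_summary <- function(gm, groups = NULL, min_group_size = 9L,
                          n_ref = 9L, unbiased_he = FALSE) {
  if (is.null(groups)) groups <- unique(gm$individuals$group)
  sizes <- table(gm$individuals$group)[groups]
  rows <- list()
  for (g in groups) {
    n <- as.integer(sizes[[g]])
    if (is.na(n) || n < min_group_size) {
      message("group ", g, " omitted (", if (is.na(n)) 0 else n,
              " < ", min_group_size, " cultivars)")
      next
    }
    ho <- observed_het(gm, groups = g)
    he <- expected_het(gm, groups = g, unbiased = unbiased_he)
    ar <- suppressWarnings(allelic_richness(gm, groups = g, n_ref = n_ref))
    fx <- suppressWarnings(fixation_index(ho$per_locus, he$per_locus))
    rows[[g]] <- data.frame(group = g, n = n, Ho = ho$mean, He = he$mean,
                            AR = ar$mean, F = fx$mean,
                            stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group = character(0), n = integer(0), Ho = numeric(0),
               He = numeric(0), AR = numeric(0), F = numeric(0))
  rownames(out) <- NULL
  out
}
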