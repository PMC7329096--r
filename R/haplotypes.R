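#' Assign chloroplast haplotypes from cpSSR allele combinations
#'
#' Individuals carrying the identical combination of alleles at every
#' chloroplast locus share a haplotype. Individuals with any missing
#' chloroplast call are left unassigned (`NA`) rather than fuzzily matched.
#' Labels `HAP1, HAP2, ...` are assigned in order of decreasing haplotype
#' frequency, ties broken by first occurrence. A reference map can pin an
#' established labelling: matching allele tuples take the reference labels
#' and novel tuples continue the numbering after the largest reference
#' number.
#'
#' @param gm a [genotype_matrix()] with at least one chloroplast locus.
#' @param reference optional named list (label -> integer vector of alleles,
#'   one per chloroplast locus, in `cp_loci(gm)` order) or a matrix with
#'   labels as row names and one column per chloroplast locus.
#' @return An object of class `haplotype_assignment`: list with `haplotype`
#'   (named character vector per individual, `NA` when unassigned),
#'   `definitions` (named list label -> named integer allele tuple) and
#'   `n_haplotypes`.
#' @export
assign_haplotypes <- function(gm, reference = NULL) {
  cps <- cp_loci(gm)
  if (length(cps) == 0) stop("no chloroplast loci in the matrix")
  n <- n_individuals(gm)
  nm <- individual_names(gm)
  complete <- if (n) rowSums(is.na(gm$cp)) == 0 else logical(0)
  tuple <- rep(NA_character_, n)
  tuple[complete] <- apply(gm$cp[complete, , drop = FALSE], 1,
                           paste, collapse = "-")

  seen <- tuple[complete]
  if (length(seen)) {
    freq <- table(seen)
    first <- match(names(freq), seen)
    ord <- order(-as.integer(freq), first)
    tuples_sorted <- names(freq)[ord]
  } else {
    tuples_sorted <- character(0)
  }

  labels <- character(0)
  defs <- list()
  next_num <- 1L
  if (!is.null(reference)) {
    if (is.matrix(reference)) {
      reference <- setNames(lapply(seq_len(nrow(reference)),
                                   function(i) reference[i, ]),
                            rownames(reference))
    }
    if (is.null(names(reference)) || any(names(reference) == "")) {
      stop("`reference` must be a named list of allele tuples")
    }
    bad <- vapply(reference, length, 1L) != length(cps)
    if (any(bad)) {
      stop("reference tuple(s) with wrong length: ",
           paste(names(reference)[bad], collapse = ", "))
    }
    ref_keys <- vapply(reference, paste, "", collapse = "-")
    nums <- suppressWarnings(as.integer(sub("^\\D*", "", names(reference))))
    next_num <- max(c(0L, nums), na.rm = TRUE) + 1L
  } else {
    ref_keys <- character(0)
  }

  for (tp in tuples_sorted) {
    hit <- which(ref_keys == tp)
    if (length(hit)) {
      lab <- names(ref_keys)[hit[1]]
    } else {
      lab <- paste0("HAP", next_num)
      next_num <- next_num + 1L
    }
    labels <- c(labels, lab)
    alleles <- as.integer(strsplit(tp, "-", fixed = TRUE)[[1]])
    defs[[lab]] <- setNames(alleles, cps)
  }

  hap <- setNames(labels[match(tuple, tuples_sorted)], nm)
  structure(list(haplotype = hap, definitions = defs,
                 n_haplotypes = length(defs)),
            class = "haplotype_assignment")
}

#' @export
print.haplotype_assignment <- function(x, ...) {
  cat("haplotype_assignment: ", x$n_haplotypes, " haplotypes over ",
      sum(!is.na(x$haplotype)), " assigned individuals (",
      sum(is.na(x$haplotype)), " unassigned)\n", sep = "")
  tab <- table(x$haplotype)
  for (lab in names(x$definitions)) {
    cat(sprintf("  %s (%s): n = %d\n", lab,
                paste(x$definitions[[lab]], collapse = "-"),
                as.integer(tab[lab])))
  }
  invisible(x)
}

#' Tabulate haplotype counts by cultivar group
#'
#' @param assignment a [assign_haplotypes()] result covering `gm`.
#' @param gm the [genotype_matrix()] providing group labels.
#' @return An integer matrix, groups (first-occurrence order) by haplotype
#'   labels; cell (g, h) counts the individuals of group g carrying h.
#'   Unassigned individuals are not counted, so row sums equal group sizes
#'   minus the unassigned.
#' @export
haplotype_table <- function(assignment, gm) {
  nm <- individual_names(gm)
  if (!all(nm %in% names(assignment$haplotype))) {
    stop("assignment does not cover every individual in the matrix")
  }
  hap <- assignment$haplotype[nm]
  grp <- gm$individuals$group
  glev <- unique(grp)
  hlev <- names(assignment$definitions)
  tab <- table(factor(grp, levels = glev), factor(hap, levels = hlev))
  mat <- matrix(as.integer(tab), nrow = length(glev),
                dimnames = list(group = glev, haplotype = hlev))
  mat
}
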