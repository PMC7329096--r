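#' Construct a genotype matrix
#'
#' The central container of the package: a table of individuals (cultivars)
#' typed at codominant nuclear SSR loci (two integer allele sizes per locus)
#' and haploid chloroplast SSR loci (one integer allele size per locus).
#' Nuclear allele pairs are unordered and stored canonically with the smaller
#' size first; a call with any missing half is treated as entirely missing
#' and stored as `NA`.
#'
#' @param individuals data.frame with at least columns `name` (unique cultivar
#'   name) and `group` (group code, e.g. `"J_KA"`); optional columns
#'   `accession` and `origin` are carried along. A plain character vector of
#'   names is accepted and assigned to a single group `"ALL"`.
#' @param nuclear integer array of dimension `n_individuals x n_loci x 2`
#'   holding allele sizes (> 0), with locus names on the second dimension.
#'   `NA` or 0 encodes a missing half-call. May be `NULL` for a matrix with
#'   no nuclear loci.
#' @param cp integer matrix `n_individuals x n_cp_loci` of haploid chloroplast
#'   allele sizes, with locus names as column names. `NA` or 0 is missing.
#'   May be `NULL`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `individuals`, `nuclear` (canonicalized array) and `cp`.
#' @examples
#' nuc <- array(c(150L, 150L, 152L, 150L), dim = c(2, 1, 2),
#'              dimnames = list(NULL, "LocusA", NULL))
#' gm <- genotype_matrix(c("A", "B"), nuclear = nuc)
#' nuclear_calls(gm, "LocusA")
#' @export
genotype_matrix <- function(individuals, nuclear = NULL, cp = NULL) {
  if (is.character(individuals)) {
    individuals <- data.frame(name = individuals,
                              group = rep("ALL", length(individuals)),
                              stringsAsFactors = FALSE)
  }
  if (!is.data.frame(individuals) ||
      !all(c("name", "group") %in% names(individuals))) {
    stop("`individuals` must be a data.frame with columns `name` and `group`")
  }
  individuals$name <- as.character(individuals$name)
  individuals$group <- as.character(individuals$group)
  rownames(individuals) <- NULL
  if (anyDuplicated(individuals$name)) {
    stop("duplicated cultivar names: ",
         paste(unique(individuals$name[duplicated(individuals$name)]),
               collapse = ", "))
  }
  n <- nrow(individuals)

  if (is.null(nuclear)) {
    nuclear <- array(NA_integer_, dim = c(n, 0, 2))
  }
  if (length(dim(nuclear)) != 3L || dim(nuclear)[3] != 2L) {
    stop("`nuclear` must be an n x loci x 2 array")
  }
  if (dim(nuclear)[1] != n) {
    stop("`nuclear` has ", dim(nuclear)[1], " rows but there are ",
         n, " individuals")
  }
  if (is.null(dimnames(nuclear)[[2]]) && dim(nuclear)[2] > 0) {
    dimnames(nuclear)[[2]] <- paste0("L", seq_len(dim(nuclear)[2]))
  }
  nuclear <- canonicalize_pairs(nuclear)
  dimnames(nuclear)[[1]] <- individuals$name

  if (is.null(cp)) {
    cp <- matrix(NA_integer_, nrow = n, ncol = 0)
  }
  cp <- as.matrix(cp)
  storage.mode(cp) <- "integer"
  if (nrow(cp) != n) {
    stop("`cp` has ", nrow(cp), " rows but there are ", n, " individuals")
  }
  if (is.null(colnames(cp)) && ncol(cp) > 0) {
    colnames(cp) <- paste0("cp", seq_len(ncol(cp)))
  }
  cp[!is.na(cp) & cp <= 0L] <- NA_integer_
  rownames(cp) <- individuals$name

  if (anyDuplicated(c(dimnames(nuclear)[[2]], colnames(cp)))) {
    stop("locus names must be unique across the nuclear and chloroplast panels")
  }

  structure(list(individuals = individuals, nuclear = nuclear, cp = cp),
            class = "genotype_matrix")
}

# sort each diploid pair low-first; any missing/non-positive half voids the call
canonicalize_pairs <- function(arr) {
  d <- dim(arr)
  a <- matrix(as.integer(arr[, , 1]), d[1], d[2])
  b <- matrix(as.integer(arr[, , 2]), d[1], d[2])
  bad <- is.na(a) | is.na(b) | a <= 0L | b <= 0L
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  lo[bad] <- NA_integer_
  hi[bad] <- NA_integer_
  out <- array(NA_integer_, dim = d, dimnames = dimnames(arr))
  out[, , 1] <- lo
  out[, , 2] <- hi
  out
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", n_individuals(x), " individuals, ",
      length(nuclear_loci(x)), " nuclear loci, ",
      length(cp_loci(x)), " chloroplast loci\n", sep = "")
  grp <- table(x$individuals$group)
  cat("groups: ",
      paste(names(grp), " (", as.integer(grp), ")", sep = "", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Accessors for genotype matrices
#'
#' @param gm a [genotype_matrix()].
#' @return `n_individuals()` the number of rows; `individual_names()` the
#'   cultivar names; `nuclear_loci()` / `cp_loci()` the locus name vectors.
#' @export
n_individuals <- function(gm) nrow(gm$individuals)

#' @rdname n_individuals
#' @export
individual_names <- function(gm) gm$individuals$name

#' @rdname n_individuals
#' @export
nuclear_loci <- function(gm) dimnames(gm$nuclear)[[2]] %||% character(0)

#' @rdname n_individuals
#' @export
cp_loci <- function(gm) colnames(gm$cp) %||% character(0)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the diploid calls at one nuclear locus
#'
#' @param gm a [genotype_matrix()].
#' @param locus nuclear locus name.
#' @return A two-column integer matrix (allele_1, allele_2), one row per
#'   individual; `NA` rows are missing calls.
#' @export
nuclear_calls <- function(gm, locus) {
  if (!locus %in% nuclear_loci(gm)) stop("unknown nuclear locus: ", locus)
  out <- cbind(allele_1 = gm$nuclear[, locus, 1],
               allele_2 = gm$nuclear[, locus, 2])
  rownames(out) <- individual_names(gm)
  out
}

#' Subset a genotype matrix by individual name and/or group code
#'
#' Rows are retained in their original input order; the locus panel is
#' unchanged. Selecting by both `individuals` and `groups` keeps the union.
#'
#' @param x a [genotype_matrix()].
#' @param individuals character vector of cultivar names (may be empty).
#' @param groups character vector of group codes.
#' @param ... ignored.
#' @return A `genotype_matrix` with the selected rows.
#' @export
subset.genotype_matrix <- function(x, individuals = NULL, groups = NULL, ...) {
  if (is.null(individuals) && is.null(groups)) return(x)
  keep <- rep(FALSE, n_individuals(x))
  if (!is.null(individuals)) {
    unknown <- setdiff(individuals, individual_names(x))
    if (length(unknown)) {
      stop("unknown individual(s): ", paste(unknown, collapse = ", "))
    }
    keep <- keep | individual_names(x) %in% individuals
  }
  if (!is.null(groups)) {
    unknown <- setdiff(groups, x$individuals$group)
    if (length(unknown)) {
      stop("unknown group code(s): ", paste(unknown, collapse = ", "))
    }
    keep <- keep | x$individuals$group %in% groups
  }
  gm_take(x, which(keep))
}

# internal row subset by integer index (order preserved as given)
gm_take <- function(gm, idx) {
  genotype_matrix(gm$individuals[idx, , drop = FALSE],
                  nuclear = gm$nuclear[idx, , , drop = FALSE],
                  cp = gm$cp[idx, , drop = FALSE])
}

# internal: stack two genotype matrices sharing the same locus panel
gm_bind <- function(a, b) {
  stopifnot(identical(nuclear_loci(a), nuclear_loci(b)),
            identical(cp_loci(a), cp_loci(b)))
  nuc <- array(NA_integer_,
               dim = c(n_individuals(a) + n_individuals(b),
                       length(nuclear_loci(a)), 2),
               dimnames = list(NULL, nuclear_loci(a), NULL))
  nuc[seq_len(n_individuals(a)), , ] <- a$nuclear
  nuc[n_individuals(a) + seq_len(n_individuals(b)), , ] <- b$nuclear
  cp <- rbind(a$cp, b$cp)
  ind <- rbind(a$individuals[, c("name", "group"), drop = FALSE],
               b$individuals[, c("name", "group"), drop = FALSE])
  genotype_matrix(ind, nuclear = nuc, cp = cp)
}

#' Observed allele counts and frequencies at one locus
#'
#' Counts every non-missing gene copy once: two per typed diploid call at a
#' nuclear locus, one per typed haploid call at a chloroplast locus. Missing
#' calls are excluded. A locus with no typed copies yields `n_genes = 0` and
#' an empty frequency table (not an error).
#'
#' @param gm a [genotype_matrix()].
#' @param locus locus name (nuclear or chloroplast).
#' @param individuals,groups optional selectors passed to
#'   [subset.genotype_matrix()].
#' @return An object of class `allele_freqs`: list with `locus`, `mode`
#'   (`"nuclear-diploid"` or `"chloroplast-haploid"`), `counts` (named
#'   integer), `freqs` (named numeric summing to 1), and `n_genes`.
#' @export
allele_frequencies <- function(gm, locus, individuals = NULL, groups = NULL) {
  gm <- subset(gm, individuals = individuals, groups = groups)
  if (locus %in% nuclear_loci(gm)) {
    copies <- c(gm$nuclear[, locus, 1], gm$nuclear[, locus, 2])
    mode <- "nuclear-diploid"
  } else if (locus %in% cp_loci(gm)) {
    copies <- gm$cp[, locus]
    mode <- "chloroplast-haploid"
  } else {
    stop("unknown locus: ", locus)
  }
  copies <- copies[!is.na(copies)]
  counts <- table(copies)
  counts <- setNames(as.integer(counts), names(counts))
  n_genes <- sum(counts)
  freqs <- if (n_genes > 0) counts / n_genes else numeric(0)
  structure(list(locus = locus, mode = mode, counts = counts,
                 freqs = freqs, n_genes = n_genes),
            class = "allele_freqs")
}

#' @export
print.allele_freqs <- function(x, ...) {
  cat("allele_freqs for ", x$locus, " (", x$mode, "), n_genes = ",
      x$n_genes, "\n", sep = "")
  if (length(x$freqs)) print(round(x$freqs, 4))
  invisible(x)
}
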