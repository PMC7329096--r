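#' Pairwise codominant squared genetic distance
#'
#' The Smouse-Peakall squared distance for codominant data. Writing each
#' single-locus genotype as its allele-count vector x (entries summing to
#' 2), the per-locus contribution is \eqn{d^2 = \tfrac12 \sum_i (x_i -
#' y_i)^2}, which realises the familiar genotype-pair pattern over distinct
#' alleles i, j, k, l:
#' d2(ii,ii) = d2(ij,ij) = 0, d2(ii,ij) = d2(ij,ik) = 1, d2(ij,kl) = 2,
#' d2(ii,jk) = 3, d2(ii,jj) = 4. The total is the sum over loci at which
#' both individuals are typed; when missing data leave a pair with fewer
#' co-typed loci the sum is rescaled by (total loci / co-typed loci) so
#' totals remain comparable.
#'
#' @param gm a [genotype_matrix()] with at least 2 individuals.
#' @param individuals,groups optional selectors
#'   (see [subset.genotype_matrix()]).
#' @return An object of class `ssr_dist`: list with `names` and `d2`
#'   (symmetric matrix, zero diagonal).
#' @export
squared_distance <- function(gm, individuals = NULL, groups = NULL) {
  gm <- subset(gm, individuals = individuals, groups = groups)
  n <- n_individuals(gm)
  if (n < 2) stop("at least 2 individuals are required")
  loci <- nuclear_loci(gm)
  if (length(loci) == 0) stop("at least one nuclear locus is required")
  total <- matrix(0, n, n)
  cotyped <- matrix(0L, n, n)
  for (l in loci) {
    a <- gm$nuclear[, l, 1]; b <- gm$nuclear[, l, 2]
    typed <- !is.na(a)
    alleles <- sort(unique(c(a[typed], b[typed])))
    if (!length(alleles)) next
    cnt <- matrix(0, n, length(alleles))
    cnt[cbind(which(typed), match(a[typed], alleles))] <-
      cnt[cbind(which(typed), match(a[typed], alleles))] + 1
    cnt[cbind(which(typed), match(b[typed], alleles))] <-
      cnt[cbind(which(typed), match(b[typed], alleles))] + 1
    d2l <- as.matrix(dist(cnt))^2 / 2
    d2l[!typed, ] <- 0
    d2l[, !typed] <- 0
    total <- total + d2l
    cotyped <- cotyped + tcrossprod(typed * 1L)
  }
  off <- upper.tri(cotyped)
  if (any(cotyped[off] == 0)) {
    idx <- which(cotyped == 0 & off, arr.ind = TRUE)[1, ]
    stop("undefined distance: individuals ",
         individual_names(gm)[idx[1]], " and ",
         individual_names(gm)[idx[2]], " share no typed locus")
  }
  d2 <- total * length(loci) / cotyped
  diag(d2) <- 0
  dimnames(d2) <- list(individual_names(gm), individual_names(gm))
  structure(list(names = individual_names(gm), d2 = d2), class = "ssr_dist")
}

#' Principal coordinate analysis
#'
#' Classical scaling of a squared-distance matrix: Gower double-centering of
#' \eqn{-\tfrac12 D^2}, eigendecomposition, coordinates
#' \eqn{v_k \sqrt{\lambda_k}} for positive eigenvalues, axes in descending
#' eigenvalue order. Variance percentages are computed over the positive
#' eigenvalues only and sum to 100. Negative eigenvalues (possible for
#' non-Euclidean inputs) are reported in `eigenvalues` but excluded from
#' coordinates. Axis signs follow a deterministic convention: the first
#' coordinate of non-negligible magnitude on each axis is positive, so
#' replicate outputs are comparable.
#'
#' @param dm a [squared_distance()] result (or any symmetric squared-distance
#'   matrix with zero diagonal).
#' @param n_axes number of axes to return (truncated with a warning when it
#'   exceeds the number of positive eigenvalues).
#' @return An object of class `pcoa_result`: list with `coordinates`
#'   (individuals x axes), `eigenvalues` (all, descending) and
#'   `pct_variance` (one entry per positive eigenvalue, summing to 100).
#' @export
pcoa <- function(dm, n_axes = 3L) {
  if (inherits(dm, "ssr_dist")) {
    d2 <- dm$d2
  } else {
    d2 <- as.matrix(dm)
  }
  n <- nrow(d2)
  a <- -0.5 * d2
  b <- a - matrix(rowMeans(a), n, n) -
    matrix(colMeans(a), n, n, byrow = TRUE) + mean(a)
  eg <- eigen(b, symmetric = TRUE)
  ev <- eg$values
  tol <- max(abs(ev)) * 1e-9
  pos <- which(ev > tol)
  if (!length(pos)) stop("no positive eigenvalue; degenerate configuration")
  if (n_axes > length(pos)) {
    warning("only ", length(pos), " positive eigenvalue(s); axes truncated")
    n_axes <- length(pos)
  }
  keep <- pos[seq_len(n_axes)]
  coords <- eg$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(ev[keep]), nrow = length(keep))
  # sign convention: first non-negligible loading of each axis positive
  for (j in seq_len(ncol(coords))) {
    nz <- which(abs(coords[, j]) > max(abs(coords[, j])) * 1e-8)
    if (length(nz) && coords[nz[1], j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(d2)
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  pct <- 100 * ev[pos] / sum(ev[pos]) # one entry per positive axis; sums to 100
  structure(list(coordinates = coords, eigenvalues = ev,
                 pct_variance = pct),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  k <- ncol(x$coordinates)
  cat("pcoa_result: ", nrow(x$coordinates), " individuals, ", k,
      " axes (", paste(sprintf("%.1f%%", x$pct_variance[seq_len(k)]),
                       collapse = ", "),
      " of positive-eigenvalue variance)\n", sep = "")
  invisible(x)
}
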