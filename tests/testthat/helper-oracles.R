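# Fixture builders and independent oracle implementations shared by the
# tests. The oracles deliberately use the slowest, most literal algorithm
# available (full enumeration, all-pairs comparison, Monte-Carlo sampling)
# and never share code with the implementation they check.

# build a genotype_matrix from a list of per-locus n x 2 allele matrices
mk_gm <- function(nuclear_by_locus, names = NULL, groups = NULL, cp = NULL) {
  n <- nrow(nuclear_by_locus[[1]])
  L <- length(nuclear_by_locus)
  if (is.null(names)) names <- paste0("ind", seq_len(n))
  if (is.null(groups)) groups <- rep("ALL", n)
  arr <- array(NA_integer_, dim = c(n, L, 2),
               dimnames = list(NULL, names(nuclear_by_locus) %||%
                                 paste0("L", seq_len(L)), NULL))
  for (l in seq_len(L)) arr[, l, ] <- nuclear_by_locus[[l]]
  genotype_matrix(data.frame(name = names, group = groups,
                             stringsAsFactors = FALSE),
                  nuclear = arr, cp = cp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random diploid matrix on a small allele ladder, optionally with missing
# calls and planted clones (clone of row `from` appended per entry)
random_gm <- function(n, L, n_alleles = 4, missing_rate = 0, clones = integer(0)) {
  sizes <- 100 + 2 * (seq_len(n_alleles) - 1)
  arr <- array(sample(sizes, n * L * 2, replace = TRUE), dim = c(n, L, 2))
  if (missing_rate > 0) {
    drop <- matrix(runif(n * L) < missing_rate, n, L)
    for (l in seq_len(L)) arr[drop[, l], l, ] <- NA_integer_
  }
  nm <- paste0("ind", seq_len(n))
  if (length(clones)) {
    ext <- array(NA_integer_, dim = c(n + length(clones), L, 2))
    ext[seq_len(n), , ] <- arr
    for (k in seq_along(clones)) ext[n + k, , ] <- arr[clones[k], , ]
    arr <- ext
    nm <- c(nm, paste0("clone", seq_along(clones), "_of", clones))
  }
  dimnames(arr) <- list(NULL, paste0("L", seq_len(L)), NULL)
  genotype_matrix(nm, nuclear = arr)
}

# uniform random point on the k-simplex
rdirichlet_test <- function(k) {
  x <- rgamma(k, 1)
  x / sum(x)
}

# --- probability of identity: genotype enumeration oracle -------------------
# sum over unordered genotypes g of P(g)^2 under Hardy-Weinberg
pi_oracle <- function(p) {
  k <- length(p)
  tot <- 0
  for (i in seq_len(k)) {
    for (j in i:k) {
      pg <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
      tot <- tot + pg^2
    }
  }
  tot
}

# --- synonym groups: all-pairs comparison + union-find oracle ---------------
synonym_oracle <- function(gm, max_mismatch = 0, min_typed_frac = 0.5) {
  n <- n_individuals(gm)
  L <- length(nuclear_loci(gm))
  a <- gm$nuclear[, , 1, drop = FALSE]
  b <- gm$nuclear[, , 2, drop = FALSE]
  typed <- matrix(!is.na(a), n, L)
  eligible <- rowSums(typed) >= min_typed_frac * L
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j >= i || !eligible[i] || !eligible[j]) next
      co <- typed[i, ] & typed[j, ]
      if (!any(co)) next
      diff <- sum(a[i, co, 1] != a[j, co, 1] | b[i, co, 1] != b[j, co, 1])
      if (diff <= max_mismatch) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  comp <- split(individual_names(gm), roots)
  comp <- comp[vapply(comp, length, 1L) > 1]
  canon_groups(unname(comp))
}

# normalize a partition's groups for set-wise comparison
canon_groups <- function(groups) {
  g <- lapply(groups, sort)
  g[order(vapply(g, paste, "", collapse = "|"))]
}

# --- parentage: exhaustive trio enumeration oracle --------------------------
trio_oracle_pairs <- function(gm, child, candidates, tol) {
  nm <- individual_names(gm)
  gi <- function(w) cbind(gm$nuclear[match(w, nm), , 1],
                          gm$nuclear[match(w, nm), , 2])
  pc <- gi(child)
  compat_single <- function(p) {
    pp <- gi(p)
    co <- !is.na(pc[, 1]) & !is.na(pp[, 1])
    mm <- 0
    for (l in which(co)) {
      if (length(intersect(pc[l, ], pp[l, ])) == 0) mm <- mm + 1
    }
    mm
  }
  ok_single <- candidates[vapply(candidates, compat_single, 1) <= tol]
  out <- list()
  if (length(ok_single) >= 2) {
    prs <- combn(ok_single, 2, simplify = FALSE)
    for (pr in prs) {
      p1 <- gi(pr[1]); p2 <- gi(pr[2])
      bad <- 0
      for (l in seq_len(nrow(pc))) {
        if (anyNA(c(pc[l, ], p1[l, ], p2[l, ]))) next
        phases <- c(pc[l, 1] %in% p1[l, ] && pc[l, 2] %in% p2[l, ],
                    pc[l, 2] %in% p1[l, ] && pc[l, 1] %in% p2[l, ])
        if (!any(phases)) bad <- bad + 1
      }
      if (bad <= tol) out[[length(out) + 1]] <-
          list(p1 = pr[1], p2 = pr[2], n = bad)
    }
  }
  out
}

# --- allelic richness: Monte-Carlo subsampling oracle -----------------------
ar_mc_oracle <- function(counts, g, n_draws = 20000) {
  pool <- rep(seq_along(counts), counts)
  draws <- replicate(n_draws, length(unique(sample(pool, g))))
  list(mean = mean(draws), se = sd(draws) / sqrt(n_draws))
}

# --- classical scaling: Procrustes residual against a planted config --------
procrustes_residual <- function(target, coords) {
  xc <- scale(target, scale = FALSE)
  yc <- scale(coords, scale = FALSE)
  s <- svd(crossprod(yc, xc))
  rot <- s$u %*% t(s$v)
  sum((yc %*% rot - xc)^2)
}
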