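#' Configuration for the admixture Gibbs sampler
#'
#' Two named profiles bundle sensible run lengths: `"desk"` (20,000
#' post-burn-in sweeps, 2,000 burn-in, 3 replicates) for interactive and
#' validation work, and `"full"` (1,000,000 sweeps, 100,000 burn-in, 10
#' replicates) matching the classic long-run protocol. Any field can be
#' overridden explicitly.
#'
#' Hyperparameter defaults follow the canonical implementation of the
#' independent-frequency model: Dirichlet parameter `lambda = 1`, a single
#' `alpha` shared across clusters initialised at 1 under a Uniform(0, 10)
#' prior with Normal random-walk proposals of sd 0.025.
#'
#' @param K number of clusters (>= 1).
#' @param profile `"desk"` or `"full"`.
#' @param n_iter post-burn-in sweeps.
#' @param burnin burn-in sweeps.
#' @param n_reps replicate runs (used by [admixture_scan()]).
#' @param lambda Dirichlet parameter of the allele-frequency prior.
#' @param alpha_init initial value of the membership concentration alpha.
#' @param alpha_prior_max upper bound of the Uniform prior on alpha.
#' @param alpha_proposal_sd sd of the Normal random-walk proposal for alpha.
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#' @return list of class `admixture_config`.
#' @export
admixture_config <- function(K, profile = c("desk", "full"), n_iter = NULL,
                             burnin = NULL, n_reps = NULL, lambda = 1,
                             alpha_init = 1, alpha_prior_max = 10,
                             alpha_proposal_sd = 0.025, seed = NULL) {
  profile <- match.arg(profile)
  def <- if (profile == "desk") c(20000L, 2000L, 3L) else c(1000000L, 100000L, 10L)
  K <- as.integer(K)
  if (K < 1) stop("K must be >= 1")
  cfg <- list(K = K, profile = profile,
              n_iter = as.integer(n_iter %||% def[1]),
              burnin = as.integer(burnin %||% def[2]),
              n_reps = as.integer(n_reps %||% def[3]),
              lambda = lambda, alpha_init = alpha_init,
              alpha_prior_max = alpha_prior_max,
              alpha_proposal_sd = alpha_proposal_sd, seed = seed)
  if (cfg$n_iter < 1 || cfg$burnin < 0) stop("invalid run lengths")
  structure(cfg, class = "admixture_config")
}

#' Bayesian admixture clustering of multilocus genotypes
#'
#' A Gibbs sampler for the admixture model with the independent
#' allele-frequency prior and no origin information. Each sweep (i) samples
#' the cluster of origin of every non-missing gene copy from its
#' conditional \eqn{\propto q_{ik} \, p_{k,l,a}}, (ii) draws each cluster x
#' locus frequency simplex from Dirichlet(lambda + assigned allele counts),
#' (iii) draws each individual's membership vector from Dirichlet(alpha +
#' assigned copy counts), and (iv) updates the shared alpha by a Metropolis
#' step. Missing copies are skipped throughout. Reported Q and P are
#' posterior means over post-burn-in sweeps; the model evidence estimate is
#' \eqn{\widehat{\ln P(D)} = \bar L - \mathrm{var}(L)/2} from the
#' post-burn-in log-likelihood trace.
#'
#' @param gm a [genotype_matrix()] with >= 2 individuals and >= 1 nuclear
#'   locus.
#' @param config an [admixture_config()].
#' @return An object of class `admixture_result`: list with `Q`
#'   (individuals x K posterior-mean memberships, rows summing to 1), `P`
#'   (per retained locus a K x alleles frequency matrix, allele sizes as
#'   column names), `alpha_trace`, `loglik_trace`, `ln_pd`, `loci` (retained
#'   locus names), `config`, and `diagnostics` (final-sweep `z`, `P` and
#'   log-likelihood for consistency checks).
#' @export
run_admixture <- function(gm, config) {
  stopifnot(inherits(config, "admixture_config"))
  n <- n_individuals(gm)
  if (n < 2) stop("at least 2 individuals are required")
  loci <- nuclear_loci(gm)
  if (length(loci) == 0) stop("at least one nuclear locus is required")

  # encode allele sizes as per-locus 1-based indices; 0 = missing copy
  keep <- character(0)
  sizes <- list()
  cols <- list()
  for (l in loci) {
    a <- gm$nuclear[, l, 1]; b <- gm$nuclear[, l, 2]
    s <- sort(unique(c(a, b)))
    s <- s[!is.na(s)]
    if (!length(s)) {
      warning("locus ", l, " has no typed copies; excluded from clustering")
      next
    }
    col <- integer(2 * n)
    col[seq(1, 2 * n, 2)] <- match(a, s, nomatch = 0L)
    col[seq(2, 2 * n, 2)] <- match(b, s, nomatch = 0L)
    col[is.na(col)] <- 0L
    keep <- c(keep, l)
    sizes[[l]] <- s
    cols[[l]] <- col
  }
  if (!length(keep)) stop("no locus with typed copies")
  geno <- do.call(cbind, cols)
  n_alleles <- lengths(sizes)

  if (!is.null(config$seed)) set.seed(config$seed)
  raw <- gibbs_admixture_cpp(geno, as.integer(n_alleles), config$K,
                             config$n_iter, config$burnin, config$lambda,
                             config$alpha_init, config$alpha_prior_max,
                             config$alpha_proposal_sd)
  Q <- raw$Q
  dimnames(Q) <- list(individual_names(gm), paste0("Cluster", seq_len(config$K)))
  P <- raw$P
  P_last <- raw$P_last
  for (j in seq_along(keep)) {
    dimnames(P[[j]]) <- list(paste0("Cluster", seq_len(config$K)),
                             as.character(sizes[[keep[j]]]))
    dimnames(P_last[[j]]) <- dimnames(P[[j]])
  }
  names(P) <- keep
  names(P_last) <- keep
  ll <- raw$loglik_trace
  structure(list(Q = Q, P = P, alpha_trace = raw$alpha_trace,
                 loglik_trace = ll,
                 ln_pd = mean(ll) - var(ll) / 2,
                 loci = keep, config = config,
                 diagnostics = list(z_last = raw$z_last, P_last = P_last,
                                    loglik_last = raw$loglik_last,
                                    geno = geno)),
            class = "admixture_result")
}

#' @export
print.admixture_result <- function(x, ...) {
  cat("admixture_result: K = ", x$config$K, ", ", nrow(x$Q),
      " individuals, ", length(x$loci), " loci\n",
      "ln P(D) estimate: ", format(x$ln_pd), "  (", x$config$n_iter,
      " sweeps after ", x$config$burnin, " burn-in)\n", sep = "")
  invisible(x)
}

# all permutations of 1..k (k! rows); k <= 8 keeps this small
permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Align replicate admixture runs (label switching)
#'
#' Cluster labels are arbitrary, so replicate runs must be permuted onto a
#' common labelling before averaging or comparison. The first run is the
#' reference; every other run receives the column permutation of Q (and the
#' matching row permutation of each P matrix) minimizing
#' \eqn{\sum |Q - Q_{ref}|}, found exhaustively over the K! permutations.
#'
#' @param results list of [run_admixture()] results sharing K and
#'   individuals.
#' @return The input list with Q and P permuted onto the reference
#'   labelling; each run gains a `permutation` element.
#' @export
align_runs <- function(results) {
  stopifnot(length(results) >= 1)
  K <- results[[1]]$config$K
  ref <- results[[1]]$Q
  for (r in seq_along(results)) {
    if (results[[r]]$config$K != K) stop("runs disagree on K")
    if (!identical(rownames(results[[r]]$Q), rownames(ref))) {
      stop("runs cover different individuals")
    }
  }
  perms <- permutations(K)
  out <- results
  out[[1]]$permutation <- seq_len(K)
  for (r in seq_along(results)[-1]) {
    Q <- results[[r]]$Q
    cost <- apply(perms, 1, function(pp) sum(abs(Q[, pp, drop = FALSE] - ref)))
    best <- perms[which.min(cost), ]
    out[[r]]$Q <- Q[, best, drop = FALSE]
    colnames(out[[r]]$Q) <- colnames(ref)
    out[[r]]$P <- lapply(results[[r]]$P, function(p) {
      q <- p[best, , drop = FALSE]
      rownames(q) <- rownames(p)
      q
    })
    out[[r]]$permutation <- best
  }
  out
}

#' Mean membership matrix over aligned replicate runs
#'
#' @param aligned a list of runs from [align_runs()].
#' @return The element-wise mean Q matrix.
#' @export
mean_membership <- function(aligned) {
  Reduce(`+`, lapply(aligned, `[[`, "Q")) / length(aligned)
}

#' Replicate admixture runs across a range of K
#'
#' Runs `n_reps` independent chains for every K in `k_range`, with
#' deterministic per-run seeds derived from `seed`, and summarises the
#' evidence estimates with [evanno_delta_k()].
#'
#' @param gm a [genotype_matrix()].
#' @param k_range contiguous integer range of K values (e.g. `2:8`).
#' @param config an [admixture_config()] template (its K and seed are
#'   overridden per run; its `n_reps` is used unless `n_reps` is given).
#' @param n_reps replicates per K.
#' @param seed base seed; run (K, r) uses `seed + 1000 * K + r`.
#' @return list with `runs` (nested list per K), `ln_pd` (list per K of
#'   per-replicate evidence estimates) and `evanno` (a
#'   [evanno_delta_k()] table).
#' @export
admixture_scan <- function(gm, k_range, config = admixture_config(2),
                           n_reps = config$n_reps, seed = 1L) {
  k_range <- sort(as.integer(k_range))
  stopifnot(length(k_range) >= 1, all(diff(k_range) == 1))
  runs <- list()
  ln_pd <- list()
  for (K in k_range) {
    kk <- as.character(K)
    runs[[kk]] <- vector("list", n_reps)
    vals <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      cfg <- config
      cfg$K <- K
      cfg$seed <- seed + 1000L * K + r
      runs[[kk]][[r]] <- run_admixture(gm, cfg)
      vals[r] <- runs[[kk]][[r]]$ln_pd
    }
    ln_pd[[kk]] <- vals
  }
  ev <- if (length(k_range) >= 3) evanno_delta_k(ln_pd) else NULL
  list(runs = runs, ln_pd = ln_pd, evanno = ev)
}

#' Evanno's delta-K criterion
#'
#' For each interior K of a contiguous scan, the absolute second difference
#' of the evidence estimate, taken per replicate, averaged over replicates
#' and divided by the between-replicate standard deviation at K:
#' \deqn{\Delta K = \mathrm{mean}_r |L_r(K-1) - 2 L_r(K) + L_r(K+1)| /
#' \mathrm{sd}_r L_r(K).}
#' A K with zero between-replicate sd has an undefined delta-K and is
#' flagged (`defined = FALSE`), never silently 0 or infinite.
#'
#' @param ln_pd named list mapping each K (as character or integer-coercible
#'   name) to the per-replicate evidence estimates; a contiguous K range of
#'   length >= 3 with >= 2 replicates each.
#' @return data.frame with columns `K`, `mean_L`, `sd_L`, `delta_k`,
#'   `defined`; the attribute `argmax_k` holds the K maximizing the defined
#'   delta-K values.
#' @export
evanno_delta_k <- function(ln_pd) {
  ks <- sort(as.integer(names(ln_pd)))
  if (length(ks) < 3 || !all(diff(ks) == 1)) {
    stop("a contiguous K range with at least 3 values is required")
  }
  reps <- lengths(ln_pd)
  if (any(reps < 2)) stop("at least 2 replicates per K are required")
  if (length(unique(reps)) != 1) {
    stop("all K values need the same number of replicates")
  }
  L <- do.call(rbind, ln_pd[as.character(ks)]) # K x reps
  mean_L <- rowMeans(L)
  sd_L <- apply(L, 1, sd)
  delta <- rep(NA_real_, length(ks))
  defined <- rep(NA, length(ks))
  for (i in seq_along(ks)[-c(1, length(ks))]) {
    d2 <- abs(L[i - 1, ] - 2 * L[i, ] + L[i + 1, ])
    if (sd_L[i] == 0) {
      defined[i] <- FALSE
    } else {
      delta[i] <- mean(d2) / sd_L[i]
      defined[i] <- TRUE
    }
  }
  out <- data.frame(K = ks, mean_L = mean_L, sd_L = sd_L,
                    delta_k = delta, defined = defined)
  rownames(out) <- NULL
  if (any(defined %in% TRUE)) {
    attr(out, "argmax_k") <- ks[which.max(ifelse(defined %in% TRUE, delta, -Inf))]
  } else {
    attr(out, "argmax_k") <- NA_integer_
  }
  out
}

#' Classify K = 2 memberships into dominant and admixed classes
#'
#' Individuals with first-cluster membership above `hi` are dominated by
#' cluster 1, below `lo` by cluster 2, and admixed in between (boundary
#' values fall in the admixed class).
#'
#' @param Q a two-column membership matrix (rows summing to 1).
#' @param hi,lo thresholds with `hi > lo` (defaults 0.8 / 0.2).
#' @return named character vector with values `"cluster1-dominant"`,
#'   `"admixed"`, `"cluster2-dominant"`.
#' @export
classify_membership <- function(Q, hi = 0.8, lo = 0.2) {
  Q <- as.matrix(Q)
  if (ncol(Q) != 2) stop("membership classification is defined for K = 2")
  if (!(hi > lo)) stop("`hi` must exceed `lo`")
  q1 <- Q[, 1]
  out <- ifelse(q1 > hi, "cluster1-dominant",
                ifelse(q1 < lo, "cluster2-dominant", "admixed"))
  setNames(out, rownames(Q))
}
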