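#' Configuration for the synthetic SSR dataset generator
#'
#' The generator emulates the statistical structure a cultivar-collection
#' analysis assumes: two ancestral nuclear gene pools diverged by a
#' Balding-Nichols F, groups of pure individuals from each pool, an F1
#' hybrid group with recorded pedigrees and maternal chloroplast
#' inheritance, optional first-backcross individuals, clonal duplicates
#' planted under new names, missing calls and rare allele-shift genotyping
#' errors. Full ground truth is returned with every dataset.
#'
#' Defaults reproduce a realistic cultivar-collection layout: 31 nuclear
#' loci with 4-8 alleles each, 5 chloroplast loci, 12 groups totalling 200
#' unique individuals (of which one 18-member hybrid group), 30 clones
#' planted in the second pool's groups, divergence F = 0.2, 1% missing
#' calls and 0.2% allele-shift errors.
#'
#' @param n_loci number of nuclear loci.
#' @param allele_range inclusive range of allele counts per nuclear locus.
#' @param n_cp_loci number of chloroplast loci.
#' @param divergence_F Balding-Nichols divergence between the two pools,
#'   in (0, 1).
#' @param groups data.frame with columns `name`, `size` and `ancestry`
#'   (one of `"pop1"`, `"pop2"`, `"f1"`, `"bc1"`); `NULL` uses the default
#'   12-group layout.
#' @param n_clones clonal duplicates appended by [inject_artifacts()].
#' @param clone_ancestry ancestry class whose groups receive the clones.
#' @param missing_rate per-call missing probability, in \[0, 1).
#' @param error_rate per-gene-copy probability of a +/-2 size-shift error,
#'   in \[0, 1).
#' @param cp_pools list of per-pool haplotype probability vectors over the
#'   available haplotypes (names `HAP1`, ...); the default gives pool 1 a
#'   dominant and a rare haplotype and pool 2 two common plus two rare
#'   haplotypes, mirroring the skew typical of cultivated germplasm.
#' @param seed integer seed; every dataset is bit-reproducible.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 31L, allele_range = c(4L, 8L),
                       n_cp_loci = 5L, divergence_F = 0.2, groups = NULL,
                       n_clones = 30L, clone_ancestry = "pop2",
                       missing_rate = 0.01, error_rate = 0.002,
                       cp_pools = NULL, seed = 1L) {
  if (is.null(groups)) groups <- default_sim_groups()
  stopifnot(is.data.frame(groups),
            all(c("name", "size", "ancestry") %in% names(groups)),
            all(groups$ancestry %in% c("pop1", "pop2", "f1", "bc1")))
  if (!(divergence_F > 0 && divergence_F < 1)) {
    stop("divergence_F must lie strictly between 0 and 1")
  }
  if (missing_rate < 0 || missing_rate >= 1 || error_rate < 0 ||
      error_rate >= 1) {
    stop("rates must lie in [0, 1)")
  }
  if (is.null(cp_pools)) {
    cp_pools <- list(c(HAP1 = 0.95, HAP2 = 0.05),
                     c(HAP3 = 0.55, HAP4 = 0.35, HAP5 = 0.05, HAP6 = 0.05))
  }
  structure(list(n_loci = as.integer(n_loci),
                 allele_range = as.integer(allele_range),
                 n_cp_loci = as.integer(n_cp_loci),
                 divergence_F = divergence_F, groups = groups,
                 n_clones = as.integer(n_clones),
                 clone_ancestry = clone_ancestry,
                 missing_rate = missing_rate, error_rate = error_rate,
                 cp_pools = cp_pools, seed = as.integer(seed)),
            class = "sim_config")
}

default_sim_groups <- function() {
  data.frame(
    name = c("J_KA", "J_TA", "J_OJ", "KOR", "HYB", "C_SJ", "C_IO", "C_HE",
             "C_SH", "C_JI", "C_AN", "C_OR"),
    size = c(14L, 21L, 25L, 6L, 18L, 27L, 5L, 13L, 25L, 10L, 9L, 27L),
    ancestry = c("pop1", "pop1", "pop1", "pop1", "f1", "pop2", "pop2",
                 "pop2", "pop2", "pop2", "pop2", "pop2"),
    stringsAsFactors = FALSE)
}

rdirichlet1 <- function(shape) {
  g <- rgamma(length(shape), shape = shape, rate = 1)
  g[g < 1e-300] <- 1e-300
  g / sum(g)
}

#' Simulate diverged population allele frequencies
#'
#' Draws, per nuclear locus, a common ancestral frequency vector from a
#' symmetric Dirichlet(1) and two descendant pools from the Balding-Nichols
#' construction Dirichlet(p (1 - F) / F), so a single parameter F controls
#' how far the pools have drifted apart. Allele sizes sit on a 2-unit
#' ladder starting at 100 plus a per-locus offset, so the generator's
#' +/-2 size-shift errors stay on the ladder.
#'
#' @param cfg a [sim_config()].
#' @return list of per-locus lists with `sizes` (allele sizes), `ancestral`
#'   and `pops` (2 x alleles matrix of pool frequencies).
#' @export
simulate_frequencies <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  lapply(seq_len(cfg$n_loci), function(l) {
    A <- if (cfg$allele_range[1] == cfg$allele_range[2]) cfg$allele_range[1]
         else sample(cfg$allele_range[1]:cfg$allele_range[2], 1)
    anc <- rdirichlet1(rep(1, A))
    shape <- anc * (1 - cfg$divergence_F) / cfg$divergence_F
    pops <- rbind(rdirichlet1(shape), rdirichlet1(shape))
    list(sizes = 100L + (l - 1L) + 2L * (0:(A - 1L)),
         ancestral = anc, pops = pops)
  })
}

sample_cat <- function(p) sample.int(length(p), 1, prob = p)

#' Simulate individuals under the admixture generative model
#'
#' Each gene copy's population of origin is drawn from the membership
#' vector `q`, and its allele from that population's locus frequencies
#' (Hardy-Weinberg within origin). The chloroplast haplotype is drawn from
#' the pool of a population itself drawn from `q`.
#'
#' @param freqs a [simulate_frequencies()] result.
#' @param q membership vector over the two pools (non-negative, summing
#'   to 1).
#' @param n number of individuals.
#' @param cp_pools per-pool haplotype probability vectors (see
#'   [sim_config()]).
#' @return list with `nuclear` (n x loci x 2 allele-size array) and
#'   `cp_hap` (character haplotype labels).
#' @export
simulate_individuals <- function(freqs, q, n, cp_pools) {
  stopifnot(abs(sum(q) - 1) < 1e-9, all(q >= 0))
  L <- length(freqs)
  nuc <- array(NA_integer_, dim = c(n, L, 2))
  for (l in seq_len(L)) {
    fr <- freqs[[l]]
    for (cpy in 1:2) {
      origin <- sample.int(2, n, replace = TRUE, prob = q)
      for (pop in 1:2) {
        idx <- origin == pop
        if (any(idx)) {
          nuc[idx, l, cpy] <- sample(fr$sizes, sum(idx), replace = TRUE,
                                     prob = fr$pops[pop, ])
        }
      }
    }
  }
  hap <- vapply(seq_len(n), function(i) {
    pop <- sample.int(2, 1, prob = q)
    pool <- cp_pools[[pop]]
    names(pool)[sample_cat(pool)]
  }, "")
  list(nuclear = nuc, cp_hap = hap)
}

#' Simulate offspring of recorded crosses
#'
#' Each offspring inherits one uniformly chosen allele per locus from each
#' parent; the chloroplast haplotype is copied from the designated seed
#' parent (maternal inheritance).
#'
#' @param nuclear parent allele-size array (individuals x loci x 2); the
#'   parents must be fully typed.
#' @param cp_hap parent haplotype labels.
#' @param crosses data.frame with columns `seed` and `pollen` holding
#'   parent row indices, one row per offspring.
#' @return list with `nuclear` and `cp_hap` for the offspring, in cross
#'   order.
#' @export
simulate_crosses <- function(nuclear, cp_hap, crosses) {
  if (anyNA(nuclear[unique(c(crosses$seed, crosses$pollen)), , ])) {
    stop("parents must be typed at all loci")
  }
  n <- nrow(crosses)
  L <- dim(nuclear)[2]
  nuc <- array(NA_integer_, dim = c(n, L, 2))
  for (i in seq_len(n)) {
    pick <- function(parent) {
      side <- sample.int(2, L, replace = TRUE)
      m <- matrix(nuclear[parent, , ], nrow = L)
      m[cbind(seq_len(L), side)]
    }
    nuc[i, , 1] <- pick(crosses$seed[i])
    nuc[i, , 2] <- pick(crosses$pollen[i])
  }
  list(nuclear = nuc, cp_hap = cp_hap[crosses$seed])
}

#' Inject clones, missing calls and genotyping errors
#'
#' Appends `n_clones` genotype-identical copies of randomly chosen
#' originals under new names (`<original>_syn<k>`), then applies per-call
#' missingness at `missing_rate` and +/-2 allele-size-shift errors at
#' `error_rate` per gene copy, to nuclear and chloroplast calls alike.
#' Every change is logged.
#'
#' @param gm a [genotype_matrix()].
#' @param cfg a [sim_config()] (rates, clone count, clone ancestry).
#' @param clone_from character vector of individual names eligible for
#'   cloning; default: members of the groups whose ancestry class is
#'   `cfg$clone_ancestry`.
#' @return list with `gm` (augmented matrix), `clone_map` (named character,
#'   clone -> original) and `change_log` (data.frame `type`, `individual`,
#'   `locus`, `detail`).
#' @export
inject_artifacts <- function(gm, cfg, clone_from = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  log <- list()
  clone_map <- character(0)
  if (cfg$n_clones > 0) {
    if (is.null(clone_from)) {
      elig_groups <- cfg$groups$name[cfg$groups$ancestry == cfg$clone_ancestry]
      clone_from <- individual_names(gm)[gm$individuals$group %in% elig_groups]
    }
    if (!length(clone_from)) stop("no individuals eligible for cloning")
    originals <- sample(clone_from, cfg$n_clones, replace = TRUE)
    idx <- match(originals, individual_names(gm))
    counter <- table(originals)
    seen <- setNames(integer(length(counter)), names(counter))
    clone_names <- vapply(originals, function(o) {
      seen[o] <<- seen[o] + 1L
      paste0(o, "_syn", seen[o])
    }, "")
    clones <- genotype_matrix(
      data.frame(name = clone_names,
                 group = gm$individuals$group[idx],
                 stringsAsFactors = FALSE),
      nuclear = gm$nuclear[idx, , , drop = FALSE],
      cp = gm$cp[idx, , drop = FALSE])
    gm <- gm_bind(gm, clones)
    clone_map <- setNames(originals, clone_names)
    log <- c(log, lapply(clone_names, function(cn) {
      data.frame(type = "clone", individual = cn, locus = NA_character_,
                 detail = unname(clone_map[cn]), stringsAsFactors = FALSE)
    }))
  }

  n <- n_individuals(gm)
  nm <- individual_names(gm)
  nuc_loci <- nuclear_loci(gm)
  cps <- cp_loci(gm)

  if (cfg$error_rate > 0) {
    for (l in nuc_loci) {
      for (cpy in 1:2) {
        hit <- which(!is.na(gm$nuclear[, l, cpy]) &
                       runif(n) < cfg$error_rate)
        for (i in hit) {
          shift <- sample(c(-2L, 2L), 1)
          old <- gm$nuclear[i, l, cpy]
          gm$nuclear[i, l, cpy] <- old + shift
          log <- c(log, list(data.frame(
            type = "error", individual = nm[i], locus = l,
            detail = paste0(old, "->", old + shift),
            stringsAsFactors = FALSE)))
        }
      }
    }
    for (l in cps) {
      hit <- which(!is.na(gm$cp[, l]) & runif(n) < cfg$error_rate)
      for (i in hit) {
        shift <- sample(c(-2L, 2L), 1)
        old <- gm$cp[i, l]
        gm$cp[i, l] <- old + shift
        log <- c(log, list(data.frame(
          type = "error", individual = nm[i], locus = l,
          detail = paste0(old, "->", old + shift), stringsAsFactors = FALSE)))
      }
    }
  }

  if (cfg$missing_rate > 0) {
    for (l in nuc_loci) {
      hit <- which(runif(n) < cfg$missing_rate)
      if (length(hit)) {
        gm$nuclear[hit, l, ] <- NA_integer_
        log <- c(log, lapply(nm[hit], function(w) data.frame(
          type = "missing", individual = w, locus = l, detail = "nuclear",
          stringsAsFactors = FALSE)))
      }
    }
    for (l in cps) {
      hit <- which(runif(n) < cfg$missing_rate)
      if (length(hit)) {
        gm$cp[hit, l] <- NA_integer_
        log <- c(log, lapply(nm[hit], function(w) data.frame(
          type = "missing", individual = w, locus = l, detail = "cp",
          stringsAsFactors = FALSE)))
      }
    }
  }

  gm$nuclear <- canonicalize_pairs(gm$nuclear)
  change_log <- if (length(log)) do.call(rbind, log) else
    data.frame(type = character(0), individual = character(0),
               locus = character(0), detail = character(0))
  list(gm = gm, clone_map = clone_map, change_log = change_log)
}

#' Generate a complete synthetic SSR dataset with ground truth
#'
#' Orchestrates the generator: pool frequencies, pure individuals per
#' group, F1 hybrids as recorded crosses between random members of the two
#' pools (seed side chosen at random), optional first backcrosses (F1 x
#' pool-1), chloroplast calls derived from the haplotype definitions, and
#' finally artifact injection (clones, missingness, errors).
#'
#' @param cfg a [sim_config()].
#' @return list with `gm` (the final [genotype_matrix()]) and `truth`, a
#'   list holding `freqs` (per-locus pool frequencies), `q_true`
#'   (individuals x 2, pre-artifact individuals), `pedigree` (data.frame
#'   `child`, `seed`, `pollen`), `clone_map`, `cp_haplotype_true`,
#'   `hap_definitions`, `change_log` and `config`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  freqs <- simulate_frequencies(cfg)

  hap_defs <- cp_hap_definitions(cfg)
  groups <- cfg$groups
  pure <- groups[groups$ancestry %in% c("pop1", "pop2"), , drop = FALSE]

  nuc_list <- list()
  ind_list <- list()
  hap_list <- list()
  q_list <- list()
  for (g in seq_len(nrow(pure))) {
    q <- if (pure$ancestry[g] == "pop1") c(1, 0) else c(0, 1)
    sim <- simulate_individuals(freqs, q, pure$size[g], cfg$cp_pools)
    nms <- sprintf("%s_%02d", pure$name[g], seq_len(pure$size[g]))
    nuc_list[[g]] <- sim$nuclear
    hap_list[[g]] <- sim$cp_hap
    ind_list[[g]] <- data.frame(name = nms, group = pure$name[g],
                                stringsAsFactors = FALSE)
    q_list[[g]] <- matrix(q, pure$size[g], 2, byrow = TRUE)
  }
  nuclear <- do.call(abind3, nuc_list)
  ind <- do.call(rbind, ind_list)
  haps <- unlist(hap_list)
  q_true <- do.call(rbind, q_list)

  is_p1 <- ind$group %in% pure$name[pure$ancestry == "pop1"]
  pedigree <- data.frame(child = character(0), seed = character(0),
                         pollen = character(0), stringsAsFactors = FALSE)

  make_crosses <- function(n, pool_a_idx, pool_b_idx) {
    a <- sample(pool_a_idx, n, replace = TRUE)
    b <- sample(pool_b_idx, n, replace = TRUE)
    seed_is_a <- runif(n) < 0.5
    data.frame(seed = ifelse(seed_is_a, a, b),
               pollen = ifelse(seed_is_a, b, a))
  }

  hyb <- groups[groups$ancestry %in% c("f1", "bc1"), , drop = FALSE]
  for (g in seq_len(nrow(hyb))) {
    if (hyb$ancestry[g] == "f1") {
      crosses <- make_crosses(hyb$size[g], which(is_p1), which(!is_p1))
      q_child <- matrix(0.5, hyb$size[g], 2)
    } else {
      # BC1: F1-like admixed parent crossed back to pool 1. The F1 parents
      # are the hybrids already simulated; require an f1 group before bc1.
      f1_rows <- which(ind$group %in% hyb$name[hyb$ancestry == "f1"])
      if (!length(f1_rows)) stop("a bc1 group requires a preceding f1 group")
      crosses <- make_crosses(hyb$size[g], f1_rows, which(is_p1))
      q_child <- matrix(c(0.75, 0.25), hyb$size[g], 2, byrow = TRUE)
    }
    off <- simulate_crosses(nuclear, haps, crosses)
    nms <- sprintf("%s_%02d", hyb$name[g], seq_len(hyb$size[g]))
    pedigree <- rbind(pedigree, data.frame(
      child = nms, seed = ind$name[crosses$seed],
      pollen = ind$name[crosses$pollen], stringsAsFactors = FALSE))
    nuclear <- abind3(nuclear, off$nuclear)
    ind <- rbind(ind, data.frame(name = nms, group = hyb$name[g],
                                 stringsAsFactors = FALSE))
    haps <- c(haps, off$cp_hap)
    q_true <- rbind(q_true, q_child)
    is_p1 <- c(is_p1, rep(FALSE, hyb$size[g]))
  }

  cp <- hap_defs[haps, , drop = FALSE]
  rownames(cp) <- NULL
  gm <- genotype_matrix(ind, nuclear = nuclear, cp = cp)
  rownames(q_true) <- ind$name
  colnames(q_true) <- c("pop1", "pop2")
  names(haps) <- ind$name

  art <- inject_artifacts(gm, cfg)
  list(gm = art$gm,
       truth = list(freqs = freqs, q_true = q_true, pedigree = pedigree,
                    clone_map = art$clone_map, cp_haplotype_true = haps,
                    hap_definitions = hap_defs, change_log = art$change_log,
                    config = cfg))
}

# haplotype label -> cp allele tuple; haplotypes sit on a 2-unit ladder so
# every pair of definitions differs at every cp locus
cp_hap_definitions <- function(cfg) {
  labs <- unique(unlist(lapply(cfg$cp_pools, names)))
  num <- as.integer(sub("^HAP", "", labs))
  defs <- t(vapply(num, function(h) 90L + 2L * (h - 1L) + integer(cfg$n_cp_loci),
                   integer(cfg$n_cp_loci)))
  rownames(defs) <- labs
  colnames(defs) <- paste0("cpSSR", seq_len(cfg$n_cp_loci))
  defs
}

# bind 3-d arrays along the first dimension
abind3 <- function(...) {
  parts <- list(...)
  parts <- parts[!vapply(parts, is.null, TRUE)]
  if (length(parts) == 1) return(parts[[1]])
  d2 <- dim(parts[[1]])[2]
  out <- array(NA_integer_,
               dim = c(sum(vapply(parts, function(p) dim(p)[1], 1L)), d2, 2))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}
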