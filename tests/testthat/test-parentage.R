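test_that("pairwise mismatches follow the shared-allele rule", {
  gm <- mk_gm(list(L1 = rbind(c(150L, 152L), c(152L, 154L), c(156L, 158L)),
                   L2 = rbind(c(200L, 200L), c(202L, 204L), c(200L, 202L))),
              names = c("A", "B", "C"))
  expect_identical(pairwise_mismatches(gm, "A", "B"), "L2")
  expect_identical(pairwise_mismatches(gm, "A", "C"), "L1")
  expect_length(pairwise_mismatches(gm, "B", "C"), 1)

  clone <- mk_gm(list(L1 = rbind(c(150L, 152L), c(150L, 152L))),
                 names = c("A", "B"))
  expect_length(pairwise_mismatches(clone, "A", "B"), 0)

  expect_error(pairwise_mismatches(gm, "A", "A"), "differ")
  expect_error(pairwise_mismatches(gm, "A", "Z"), "Z")
})

test_that("mismatch comparison is symmetric and skips missing loci", {
  set.seed(31)
  gm <- random_gm(12, 8, missing_rate = 0.2)
  nm <- individual_names(gm)
  for (k in 1:15) {
    pr <- sample(nm, 2)
    expect_identical(pairwise_mismatches(gm, pr[1], pr[2]),
                     pairwise_mismatches(gm, pr[2], pr[1]))
  }
  # a locus missing in one member never counts as a mismatch
  gm2 <- mk_gm(list(L1 = rbind(c(150L, 150L), c(NA, NA))),
               names = c("A", "B"))
  expect_length(pairwise_mismatches(gm2, "A", "B"), 0)
})

test_that("raising the tolerance never removes candidates", {
  set.seed(32)
  gm <- random_gm(15, 10, n_alleles = 4)
  nm <- individual_names(gm)
  for (tol in 0:2) {
    lo <- find_candidate_parents(gm, nm[1], nm[-1], tol = tol)$candidate
    hi <- find_candidate_parents(gm, nm[1], nm[-1], tol = tol + 1)$candidate
    expect_true(all(lo %in% hi))
  }
  expect_error(find_candidate_parents(gm, nm[1], nm), "candidates")
  expect_identical(nrow(find_candidate_parents(gm, nm[1], character(0))), 0L)
})

test_that("trio compatibility takes one allele from each parent", {
  gm <- mk_gm(list(L1 = rbind(c(150L, 152L), c(150L, 150L), c(152L, 154L))),
              names = c("child", "p1", "p2"))
  pairs <- find_parent_pairs(gm, "child", c("p1", "p2"), tol = 0)
  expect_identical(nrow(pairs), 1L)
  expect_identical(pairs$n_trio_incompatible, 0L)

  # homozygous child needs the allele in BOTH parents
  gm2 <- mk_gm(list(L1 = rbind(c(150L, 150L), c(150L, 152L), c(152L, 154L))),
               names = c("child", "p1", "p2"))
  pairs2 <- find_parent_pairs(gm2, "child", c("p1", "p2"), tol = 0)
  expect_identical(nrow(pairs2), 0L)
})

test_that("pair enumeration matches the exhaustive trio oracle", {
  set.seed(33)
  for (rep in 1:12) {
    gm <- random_gm(12, 6, n_alleles = 3,
                    missing_rate = sample(c(0, 0.1), 1))
    nm <- individual_names(gm)
    child <- nm[1]
    cand <- nm[-1]
    for (tol in 0:1) {
      got <- find_parent_pairs(gm, child, cand, tol = tol)
      want <- trio_oracle_pairs(gm, child, cand, tol)
      key <- function(p1, p2, n) paste(pmin(p1, p2), pmax(p1, p2), n)
      expect_setequal(
        key(got$parent_1, got$parent_2, got$n_trio_incompatible),
        vapply(want, function(w) key(w$p1, w$p2, w$n), ""))
    }
  }
})

test_that("simulated trios are recovered and a single error is rescued by the tolerance", {
  sim <- simulate_dataset(sim_config(
    n_loci = 31L, seed = 34, n_clones = 0L, missing_rate = 0, error_rate = 0,
    groups = data.frame(name = c("P1", "P2", "F1"), size = c(15L, 15L, 6L),
                        ancestry = c("pop1", "pop2", "f1"))))
  gm <- sim$gm
  ped <- sim$truth$pedigree
  nm <- individual_names(gm)
  for (i in seq_len(nrow(ped))) {
    pairs <- find_parent_pairs(gm, ped$child[i], setdiff(nm, ped$child[i]),
                               tol = 0)
    hit <- pairs$parent_1 %in% ped[i, c("seed", "pollen")] &
      pairs$parent_2 %in% ped[i, c("seed", "pollen")]
    expect_true(any(hit & pairs$n_trio_incompatible == 0))
  }

  # inject one allele error into a true parent: broken at tol 0, rescued at 1
  child <- ped$child[1]
  seed_p <- ped$seed[1]
  gm_err <- gm
  i <- match(seed_p, nm)
  l <- which(!is.na(gm_err$nuclear[i, , 1]))[1]
  gm_err$nuclear[i, l, 1] <- gm_err$nuclear[i, l, 1] + 2L
  gm_err$nuclear <- ssrpipe:::canonicalize_pairs(gm_err$nuclear)
  mm <- pairwise_mismatches(gm_err, child, seed_p)
  if (length(mm) == 1) { # the shift can still share the other allele
    cand0 <- find_candidate_parents(gm_err, child, seed_p, tol = 0)
    cand1 <- find_candidate_parents(gm_err, child, seed_p, tol = 1)
    expect_identical(nrow(cand0), 0L)
    expect_identical(cand1$candidate, seed_p)
  }
})

test_that("chloroplast haplotypes settle seed and pollen roles only when decisive", {
  hap <- structure(list(haplotype = c(child = "HAP3", pA = "HAP3",
                                      pB = "HAP1", pC = "HAP3",
                                      pD = NA_character_)),
                   class = "haplotype_assignment")
  r <- assign_roles("child", c("pA", "pB"), hap)
  expect_identical(r$seed_parent, "pA")
  expect_identical(r$pollen_parent, "pB")

  r2 <- assign_roles("child", c("pA", "pC"), hap)
  expect_identical(r2$seed_parent, PARENT_AMBIGUOUS)

  r3 <- assign_roles("child", "pB", hap)
  expect_identical(r3$seed_parent, PARENT_UNKNOWN)
  expect_identical(r3$pollen_parent, "pB")

  r4 <- assign_roles("child", "pA", hap)
  expect_identical(r4$seed_parent, "pA")

  r5 <- assign_roles("child", c("pA", "pD"), hap)
  expect_identical(r5$seed_parent, PARENT_UNKNOWN)
})

test_that("parentage_analysis reports the whole pedigree with correct roles", {
  sim <- simulate_dataset(sim_config(
    n_loci = 31L, seed = 35, n_clones = 0L, missing_rate = 0, error_rate = 0,
    groups = data.frame(name = c("P1", "P2", "F1"), size = c(12L, 12L, 5L),
                        ancestry = c("pop1", "pop2", "f1"))))
  gm <- sim$gm
  ped <- sim$truth$pedigree
  haps <- assign_haplotypes(gm)
  res <- parentage_analysis(gm, ped$child,
                            setdiff(individual_names(gm), ped$child),
                            tol = 1, haplotypes = haps)
  expect_identical(res$child, ped$child)
  for (i in seq_len(nrow(res))) {
    expect_setequal(c(res$parent_1[i], res$parent_2[i]),
                    c(ped$seed[i], ped$pollen[i]))
    decisive <- haps$haplotype[[ped$seed[i]]] !=
      haps$haplotype[[ped$pollen[i]]]
    if (decisive) {
      expect_identical(res$seed_parent[i], ped$seed[i])
      expect_identical(res$pollen_parent[i], ped$pollen[i])
    } else {
      expect_identical(res$seed_parent[i], PARENT_AMBIGUOUS)
    }
  }
})
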