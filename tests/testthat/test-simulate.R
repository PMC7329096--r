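test_that("the generator is bit-reproducible under a fixed seed", {
  cfg <- sim_config(n_loci = 8L, seed = 71,
                    groups = data.frame(name = c("A", "B", "H"),
                                        size = c(6L, 6L, 4L),
                                        ancestry = c("pop1", "pop2", "f1")),
                    n_clones = 3L, clone_ancestry = "pop2")
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_equal(s1$gm, s2$gm)
  expect_identical(s1$truth$pedigree, s2$truth$pedigree)
  expect_identical(s1$truth$clone_map, s2$truth$clone_map)
})

test_that("configuration bounds are enforced", {
  expect_error(sim_config(divergence_F = 0), "divergence_F")
  expect_error(sim_config(divergence_F = 1), "divergence_F")
  expect_error(sim_config(missing_rate = 1), "rates")
  expect_error(sim_config(groups = data.frame(name = "X", size = 3L,
                                              ancestry = "exotic")))
})

test_that("tiny divergence keeps both pools near the ancestral frequencies", {
  cfg <- sim_config(n_loci = 20L, divergence_F = 1e-6, seed = 72)
  set.seed(cfg$seed)
  fr <- simulate_frequencies(cfg)
  dev <- vapply(fr, function(f)
    max(abs(f$pops[1, ] - f$ancestral), abs(f$pops[2, ] - f$ancestral)), 1.0)
  expect_lt(max(dev), 0.01)
})

test_that("sampled genotypes reproduce the generating frequencies", {
  cfg <- sim_config(n_loci = 3L, seed = 73, allele_range = c(4L, 4L))
  set.seed(73)
  fr <- simulate_frequencies(cfg)
  sim <- simulate_individuals(fr, c(1, 0), 2500, cfg$cp_pools)
  for (l in 1:3) {
    obs <- tabulate(match(as.vector(sim$nuclear[, l, ]), fr[[l]]$sizes), 4) / 5000
    p <- fr[[l]]$pops[1, ]
    se <- sqrt(p * (1 - p) / 5000)
    expect_true(all(abs(obs - p) <= 3 * se + 1e-3))
  }
  expect_error(simulate_individuals(fr, c(0.7, 0.6), 5, cfg$cp_pools))
})

test_that("crosses are Mendelian", {
  # homozygote x homozygote: every offspring heterozygous ij
  nuc <- array(c(150L, 152L, 150L, 152L), dim = c(2, 1, 2))
  off <- simulate_crosses(nuc, c("HAP1", "HAP2"),
                          data.frame(seed = rep(1L, 50), pollen = rep(2L, 50)))
  expect_true(all(off$nuclear[, 1, 1] == 150L & off$nuclear[, 1, 2] == 152L |
                    off$nuclear[, 1, 1] == 152L & off$nuclear[, 1, 2] == 150L))
  expect_identical(unique(off$cp_hap), "HAP1")

  # ij x ij segregates 1:2:1
  set.seed(74)
  nuc2 <- array(c(150L, 150L, 152L, 152L), dim = c(2, 1, 2))
  off2 <- simulate_crosses(nuc2, c("HAP1", "HAP1"),
                           data.frame(seed = rep(1L, 10000),
                                      pollen = rep(2L, 10000)))
  g <- paste(pmin(off2$nuclear[, 1, 1], off2$nuclear[, 1, 2]),
             pmax(off2$nuclear[, 1, 1], off2$nuclear[, 1, 2]))
  counts <- table(factor(g, levels = c("150 150", "150 152", "152 152")))
  p <- stats::chisq.test(counts, p = c(0.25, 0.5, 0.25))$p.value
  expect_gt(p, 0.001)

  nuc3 <- array(c(150L, NA, 150L, NA), dim = c(2, 1, 2))
  expect_error(simulate_crosses(nuc3, c("HAP1", "HAP1"),
                                data.frame(seed = 1L, pollen = 2L)),
               "typed")
})

test_that("every simulated offspring passes trio screening with its true parents", {
  sim <- simulate_dataset(sim_config(
    n_loci = 20L, seed = 75, n_clones = 0L, missing_rate = 0, error_rate = 0,
    groups = data.frame(name = c("P1", "P2", "F1"), size = c(8L, 8L, 6L),
                        ancestry = c("pop1", "pop2", "f1"))))
  ped <- sim$truth$pedigree
  for (i in seq_len(nrow(ped))) {
    expect_length(
      ssrpipe:::trio_incompatible_loci(sim$gm, ped$child[i], ped$seed[i],
                                       ped$pollen[i]), 0)
  }
})

test_that("artifact injection is exactly what the change log says", {
  cfg <- sim_config(n_loci = 10L, seed = 76, n_clones = 4L,
                    missing_rate = 0, error_rate = 0,
                    groups = data.frame(name = c("A", "B"),
                                        size = c(6L, 6L),
                                        ancestry = c("pop1", "pop2")))
  sim <- simulate_dataset(cfg)
  # only clone rows were added; nothing else changed
  expect_identical(n_individuals(sim$gm), 16L)
  expect_true(all(sim$truth$change_log$type == "clone"))
  for (cl in names(sim$truth$clone_map)) {
    orig <- sim$truth$clone_map[[cl]]
    expect_identical(sim$gm$nuclear[cl, , ], sim$gm$nuclear[orig, , ])
  }
  # the planted clones are recovered as synonym groups
  part <- find_synonym_groups(sim$gm)
  expect_identical(sum(lengths(part$groups)) - length(part$groups), 4L)
  expect_identical(part$n_unique, 12L)

  # clones carry their original's group
  grp <- sim$gm$individuals$group
  names(grp) <- individual_names(sim$gm)
  expect_identical(unname(grp[names(sim$truth$clone_map)]),
                   unname(grp[unname(sim$truth$clone_map)]))
})

test_that("injected rates show up in the change log at about the right frequency", {
  cfg <- sim_config(n_loci = 20L, seed = 77, n_clones = 0L,
                    missing_rate = 0.05, error_rate = 0.01,
                    groups = data.frame(name = "A", size = 60L,
                                        ancestry = "pop1"))
  sim <- simulate_dataset(cfg)
  log <- sim$truth$change_log
  n_missing_nuc <- sum(log$type == "missing" & log$detail == "nuclear")
  # 60 x 20 calls at 5%: expect about 60, allow 4 sd
  expect_lt(abs(n_missing_nuc - 60), 4 * sqrt(60 * 0.95) + 1)
  expect_gt(sum(log$type == "error"), 0)
  # every logged missing call is indeed missing
  miss <- log[log$type == "missing" & log$detail == "nuclear", ]
  for (i in seq_len(min(nrow(miss), 20))) {
    expect_true(all(is.na(sim$gm$nuclear[miss$individual[i],
                                         miss$locus[i], ])))
  }
})

test_that("generated datasets satisfy the container invariants", {
  sim <- simulate_dataset(sim_config(n_loci = 6L, seed = 78))
  nuc <- sim$gm$nuclear
  typed <- !is.na(nuc[, , 1])
  expect_true(all(nuc[, , 1][typed] <= nuc[, , 2][typed]))
  expect_true(all(nuc[!is.na(nuc)] > 0))
  expect_identical(sum(duplicated(individual_names(sim$gm))), 0L)
})
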