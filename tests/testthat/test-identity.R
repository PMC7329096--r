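test_that("planted clones form a single synonym group with the first name as representative", {
  set.seed(11)
  base <- random_gm(5, 8)
  # individuals 2 and 5 become clones of individual 1
  base$nuclear[2, , ] <- base$nuclear[1, , ]
  base$nuclear[5, , ] <- base$nuclear[1, , ]
  part <- find_synonym_groups(base)
  expect_length(part$groups, 1)
  expect_identical(part$groups[[1]], c("ind1", "ind2", "ind5"))
  expect_identical(part$representatives, "ind1")
  expect_identical(part$n_unique, 3L)
  expect_identical(part$unique_individuals, c("ind1", "ind3", "ind4"))

  dd <- dedupe(base, part)
  expect_identical(individual_names(dd), c("ind1", "ind3", "ind4"))
})

test_that("all-distinct genotypes yield no groups; empty input is not an error", {
  gm <- mk_gm(list(L1 = rbind(c(150L, 150L), c(152L, 152L), c(154L, 154L))))
  part <- find_synonym_groups(gm)
  expect_length(part$groups, 0)
  expect_identical(part$n_unique, 3L)
  expect_equal(dedupe(gm, part), gm)

  empty <- genotype_matrix(character(0),
                           nuclear = array(NA_integer_, c(0, 1, 2)))
  expect_identical(find_synonym_groups(empty)$n_input, 0L)
})

test_that("hash-based grouping equals the all-pairs union-find oracle", {
  set.seed(12)
  for (rep in 1:25) {
    n <- 30
    clones <- sample(n, sample(0:4, 1), replace = TRUE)
    gm <- random_gm(n, 6, n_alleles = 3,
                    missing_rate = sample(c(0, 0.1), 1), clones = clones)
    mm <- sample(0:1, 1)
    got <- canon_groups(find_synonym_groups(gm, max_mismatch = mm)$groups)
    want <- synonym_oracle(gm, max_mismatch = mm)
    expect_identical(got, want)
  }
})

test_that("planting k clones of one genotype yields exactly one group of size k + 1", {
  set.seed(13)
  for (k in c(1, 3, 5)) {
    gm <- random_gm(20, 10, n_alleles = 6, clones = rep(7L, k))
    part <- find_synonym_groups(gm)
    grp <- Filter(function(g) "ind7" %in% g, part$groups)
    expect_length(grp, 1)
    expect_length(grp[[1]], k + 1)
  }
})

test_that("under-typed individuals are flagged, never matched", {
  gm <- mk_gm(list(L1 = rbind(c(150L, 150L), c(150L, 150L), c(150L, 150L)),
                   L2 = rbind(c(200L, 202L), c(200L, 202L), c(NA, NA)),
                   L3 = rbind(c(300L, 300L), c(300L, 300L), c(NA, NA)),
                   L4 = rbind(c(400L, 400L), c(400L, 400L), c(NA, NA))))
  part <- find_synonym_groups(gm)
  expect_identical(part$flagged, "ind3")
  expect_identical(part$groups[[1]], c("ind1", "ind2"))
  expect_false("ind3" %in% unlist(part$groups))
})

test_that("dedupe rejects a stale partition", {
  gm <- random_gm(6, 4, clones = 2L)
  part <- find_synonym_groups(gm)
  smaller <- subset(gm, individuals = individual_names(gm)[1:3])
  expect_error(dedupe(smaller, part), "stale")
})

test_that("single-locus PI matches hand values and the enumeration oracle", {
  mono <- structure(list(freqs = c(`150` = 1), n_genes = 10L),
                    class = "allele_freqs")
  expect_equal(pi_locus(mono), 1.0)

  two <- structure(list(freqs = c(0.5, 0.5), n_genes = 20L),
                   class = "allele_freqs")
  expect_equal(pi_locus(two), 0.375)

  three <- structure(list(freqs = c(0.5, 0.3, 0.2), n_genes = 20L),
                     class = "allele_freqs")
  expect_equal(pi_locus(three), 0.2166)

  set.seed(14)
  for (rep in 1:200) {
    p <- as.vector(rmultinom(1, 40, runif(sample(2:8, 1)))) / 40
    p <- p[p > 0]
    fr <- structure(list(freqs = p, n_genes = 40L), class = "allele_freqs")
    expect_equal(pi_locus(fr), pi_oracle(p), tolerance = 1e-12)
  }

  expect_error(pi_locus(structure(list(freqs = numeric(0), n_genes = 0L),
                                  class = "allele_freqs")), "empty")
})

test_that("panel PI multiplies across loci and never increases with more loci", {
  # two loci, each with frequencies (0.5, 0.5) -> per-locus 0.375
  gm <- mk_gm(list(L1 = rbind(c(150L, 150L), c(152L, 152L)),
                   L2 = rbind(c(200L, 200L), c(202L, 202L))))
  res <- pi_panel(gm)
  expect_equal(res$per_locus$pi, c(0.375, 0.375))
  expect_equal(res$mean_pi, 0.375)
  expect_equal(res$cumulative_pi, 0.140625)

  one <- pi_panel(subset(gm, individuals = individual_names(gm)),
                  groups = NULL)
  expect_equal(pi_panel(mk_gm(list(L1 = rbind(c(150L, 150L),
                                              c(152L, 152L)))))$cumulative_pi,
               0.375)

  set.seed(15)
  gm_big <- random_gm(20, 8)
  cums <- vapply(1:8, function(k) {
    sub <- genotype_matrix(gm_big$individuals,
                           gm_big$nuclear[, 1:k, , drop = FALSE])
    pi_panel(sub)$cumulative_pi
  }, 1.0)
  expect_true(all(diff(cums) <= 1e-15))
})

test_that("an all-missing locus is excluded from PI with a warning", {
  arr <- array(NA_integer_, c(2, 2, 2), dimnames = list(NULL, c("A", "B"), NULL))
  arr[, 1, ] <- c(150L, 152L, 152L, 154L)
  gm <- genotype_matrix(c("x", "y"), nuclear = arr)
  expect_warning(res <- pi_panel(gm), "B")
  expect_identical(res$per_locus$locus, "A")
})

test_that("the unbiased PI variant approaches the naive form in large samples", {
  p <- c(0.4, 0.35, 0.25)
  small <- structure(list(freqs = p, n_genes = 12L), class = "allele_freqs")
  large <- structure(list(freqs = p, n_genes = 4000L), class = "allele_freqs")
  expect_equal(pi_locus(large, unbiased = TRUE), pi_locus(large),
               tolerance = 1e-2)
  expect_false(isTRUE(all.equal(pi_locus(small, unbiased = TRUE),
                                pi_locus(small), tolerance = 1e-3)))
})
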