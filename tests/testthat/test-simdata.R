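test_that("colony template satisfies its documented constraints", {
  ped <- colony_pedigree()
  expect_equal(length(ped$id), 16L)
  expect_true(all(c("A", "B", "C", "D", "E") %in% founders(ped)))
  # K is a child of D
  expect_equal(ped$id[ped$sire[match("K", ped$id)]], "D")
  # M, P, K childless
  expect_true(all(c("M", "P", "K") %in% childless(ped)))
  # E's only relative is the childless non-candidate N
  kin_E <- Filter(function(x) {
    !"unrelated" %in% relationship_classes(ped, "E", x)
  }, setdiff(ped$id, "E"))
  expect_equal(kin_E, "N")
  expect_false("N" %in% wgs_candidates())
  expect_true("N" %in% childless(ped))
  # relationship audit: one pair of each common colony class
  need <- c("parent_offspring", "half_sibling", "half_avuncular",
            "half_cousin", "grandparent_grandchild")
  seen <- character(0)
  for (a in ped$id) {
    for (b in ped$id) {
      if (a < b) seen <- union(seen, relationship_classes(ped, a, b))
    }
  }
  expect_true(all(need %in% seen))
})

test_that("gene dropping respects map distances and founder frequencies", {
  trio <- random_small_pedigree("trio")
  # zero genetic distance: no recombinant meioses
  mk0 <- data.frame(chrom = "c1", pos = c(500, 500 + 1), ref = "A",
                    alt = "G", alt_freq = 0.5)
  zerorate <- genetic_map(data.frame(chrom = "c1", pos_bp = c(1, 1e6),
                                     pos_cm = c(0, 1e-12)))
  flips <- 0
  for (s in 1:200) {
    tr <- simulate_truth(trio, mk0, zerorate, seed = s)
    flips <- flips + sum(tr$iv[, 1] != tr$iv[, 2])
  }
  expect_equal(flips, 0)

  # founder allele frequency within 3 binomial SEs
  ped <- colony_pedigree()
  mk <- data.frame(chrom = "c1", pos = seq_len(500) * 1000, ref = "A",
                   alt = "G", alt_freq = 0.3)
  tr <- simulate_truth(ped, mk, constant_map(1), seed = 8)
  fi <- ped$founder
  freq <- mean(c(tr$pat_allele[fi, ], tr$mat_allele[fi, ]))
  n_draws <- 2 * sum(fi) * 500
  se <- sqrt(0.3 * 0.7 / n_draws)
  expect_lt(abs(freq - 0.3), 3 * se)

  # truth is Mendelian-consistent by construction
  g <- genotype_matrix(ped$id, mk, truth_genotypes(tr))
  expect_equal(nrow(mendelian_errors(ped, g)), 0L)

  # slot labels recompute exactly from the recorded IVs
  for (t in c(1, 250, 500)) {
    part <- build_descent(ped, tr$iv[, t])
    expect_equal(unname(part[, 1]), unname(tr$pat_label[, t]))
    expect_equal(unname(part[, 2]), unname(tr$mat_label[, t]))
  }

  # recombination fraction per interval within binomial CI of haldane
  mk2 <- data.frame(chrom = "c1", pos = c(1, 2e6 + 1), ref = "A", alt = "G",
                    alt_freq = 0.5)
  theta <- haldane(2)
  rec <- 0
  for (s in 1:400) {
    tr2 <- simulate_truth(trio, mk2, constant_map(1), seed = 1000 + s)
    rec <- rec + sum(tr2$iv[, 1] != tr2$iv[, 2])
  }
  n <- 400 * 2
  expect_lt(abs(rec / n - theta), 3 * sqrt(theta * (1 - theta) / n))
})

test_that("observation model calls, filters, and reproduces truth", {
  ped <- colony_pedigree()
  mk <- data.frame(chrom = "c1", pos = seq_len(400) * 1000, ref = "A",
                   alt = "G", alt_freq = 0.4)
  tr <- simulate_truth(ped, mk, constant_map(1), seed = 3)
  # error-free deep sequencing: calls equal truth wherever non-missing
  g <- simulate_observation(tr, coverage_model(60, 0), seed = 4)
  truth <- truth_genotypes(tr)
  nm <- !is.na(g$geno)
  expect_true(all(g$geno[nm] == truth[nm]))
  expect_gt(mean(nm), 0.99)

  # depth below 10 is always filtered
  glow <- simulate_observation(tr, coverage_model(4, 0.01), seed = 5)
  expect_true(all(is.na(glow$geno[glow$depth < 10])))

  # realistic noise: concordance of non-missing calls >= 0.99
  gn <- simulate_observation(tr, coverage_model(30, 0.01), seed = 6)
  nm <- !is.na(gn$geno)
  expect_gte(mean(gn$geno[nm] == truth[nm]), 0.99)

  # reproducibility
  g2 <- simulate_observation(tr, coverage_model(30, 0.01), seed = 6)
  expect_identical(gn$geno, g2$geno)
})

test_that("GBS designs sparsify markers and cells as specified", {
  ped <- colony_pedigree()
  mk <- data.frame(chrom = "c1", pos = seq_len(625) * 1000, ref = "A",
                   alt = "G", alt_freq = 0.4)
  tr <- simulate_truth(ped, mk, constant_map(1), seed = 7)
  g <- genotype_matrix(ped$id, mk, truth_genotypes(tr))
  # identity design
  all_kept <- apply_gbs_design(g, gbs_design(seq_len(625), 1), seed = 1)
  expect_identical(all_kept$geno, g$geno)
  # markers outside the design become missing everywhere
  half <- apply_gbs_design(g, gbs_design(1:300, 1), seed = 1)
  expect_true(all(is.na(half$geno[, 301:625])))
  expect_false(anyNA(half$geno[, 1:300]))
  # per-cell retention close to the nominal 0.69 call rate
  thin <- apply_gbs_design(g, gbs_design(seq_len(625), 0.69), seed = 2)
  kept <- mean(!is.na(thin$geno))
  n <- length(thin$geno)
  expect_lt(abs(kept - 0.69), 3 * sqrt(0.69 * 0.31 / n))
})
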