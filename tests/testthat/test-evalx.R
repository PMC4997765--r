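# minimal hand-built imputation object for metric tests
fake_imp <- function(thr_n, thr_dose, thr_allele, ml_dose, markers, ids,
                     donors = character(0)) {
  structure(list(ids = ids, markers = markers, donors = donors,
                 thr_n_alleles = thr_n, thr_dose = thr_dose,
                 thr_allele = thr_allele, ml_dose = ml_dose),
            class = "imputation")
}

test_that("allele accuracy counts multiset matches per attempted allele", {
  mk <- data.frame(chrom = "c1", pos = 1:5 * 100, ref = "A", alt = "G",
                   alt_freq = 0.3)
  ids <- c("x", "y")
  truth <- rbind(c(0L, 1L, 2L, 1L, 0L), c(2L, 2L, 2L, 2L, 2L))
  # x: full calls RR, RA, RA (vs truth 0,1,2), one half-call alt (vs 1),
  #    one no-call
  thr_n <- rbind(c(2L, 2L, 2L, 1L, 0L), rep(2L, 5))
  thr_dose <- rbind(c(0L, 1L, 1L, NA, NA), rep(1L, 5))
  thr_allele <- rbind(c(NA, NA, NA, 1L, NA), rep(NA, 5))
  ml <- rbind(c(0L, 1L, 1L, 1L, 1L), rep(2L, 5))
  imp <- fake_imp(thr_n, thr_dose, thr_allele, ml, mk, ids)
  acc <- allele_accuracy(imp, truth, ids = "x")
  # attempted 2+2+2+1 = 7; correct 2+2+1+1 = 6
  expect_equal(acc$attempted, 7L)
  expect_equal(acc$correct, 6L)
  expect_equal(acc$accuracy, 6 / 7)
  expect_equal(acc$marker_fraction, 4 / 5)
  expect_equal(acc$allele_fraction, 7 / 10)
  # two-allele RA call against AA truth: 1 of 2 alleles correct
  acc_y <- allele_accuracy(imp, truth, ids = "y")
  expect_equal(acc_y$accuracy, 0.5)
  # most-likely is always a full call; x: ml vs truth
  accml <- allele_accuracy(imp, truth, ids = "x", method = "most_likely")
  expect_equal(accml$attempted, 10L)
  expect_equal(accml$correct, 2L + 2L + 1L + 2L + 1L)
  expect_equal(fraction_imputed(imp, "x", "most_likely")$marker_fraction, 1)
  expect_equal(fraction_imputed(imp, "x")$marker_fraction, 0.8)
})

test_that("frequency stratification bins every true allele copy once", {
  mk <- data.frame(chrom = "c1", pos = 1:4 * 100, ref = "A", alt = "G",
                   alt_freq = c(0.1, 0.3, 0.6, 0.9))
  ids <- "x"
  truth <- matrix(c(1L, 1L, 1L, 1L), 1)
  thr_n <- matrix(c(2L, 2L, 0L, 1L), 1)
  thr_dose <- matrix(c(1L, 1L, NA, NA), 1)
  thr_allele <- matrix(c(NA, NA, NA, 1L), 1)
  imp <- fake_imp(thr_n, thr_dose, thr_allele, thr_dose, mk, ids)
  st <- stratify_by_freq(imp, truth, ids = "x", ref_chroms = 30)
  # every het site contributes one alt copy (bin of p) and one ref copy
  # (bin of 1-p); totals must cover 8 copies
  expect_equal(sum(st$n_true[1:4]), 8)
  # the p = 0.1 alt copy: round(0.1*30) = 3 copies, not singleton
  expect_equal(st$n_true[st$bin == "[0,0.25)"], 2)  # alt@0.1 + ref@0.9
  # singleton row exists with correct accounting for p = 1/30-ish bins
  expect_true("singleton" %in% st$bin)
  # called-and-correct copies: marker1 RA vs truth 1 -> both correct
  expect_equal(sum(st$n_correct[1:4]), 2 + 2 + 0 + 1)
})

test_that("genotype concordance compares co-called cells only", {
  mk <- data.frame(chrom = "c1", pos = 1:100 * 10, ref = "A", alt = "G")
  a <- genotype_matrix(c("s1"), mk, matrix(rep(0:1, 50), 1))
  b <- genotype_matrix(c("s1"), mk, matrix(rep(0:1, 50), 1))
  expect_equal(genotype_concordance(a, b)$concordance, 1)
  g2 <- b$geno
  g2[1, 7] <- 2L
  g2[1, 9] <- NA
  b2 <- genotype_matrix("s1", mk, g2)
  cc <- genotype_concordance(a, b2)
  expect_equal(cc$concordance, 98 / 99)
  expect_equal(cc$n_both, 99L)

  # simulated down-sampling comparison: deep vs shallow observation of the
  # same truth matches a cell-count oracle
  ped <- colony_pedigree()
  mks <- data.frame(chrom = "c1", pos = seq_len(200) * 1000, ref = "A",
                    alt = "G", alt_freq = 0.4)
  tr <- simulate_truth(ped, mks, constant_map(1), seed = 31)
  deep <- simulate_observation(tr, coverage_model(30, 0.01), seed = 1)
  shallow <- simulate_observation(tr, coverage_model(12, 0.01), seed = 2)
  cc2 <- genotype_concordance(deep, shallow)
  both <- !is.na(deep$geno) & !is.na(shallow$geno)
  expect_equal(cc2$n_both, sum(both))
  expect_equal(cc2$concordance,
               mean(deep$geno[both] == shallow$geno[both]))
  expect_gt(cc2$concordance, 0.97)
})

test_that("masking non-framework markers keeps a recoverable truth store", {
  ped <- colony_pedigree()
  mk <- data.frame(chrom = "c1", pos = seq_len(50) * 1000, ref = "A",
                   alt = "G", alt_freq = 0.4)
  tr <- simulate_truth(ped, mk, constant_map(1), seed = 2)
  g <- genotype_matrix(ped$id, mk, truth_genotypes(tr))
  fw <- mk[seq(1, 50, by = 5), ]
  out <- mask_nonframework(g, fw)
  expect_equal(ncol(out$truth), 40L)
  expect_true(all(is.na(out$masked$geno[, attr(out$truth, "marker_idx")])))
  expect_identical(out$masked$geno[, seq(1, 50, by = 5)],
                   g$geno[, seq(1, 50, by = 5)])
  expect_equal(out$truth, g$geno[, -seq(1, 50, by = 5)],
               ignore_attr = TRUE)
  # framework-only matrix: identity, empty truth store
  fw_only <- subset_genotypes(g, markers = seq(1, 50, by = 5))
  out2 <- mask_nonframework(fw_only, fw)
  expect_equal(ncol(out2$truth), 0L)
  expect_identical(out2$masked$geno, fw_only$geno)
})

test_that("experiment drivers are reproducible given the seed", {
  scen <- sim_scenario(n_framework = 25, n_dense = 40, n_iv_samples = 60,
                       burn_in = 40, thin = 1)
  a <- run_strategy_comparison(scen, n_donors = 3, n_replicates = 1,
                               seed = 5)
  b <- run_strategy_comparison(scen, n_donors = 3, n_replicates = 1,
                               seed = 5)
  expect_identical(a, b)
  sw <- run_wgs_ratio_sweep(scen, donor_order = wgs_candidates(),
                            n_donors = c(1, 3), n_replicates = 1, seed = 6)
  expect_setequal(unique(sw$n_donors), c(1, 3))
})
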