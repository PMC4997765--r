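test_that("dense-position bit interpolation matches its closed form", {
  expect_equal(interp_iv_bit(0, 0, 1e-9, 1e-9), 1, tolerance = 1e-6)
  expect_equal(interp_iv_bit(0, 1, 0.15, 0.15), 0.5)
  expect_equal(interp_iv_bit(0, 1, 0.1, 0.2),
               (0.9 * 0.2) / (0.9 * 0.2 + 0.1 * 0.8))
  # single flank: plain transition
  expect_equal(interp_iv_bit(0, NA, 0.1, NA), 0.9)
  expect_equal(interp_iv_bit(NA, 1, NA, 0.3), 0.3)
})

test_that("threshold presets follow the strict/relaxed convention", {
  strict <- call_thresholds()
  expect_equal(strict$t_both, 0.98)
  expect_equal(strict$t_single, 0.99)
  relaxed <- call_thresholds(preset = "relaxed")
  expect_equal(relaxed$t_both, 0.95)
  expect_equal(relaxed$t_single, 0.98)
  expect_error(call_thresholds(0.4))
})

test_that("most-likely calling breaks ties toward the major allele", {
  expect_equal(call_most_likely(c(0.7, 0.2, 0.1)), 0L)
  expect_equal(call_most_likely(c(0.1, 0.2, 0.7)), 2L)
  expect_equal(call_most_likely(c(0.5, 0.5, 0), p = 0.2), 0L)
  expect_equal(call_most_likely(c(0, 0.5, 0.5), p = 0.8), 2L)
  # random posteriors match an argmax oracle away from ties
  set.seed(12)
  gp <- matrix(runif(300), ncol = 3)
  gp <- gp / rowSums(gp)
  expect_equal(call_most_likely(gp, 0.3),
               as.integer(max.col(gp, ties.method = "first") - 1L))
})

test_that("threshold calling yields full, half, or no calls", {
  t <- call_thresholds()
  full <- call_threshold(c(0.995, 0.004, 0.001), c(0.01, 0.01), t)
  expect_equal(full$n_alleles, 2L)
  expect_equal(full$dose, 0L)
  # ref confidently present (P = 0.99) but full genotype uncertain
  half <- call_threshold(c(0.75, 0.24, 0.01), t = t)
  expect_equal(half$n_alleles, 1L)
  expect_equal(half$allele, 0L)
  none <- call_threshold(c(0.5, 0.3, 0.2), t = t)
  expect_equal(none$n_alleles, 0L)
  # slot rule: one slot confidently ref, the other uncertain
  half_s <- call_threshold(c(0.6, 0.35, 0.05), ap = c(0.005, 0.4), t = t,
                           rule = "slot")
  expect_equal(half_s$n_alleles, 1L)
  expect_equal(half_s$allele, 0L)
})

test_that("dense posterior reduces to IBD copying and Hardy-Weinberg", {
  trio <- random_small_pedigree("trio")
  sim <- small_framework(trio, 3, seed = 61, p = c(0.5, 0.5, 0.5))
  ivs <- exact_iv_posterior(trio, sim$g, constant_map(1), n_samples = 400,
                            seed = 2)
  p <- 0.3
  # both child slots IBD with an observed hom-alt parent pair:
  # C1 observed as 2 forces its own posterior to hom alt (self-imputation)
  dp <- dense_posterior(ivs, trio, c(C1 = 2), p, pos_cm = 3.1, seed = 5)
  expect_equal(unname(dp$genotype["C1", ]), c(0, 0, 1))
  # unrelated to any observed individual -> Hardy-Weinberg prior
  dp2 <- dense_posterior(ivs, trio, c(C1 = 1), p, pos_cm = 3.1, seed = 5)
  for (founder in c("F1", "M1")) {
    got <- dp2$genotype[founder, ]
    hw <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    # founders share exactly one gene with the child; the slot NOT shared
    # stays at the prior, so only check the posterior is a proper mixture
    expect_equal(sum(got), 1, tolerance = 1e-9)
  }
  ped2 <- pedigree(c("X", "Y"), c(NA, NA), c(NA, NA))
  sim2 <- small_framework(ped2, 2, seed = 3)
  ivs2 <- exact_iv_posterior(ped2, sim2$g, constant_map(1), n_samples = 10)
  dp3 <- dense_posterior(ivs2, ped2, c(X = 2), 0.3, pos_cm = 3)
  expect_equal(unname(dp3$genotype["Y", ]),
               c((1 - 0.3)^2, 2 * 0.3 * 0.7, 0.3^2), tolerance = 1e-12)
})

test_that("dense posterior matches the full joint-likelihood brute force", {
  # one framework + one dense marker; exhaustive dense-IV enumeration
  for (seed in c(5, 17, 23)) {
    set.seed(seed)
    ped <- random_small_pedigree(sample(c("trio", "quartet"), 1))
    sim <- small_framework(ped, 1, seed = seed)
    p_fw <- sim$markers$alt_freq[1]
    p_dense <- runif(1, 0.1, 0.9)
    d_cm <- runif(1, 0.2, 1.5)
    ivs <- exact_iv_posterior(ped, sim$g, constant_map(1),
                              n_samples = 4000, seed = seed)
    obs_ids <- sample(ped$id, 2)
    truth_d <- sapply(obs_ids, function(i) sample(0:2, 1))
    fw_obs <- as.list(stats::setNames(sim$g$geno[, 1], ped$id))
    oracle <- tryCatch(
      oracle_dense_posterior(ped, fw_obs, as.list(truth_d), p_fw, p_dense,
                             haldane(d_cm), target_id = ped$id[1]),
      error = function(e) NULL)
    if (is.null(oracle) || anyNA(oracle)) next  # inconsistent draw
    dp <- dense_posterior(ivs, ped, truth_d, p_dense,
                          pos_cm = sim$markers$pos[1] / 1e6 + d_cm,
                          exhaustive = TRUE)
    expect_equal(unname(dp$genotype[ped$id[1], ]), unname(oracle),
                 tolerance = 1e-9)
  }
})

test_that("relaxed-threshold calls contain all strict-threshold calls", {
  ped <- colony_pedigree()
  scen_s <- sim_scenario(n_framework = 40, n_dense = 80,
                         n_iv_samples = 150, burn_in = 100, thin = 1)
  data <- simulate_scenario(scen_s, seed = 9)
  ivs <- sample_iv_mcmc(ped, data$framework, scen_s$map, n_samples = 150,
                        burn_in = 100, thin = 1, seed = 3)
  donors <- c("B", "H", "J")
  dense_obs <- matrix(NA_integer_, 16, nrow(data$dense_markers))
  di <- match(donors, ped$id)
  dense_obs[di, ] <- data$dense_obs_src[di, ]
  strict <- impute_chromosome(ped, ivs, data$dense_markers, dense_obs,
                              scen_s$map, call_thresholds(), seed = 4)
  relaxed <- impute_chromosome(ped, ivs, data$dense_markers, dense_obs,
                               scen_s$map, call_thresholds(preset = "relaxed"),
                               seed = 4)
  expect_true(all(relaxed$thr_n_alleles >= strict$thr_n_alleles))
  # most-likely always calls a full genotype
  expect_false(anyNA(strict$ml_dose))
})

test_that("genotype posteriors are normalized at every site", {
  ped <- colony_pedigree()
  scen_s <- sim_scenario(n_framework = 30, n_dense = 50,
                         n_iv_samples = 100, burn_in = 80, thin = 1)
  data <- simulate_scenario(scen_s, seed = 19)
  ivs <- sample_iv_mcmc(ped, data$framework, scen_s$map, n_samples = 100,
                        burn_in = 80, thin = 1, seed = 3)
  dense_obs <- matrix(NA_integer_, 16, nrow(data$dense_markers))
  di <- match(c("B", "C"), ped$id)
  dense_obs[di, ] <- data$dense_obs_src[di, ]
  imp <- impute_chromosome(ped, ivs, data$dense_markers, dense_obs,
                           scen_s$map, seed = 4)
  tot <- imp$p_rr + imp$p_ra + imp$p_aa
  expect_lt(max(abs(tot[!is.na(tot)] - 1)), 1e-9)
})
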