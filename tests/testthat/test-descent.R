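test_that("descent partitions follow the selected parental slots", {
  trio <- random_small_pedigree("trio")
  part <- build_descent(trio, c(0, 0))
  # child copies the father's and mother's own paternal genes
  expect_equal(unname(part["C1", ]), unname(part[c("F1", "M1"), 1]))
  part2 <- build_descent(trio, c(1, 0))
  expect_equal(unname(part2["C1", "paternal"]), unname(part2["F1", 2]))
  expect_error(build_descent(trio, c(0, 0, 0)), "meiosis count")

  # all-zero IV: only grand-paternal-line genes appear below founders
  ped <- colony_pedigree()
  p0 <- build_descent(ped, rep(0L, 16))
  for (i in which(!ped$founder)) {
    expect_equal(p0[i, 1], p0[ped$sire[i], 1])
    expect_equal(p0[i, 2], p0[ped$dam[i], 1])
  }
})

test_that("descent labels match a recursive path-tracing oracle", {
  ped <- colony_pedigree()
  trace <- function(iv, i, slot) {
    if (ped$founder[i]) return(2L * ped$founder_rank[i] - 2L + slot)
    mei <- if (slot == 1L) ped$pat_meiosis[i] else ped$mat_meiosis[i]
    par <- if (slot == 1L) ped$sire[i] else ped$dam[i]
    trace(iv, par, iv[mei] + 1L)
  }
  set.seed(4)
  for (rep in 1:20) {
    iv <- sample(0:1, 16, replace = TRUE)
    part <- build_descent(ped, iv)
    for (i in seq_along(ped$id)) {
      expect_equal(part[i, 1], trace(iv, i, 1L))
      expect_equal(part[i, 2], trace(iv, i, 2L))
    }
  }
})

test_that("locus likelihood matches hand-computable cases", {
  trio <- random_small_pedigree("trio")
  part <- build_descent(trio, c(0, 0))
  expect_equal(locus_likelihood(part, c(X = NA), 0.3), 1)  # no observations
  # one individual, two distinct genes, hom alt -> p^2
  expect_equal(locus_likelihood(part, c(F1 = 2), 0.3), 0.09)
  # shared gene contradiction: father hom-ref, child hom-alt
  expect_equal(locus_likelihood(part, c(F1 = 0, M1 = 0, C1 = 2), 0.3), 0)
  expect_error(locus_likelihood(part, c(ZZ = 1), 0.3), "unknown id")
})

test_that("locus likelihood equals founder-assignment enumeration", {
  set.seed(77)
  for (nm in c("trio", "quartet", "sibs3", "grand")) {
    ped <- random_small_pedigree(nm)
    for (rep in 1:25) {
      iv <- sample(0:1, ped$n_meioses, replace = TRUE)
      part <- build_descent(ped, iv)
      n_obs <- sample(seq_along(ped$id), 1)
      ids <- sample(ped$id, n_obs)
      obs <- stats::setNames(sample(0:2, n_obs, replace = TRUE), ids)
      p <- runif(1, 0.05, 0.95)
      got <- locus_likelihood(part, obs, p)
      want <- oracle_locus_lik(part, as.list(obs), p)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("transition probabilities factorize over meioses", {
  expect_equal(transition_prob(c(0, 1), c(0, 1), 0), 1)
  expect_equal(transition_prob(c(0, 0), c(1, 0), 0.1), 0.1 * 0.9)
  # normalization over all targets
  tot <- sum(vapply(0:15, function(s) {
    transition_prob(c(0, 1, 0, 1), bitwAnd(bitwShiftR(s, 0:3), 1L), 0.23)
  }, numeric(1)))
  expect_equal(tot, 1)
  expect_error(transition_prob(c(0), c(0, 1), 0.1), "mismatch")
})

test_that("exact HMM marginals equal joint-sequence enumeration", {
  for (cfg in list(list(ped = "trio", T = 2, seed = 1),
                   list(ped = "trio", T = 4, seed = 2),
                   list(ped = "quartet", T = 3, seed = 3),
                   list(ped = "sibs3", T = 2, seed = 4),
                   list(ped = "grand", T = 2, seed = 5))) {
    ped <- random_small_pedigree(cfg$ped)
    sim <- small_framework(ped, cfg$T, seed = cfg$seed)
    ivp <- exact_iv_posterior(ped, sim$g, constant_map(1), n_samples = 0,
                              seed = 1)
    inp <- pedimpute:::.iv_inputs(ped, sim$g, constant_map(1))
    obs <- sim$g$geno
    rownames(obs) <- ped$id
    want <- oracle_iv_marginals(ped, obs, inp$theta, inp$p)
    expect_lt(max(abs(ivp$marginals - want)), 1e-12)
  }
})

test_that("uninformative data gives the uniform IV posterior", {
  trio <- random_small_pedigree("trio")
  mk <- data.frame(chrom = "c1", pos = 100, ref = "A", alt = "G",
                   alt_freq = 0.4)
  g <- genotype_matrix(trio$id, mk, matrix(NA_integer_, 3, 1))
  ivp <- exact_iv_posterior(trio, g, constant_map(1), n_samples = 0)
  expect_equal(as.vector(ivp$marginals), rep(1 / 4, 4))
  # fully homozygous data: likelihood is IV-independent
  g2 <- genotype_matrix(trio$id, mk, matrix(c(0L, 0L, 0L), 3, 1))
  ivp2 <- exact_iv_posterior(trio, g2, constant_map(1), n_samples = 0)
  expect_equal(as.vector(ivp2$marginals), rep(1 / 4, 4))
})

test_that("exact mode rejects oversized pedigrees and impossible data", {
  trio <- random_small_pedigree("trio")
  mk <- data.frame(chrom = "c1", pos = 100, ref = "A", alt = "G",
                   alt_freq = 0.4)
  g <- genotype_matrix(trio$id, mk, matrix(c(0L, 0L, 2L), 3, 1))
  expect_error(exact_iv_posterior(trio, g, constant_map(1)),
               "Mendelian-impossible")
  expect_error(exact_iv_posterior(colony_pedigree(),
                                  small_framework(colony_pedigree(), 2,
                                                  seed = 1)$g,
                                  constant_map(1), m_max = 4),
               "m_max")
})

test_that("MCMC marginals agree with the exact posterior", {
  tv_max <- 0
  for (cfg in list(list(ped = "trio", T = 3, seed = 11),
                   list(ped = "quartet", T = 3, seed = 12),
                   list(ped = "sibs3", T = 2, seed = 13))) {
    ped <- random_small_pedigree(cfg$ped)
    sim <- small_framework(ped, cfg$T, seed = cfg$seed)
    ivp <- exact_iv_posterior(ped, sim$g, constant_map(1), n_samples = 0)
    mc <- sample_iv_mcmc(ped, sim$g, constant_map(1), n_samples = 20000,
                         burn_in = 500, thin = 1, seed = 99)
    S <- 2^ped$n_meioses
    for (t in seq_len(cfg$T)) {
      emp <- tabulate(mc$samples[, t] + 1L, nbins = S) / nrow(mc$samples)
      tv <- 0.5 * sum(abs(emp - ivp$marginals[t, ]))
      tv_max <- max(tv_max, tv)
      expect_lt(tv, 0.02)
    }
  }
})

test_that("MCMC is reproducible and uniform under no data", {
  trio <- random_small_pedigree("trio")
  sim <- small_framework(trio, 3, seed = 21)
  a <- sample_iv_mcmc(trio, sim$g, constant_map(1), n_samples = 200,
                      burn_in = 50, thin = 2, seed = 7)
  b <- sample_iv_mcmc(trio, sim$g, constant_map(1), n_samples = 200,
                      burn_in = 50, thin = 2, seed = 7)
  expect_identical(a$samples, b$samples)

  # unobserved data: empirical IV distribution uniform (chi-square GOF)
  mk <- data.frame(chrom = "c1", pos = c(1e6, 2e6), ref = "A", alt = "G",
                   alt_freq = 0.5)
  g0 <- genotype_matrix(trio$id, mk, matrix(NA_integer_, 3, 2))
  mc <- sample_iv_mcmc(trio, g0, constant_map(1), n_samples = 8000,
                       burn_in = 200, thin = 2, seed = 31)
  counts <- tabulate(mc$samples[, 1] + 1L, nbins = 4)
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
})

test_that("every retained IV realization is consistent with the data", {
  ped <- random_small_pedigree("sibs3")
  sim <- small_framework(ped, 4, seed = 41)
  mc <- sample_iv_mcmc(ped, sim$g, constant_map(1), n_samples = 300,
                       burn_in = 100, thin = 1, seed = 5)
  for (s in sample(nrow(mc$samples), 20)) {
    bits <- iv_bits(mc, s)
    for (t in seq_len(mc$n_markers)) {
      obs <- stats::setNames(sim$g$geno[, t], ped$id)
      lik <- locus_likelihood(ped, obs, sim$markers$alt_freq[t],
                              iv = bits[, t])
      expect_gt(lik, 0)
    }
  }
})
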