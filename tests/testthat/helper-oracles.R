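# Independent brute-force oracles used to verify the package's closed-form
# and HMM computations. These deliberately use naive enumeration, not the
# implementation's algorithms.

# naive character-by-character IUPAC motif scan (both strands)
oracle_scan <- function(seq, enzyme) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  rc <- function(m) paste(rev(comp[strsplit(m, "")[[1]]]), collapse = "")
  s <- strsplit(toupper(seq), "")[[1]]
  scan1 <- function(motif, off) {
    mm <- strsplit(motif, "")[[1]]
    L <- length(mm)
    n_pos <- length(s) - L + 1
    if (n_pos < 1) return(integer(0))
    ok <- rep(TRUE, n_pos)
    for (k in seq_len(L)) {  # character-by-character comparison
      ok <- ok & s[k:(n_pos + k - 1)] %in% iupac[[mm[k]]]
    }
    which(ok) - 1L + off
  }
  fwd <- scan1(enzyme$motif, enzyme$cut_offset)
  rcm <- rc(enzyme$motif)
  if (rcm == enzyme$motif) return(sort(fwd))
  rev <- scan1(rcm, nchar(enzyme$motif) - enzyme$cut_offset)
  sort(unique(c(fwd, rev)))
}

# brute-force single-locus likelihood: enumerate all founder-allele
# assignments over the genes carried by observed individuals
oracle_locus_lik <- function(part, obs, p) {
  ids <- rownames(part)
  oi <- which(ids %in% names(obs))
  genes <- sort(unique(as.vector(part[oi, , drop = FALSE])))
  k <- length(genes)
  if (k == 0) return(1)
  tot <- 0
  for (a in 0:(2^k - 1)) {
    al <- integer(max(part))
    al[genes] <- bitwAnd(bitwShiftR(a, seq_len(k) - 1L), 1L)
    ok <- all(vapply(oi, function(i) {
      al[part[i, 1]] + al[part[i, 2]] == obs[[ids[i]]]
    }, logical(1)))
    if (ok) tot <- tot + prod(ifelse(al[genes] == 1, p, 1 - p))
  }
  tot
}

# exhaustive joint enumeration of IV sequences for the HMM posterior
oracle_iv_marginals <- function(ped, obs_mat, theta, p) {
  m <- ped$n_meioses
  S <- 2^m
  T_ <- ncol(obs_mat)
  emis <- matrix(0, T_, S)
  for (s in 0:(S - 1)) {
    bits <- bitwAnd(bitwShiftR(s, 0:(m - 1)), 1L)
    part <- build_descent(ped, bits)
    for (t in seq_len(T_)) {
      o <- obs_mat[, t]
      names(o) <- ped$id
      o <- o[!is.na(o)]
      emis[t, s + 1] <- oracle_locus_lik(part, as.list(o), p[t])
    }
  }
  seqs <- as.matrix(expand.grid(rep(list(0:(S - 1)), T_)))
  marg <- matrix(0, T_, S)
  for (r in seq_len(nrow(seqs))) {
    pr <- 1 / S
    for (t in seq_len(T_)) {
      s <- seqs[r, t]
      if (t > 1) {
        k <- sum(bitwAnd(bitwShiftR(bitwXor(s, seqs[r, t - 1]),
                                    0:(m - 1)), 1L))
        pr <- pr * theta[t - 1]^k * (1 - theta[t - 1])^(m - k)
      }
      pr <- pr * emis[t, s + 1]
    }
    if (pr > 0) {
      for (t in seq_len(T_)) {
        marg[t, seqs[r, t] + 1] <- marg[t, seqs[r, t] + 1] + pr
      }
    }
  }
  sweep(marg, 1, rowSums(marg), "/")
}

# 27-combination trio table: which (father, mother, child) dosage triples
# are Mendelian-possible
oracle_trio_possible <- function(f, m, c) {
  from <- list(`0` = 0L, `1` = 0:1, `2` = 1L)
  c %in% outer(from[[as.character(f)]], from[[as.character(m)]], "+")
}

# full joint brute force for the dense-site posterior: enumerate framework
# IVs, dense IVs and founder assignments at both markers jointly
oracle_dense_posterior <- function(ped, fw_obs, dense_obs, p_fw, p_dense,
                                   theta_fd, target_id) {
  m <- ped$n_meioses
  S <- 2^m
  n <- length(ped$id)
  gpost <- c(RR = 0, RA = 0, AA = 0)
  norm <- 0
  for (sf in 0:(S - 1)) {
    bits_f <- bitwAnd(bitwShiftR(sf, 0:(m - 1)), 1L)
    part_f <- build_descent(ped, bits_f)
    lik_f <- oracle_locus_lik(part_f, fw_obs, p_fw)
    if (lik_f == 0) next
    for (sd in 0:(S - 1)) {
      bits_d <- bitwAnd(bitwShiftR(sd, 0:(m - 1)), 1L)
      k <- sum(bits_f != bits_d)
      trans <- theta_fd^k * (1 - theta_fd)^(m - k)
      part_d <- build_descent(ped, bits_d)
      # enumerate founder alleles at the dense site over ALL genes
      G <- max(part_d)
      for (a in 0:(2^G - 1)) {
        al <- bitwAnd(bitwShiftR(a, 0:(G - 1)), 1L)
        ok <- all(vapply(names(dense_obs), function(id) {
          i <- match(id, ped$id)
          al[part_d[i, 1]] + al[part_d[i, 2]] == dense_obs[[id]]
        }, logical(1)))
        if (!ok) next
        w <- (1 / S) * lik_f * trans *
          prod(ifelse(al == 1, p_dense, 1 - p_dense))
        ti <- match(target_id, ped$id)
        dose <- al[part_d[ti, 1]] + al[part_d[ti, 2]]
        gpost[dose + 1] <- gpost[dose + 1] + w
        norm <- norm + w
      }
    }
  }
  gpost / norm
}

# small random pedigree battery: trio, quartet, three-generation chain
random_small_pedigree <- function(which = c("trio", "quartet", "sibs3",
                                            "grand")) {
  which <- match.arg(which)
  switch(which,
    trio = pedigree(c("F1", "M1", "C1"), c(NA, NA, "F1"), c(NA, NA, "M1")),
    quartet = pedigree(c("F1", "M1", "C1", "C2"),
                       c(NA, NA, "F1", "F1"), c(NA, NA, "M1", "M1")),
    sibs3 = pedigree(c("F1", "M1", "C1", "C2", "C3"),
                     c(NA, NA, "F1", "F1", "F1"),
                     c(NA, NA, "M1", "M1", "M1")),
    grand = pedigree(c("F1", "M1", "C1", "M2", "G1"),
                     c(NA, NA, "F1", NA, "C1"),
                     c(NA, NA, "M1", NA, "M2"))
  )
}

# simulate a small framework dataset on a pedigree (all members observed)
small_framework <- function(ped, n_markers, seed, p = NULL, spacing_bp = 2e6) {
  set.seed(seed)
  if (is.null(p)) p <- runif(n_markers, 0.3, 0.7)
  markers <- data.frame(chrom = "c1", pos = spacing_bp * seq_len(n_markers),
                        ref = "A", alt = "G", alt_freq = p,
                        stringsAsFactors = FALSE)
  truth <- simulate_truth(ped, markers, constant_map(1), seed = seed + 1)
  g <- genotype_matrix(ped$id, markers, truth_genotypes(truth))
  list(g = g, truth = truth, markers = markers)
}
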