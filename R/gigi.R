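#' Interpolate an inheritance bit at a dense position
#'
#' Probability that a meiosis transmits the paternal slot (bit 0) at a dense
#' position, given its bits at the flanking framework markers:
#' `P(b = x | left, right) = P(left -> x) P(x -> right) / sum_y ...`, each
#' factor a two-state Haldane transition. With a single flank (dense
#' position outside the framework span) the single-interval transition is
#' used. Meioses interpolate independently.
#'
#' @param b_left,b_right flanking bits (0/1); pass `NA` for an absent flank.
#' @param theta_left,theta_right recombination fractions to the flanks.
#' @return `P(bit = 0)` at the dense position.
#' @examples
#' interp_iv_bit(0, 1, 0.1, 0.2)  # 0.9*0.2 / (0.9*0.2 + 0.1*0.8)
#' @export
interp_iv_bit <- function(b_left, b_right, theta_left, theta_right) {
  step <- function(b, x, th) ifelse(b == x, 1 - th, th)
  if (is.na(b_left)) return(step(b_right, 0, theta_right))
  if (is.na(b_right)) return(step(b_left, 0, theta_left))
  n0 <- step(b_left, 0, theta_left) * step(b_right, 0, theta_right)
  n1 <- step(b_left, 1, theta_left) * step(b_right, 1, theta_right)
  if (n0 + n1 <= 0) return(0.5)
  n0 / (n0 + n1)
}

#' Genotype-calling thresholds
#'
#' Hard probability thresholds for the "threshold" calling method. The
#' strict preset calls a full genotype when its posterior reaches 0.98 and
#' a single allele when one slot's allele posterior reaches 0.99; the
#' relaxed preset uses 0.95 / 0.98. Lowering either value can only add
#' calls, never remove them.
#'
#' @param t_both posterior required to call both alleles.
#' @param t_single posterior required to call one allele.
#' @param preset `"strict"` or `"relaxed"`; ignored when explicit values
#'   are given.
#' @return An object of class `"call_thresholds"`.
#' @export
call_thresholds <- function(t_both = NULL, t_single = NULL,
                            preset = c("strict", "relaxed")) {
  preset <- match.arg(preset)
  if (is.null(t_both)) t_both <- if (preset == "strict") 0.98 else 0.95
  if (is.null(t_single)) t_single <- if (preset == "strict") 0.99 else 0.98
  stopifnot(t_both > 0.5, t_both <= 1, t_single > 0.5, t_single <= 1)
  structure(list(t_both = t_both, t_single = t_single),
            class = "call_thresholds")
}

#' Most-likely genotype call
#'
#' Argmax of the genotype posterior; always calls two alleles. Ties break
#' toward the genotype containing the population-major allele, then in the
#' order RR < RA < AA.
#'
#' @param gp numeric vector `c(P(RR), P(RA), P(AA))` or a 3-column matrix.
#' @param p alt-allele frequency (for the major-allele tie-break).
#' @return Integer alt dosage(s) 0/1/2.
#' @export
call_most_likely <- function(gp, p = 0.5) {
  gp <- if (is.matrix(gp)) gp else matrix(gp, ncol = 3)
  # stable tie-break: add an infinitesimal preference for genotypes
  # carrying more copies of the major allele, then for lower dosage
  major_alt <- p > 0.5
  pref <- if (major_alt) c(0, 1, 2) else c(2, 1, 0)
  eps1 <- 1e-12 * pref
  eps2 <- 1e-15 * c(2, 1, 0)
  adj <- sweep(gp, 2, eps1 + eps2, "+")
  as.integer(max.col(adj, ties.method = "first") - 1L)
}

#' Threshold genotype call
#'
#' Calls both alleles when the maximum genotype posterior reaches
#' `t_both`; otherwise calls a single allele when exactly one of the two
#' alleles is confidently present in the genotype; otherwise makes no call.
#'
#' Two single-allele rules are provided. The default (`"genotype"`) calls
#' allele `a` when the posterior probability that the genotype contains at
#' least one copy of `a` reaches `t_single` — the phase-invariant reading
#' of calling "one of two possible alleles", and the event against which
#' half-call accuracy is later scored. The `"slot"` rule instead requires
#' one haplotype slot's allele posterior to reach `t_single`; it is more
#' conservative and, because a founder's two slots are posterior-symmetric
#' (founder phase is unobservable), it can never half-call a founder even
#' when the allele content is certain.
#'
#' @param gp genotype posterior `c(P(RR), P(RA), P(AA))`.
#' @param ap slot allele posteriors `c(P(alt) slot1, P(alt) slot2)` (used
#'   by the `"slot"` rule).
#' @param t a [call_thresholds()].
#' @param p alt frequency for the most-likely tie-break within full calls.
#' @param rule single-allele rule, `"genotype"` (default) or `"slot"`.
#' @return List: `n_alleles` (0/1/2), `dose` (0/1/2 for a full call),
#'   `allele` (0/1 for a single-allele call).
#' @export
call_threshold <- function(gp, ap = NULL, t = call_thresholds(), p = 0.5,
                           rule = c("genotype", "slot")) {
  rule <- match.arg(rule)
  if (max(gp) >= t$t_both) {
    return(list(n_alleles = 2L, dose = call_most_likely(gp, p), allele = NA))
  }
  if (rule == "genotype") {
    conf <- c(gp[1] + gp[2], gp[3] + gp[2])  # P(has ref), P(has alt)
    pass <- conf >= t$t_single
    if (sum(pass) == 1L) {
      return(list(n_alleles = 1L, dose = NA,
                  allele = as.integer(which(pass) == 2L)))
    }
  } else {
    if (is.null(ap)) stop("slot rule needs slot allele posteriors")
    conf <- pmax(ap, 1 - ap)
    pass <- conf >= t$t_single
    if (sum(pass) == 1L) {
      s <- which(pass)
      return(list(n_alleles = 1L, dose = NA,
                  allele = as.integer(ap[s] >= 0.5)))
    }
  }
  list(n_alleles = 0L, dose = NA, allele = NA)
}

#' Dense-site genotype posteriors given inheritance vectors
#'
#' For each retained framework IV realization, dense-position bits are drawn
#' per meiosis from [interp_iv_bit()] (`k_dense` draws per realization); for
#' each draw the descent partition is built, founder-gene alleles are
#' conditioned on the observed dense genotypes (assignments inconsistent
#' with the observations are excluded; genes carried by no observed
#' individual follow Bernoulli(`p`)), and genotype/slot-allele posteriors
#' are averaged over all consistent realizations. Realizations under which
#' the observations are Mendelian-impossible are dropped and counted; a
#' site with no consistent realization is flagged (`NA` posteriors).
#'
#' `exhaustive = TRUE` replaces the dense-bit sampling by exact enumeration
#' of all `2^m` dense inheritance vectors weighted by their interpolation
#' probability — feasible only for small pedigrees, used by the
#' verification suite.
#'
#' @param ivs an `"iv_samples"` object on the framework panel.
#' @param ped the [pedigree()].
#' @param dense_obs named integer vector of observed alt dosages at the
#'   dense site (the WGS-designated individuals).
#' @param p alt frequency at the dense site, in (0,1).
#' @param pos_cm genetic position of the dense site.
#' @param k_dense dense-bit draws per framework realization (default 1).
#' @param seed integer seed.
#' @param exhaustive exact dense-IV enumeration (small pedigrees only).
#' @return List with `genotype` (individuals x 3 matrix: P(RR), P(RA),
#'   P(AA)), `slot_alt` (individuals x 2: per-slot P(alt)),
#'   `n_inconsistent`.
#' @export
dense_posterior <- function(ivs, ped, dense_obs, p, pos_cm, k_dense = 1,
                            seed = 1, exhaustive = FALSE) {
  obs <- rep(-1L, length(ped$id))
  names(obs) <- ped$id
  dense_obs <- dense_obs[!is.na(dense_obs)]
  if (length(dense_obs)) obs[names(dense_obs)] <- as.integer(dense_obs)
  if (exhaustive) {
    out <- .dense_posterior_exhaustive(ivs, ped, obs, p, pos_cm)
    rownames(out$genotype) <- rownames(out$slot_alt) <- ped$id
    colnames(out$genotype) <- c("RR", "RA", "AA")
    return(out)
  }
  pc <- .ped_c(ped)
  set.seed(seed)
  res <- cpp_dense_posterior(pc$sire, pc$dam, pc$frank, pc$patm, pc$matm,
                             ivs$samples, ivs$cm, pos_cm,
                             matrix(obs, ncol = 1), p, ped$n_meioses,
                             k_dense)
  gp <- cbind(RR = res$p_rr[, 1], RA = res$p_ra[, 1], AA = res$p_aa[, 1])
  ap <- cbind(res$slot1_alt[, 1], res$slot2_alt[, 1])
  rownames(gp) <- rownames(ap) <- ped$id
  list(genotype = gp, slot_alt = ap,
       n_inconsistent = res$n_inconsistent[1])
}

# Exact enumeration over dense IVs; framework IVs weighted by their
# per-locus posterior at the flanking markers when available (exact
# samples), else by the empirical sample frequencies.
.dense_posterior_exhaustive <- function(ivs, ped, obs, p, pos_cm) {
  m <- ped$n_meioses
  if (m > 12) stop("exhaustive mode supports at most 12 meioses")
  n <- length(ped$id)
  tl <- max(which(ivs$cm <= pos_cm), 0L)
  tr <- if (any(ivs$cm > pos_cm)) min(which(ivs$cm > pos_cm)) else 0L
  thl <- if (tl > 0) haldane(pos_cm - ivs$cm[tl]) else NA
  thr <- if (tr > 0) haldane(ivs$cm[tr] - pos_cm) else NA
  # flank-state distribution: exact per-locus marginals when only one flank
  # is in play and the sampler stored them, else empirical joint frequencies
  single <- xor(tl > 0, tr > 0)
  if (single && !is.null(ivs$marginals)) {
    tf <- max(tl, tr)
    wts <- ivs$marginals[tf, ]
    keys <- paste(if (tl > 0) seq_along(wts) - 1L else 0L,
                  if (tr > 0) seq_along(wts) - 1L else 0L)
    wtab <- stats::setNames(as.list(wts[wts > 0]), keys[wts > 0])
  } else {
    key <- paste(if (tl > 0) ivs$samples[, tl] else 0L,
                 if (tr > 0) ivs$samples[, tr] else 0L)
    wtab <- as.list(table(key) / nrow(ivs$samples))
  }
  acc_g <- matrix(0, n, 3)
  acc_a <- matrix(0, n, 2)
  tot_w <- 0
  for (kk in names(wtab)) {
    fl <- as.integer(strsplit(kk, " ")[[1]])
    w_flank <- as.numeric(wtab[[kk]])
    for (s in 0:(2^m - 1)) {
      bits <- bitwAnd(bitwShiftR(s, 0:(m - 1)), 1L)
      pr <- 1
      for (j in seq_len(m)) {
        p0 <- interp_iv_bit(if (tl > 0) bitwAnd(bitwShiftR(fl[1], j - 1L),
                                                1L) else NA,
                            if (tr > 0) bitwAnd(bitwShiftR(fl[2], j - 1L),
                                                1L) else NA,
                            thl, thr)
        pr <- pr * if (bits[j] == 0) p0 else 1 - p0
      }
      if (pr == 0) next
      ps <- .partition_posterior(ped, bits, obs, p)
      if (is.null(ps)) next  # inconsistent under this dense IV
      acc_g <- acc_g + w_flank * pr * ps$genotype
      acc_a <- acc_a + w_flank * pr * ps$slot_alt
      tot_w <- tot_w + w_flank * pr
    }
  }
  if (tot_w == 0) {
    return(list(genotype = matrix(NA_real_, n, 3),
                slot_alt = matrix(NA_real_, n, 2), n_inconsistent = NA))
  }
  list(genotype = acc_g / tot_w, slot_alt = acc_a / tot_w,
       n_inconsistent = 0L)
}

# Per-individual genotype posterior given a fixed descent partition,
# conditioning founder-gene alleles on the observed genotypes by direct
# enumeration (reference implementation; small gene counts only).
.partition_posterior <- function(ped, iv, obs, p) {
  part <- build_descent(ped, iv)
  n <- nrow(part)
  genes <- sort(unique(as.vector(part[obs >= 0, , drop = FALSE])))
  k <- length(genes)
  ng <- max(part)
  n_assign <- 2^k
  weights <- numeric(n_assign)
  assigns <- matrix(0L, n_assign, ng)
  wsum <- 0
  for (a in seq_len(n_assign) - 1L) {
    al <- rep(NA_integer_, ng)
    if (k > 0) al[genes] <- bitwAnd(bitwShiftR(a, seq_len(k) - 1L), 1L)
    ok <- TRUE
    for (i in which(obs >= 0)) {
      if (al[part[i, 1]] + al[part[i, 2]] != obs[i]) { ok <- FALSE; break }
    }
    if (!ok) next
    w <- prod(ifelse(al[genes] == 1, p, 1 - p))
    weights[a + 1L] <- w
    assigns[a + 1L, ] <- ifelse(is.na(al), -1L, al)
    wsum <- wsum + w
  }
  if (wsum == 0) return(NULL)
  gmat <- matrix(0, n, 3)
  amat <- matrix(0, n, 2)
  for (a in which(weights > 0)) {
    w <- weights[a] / wsum
    al <- assigns[a, ]
    for (i in seq_len(n)) {
      pa <- if (al[part[i, 1]] >= 0) al[part[i, 1]] else p
      pb <- if (al[part[i, 2]] >= 0) al[part[i, 2]] else p
      if (part[i, 1] == part[i, 2]) {
        gmat[i, ] <- gmat[i, ] + w * c(1 - pa, 0, pa)
        amat[i, ] <- amat[i, ] + w * c(pa, pa)
      } else {
        gmat[i, ] <- gmat[i, ] +
          w * c((1 - pa) * (1 - pb), pa * (1 - pb) + (1 - pa) * pb, pa * pb)
        amat[i, ] <- amat[i, ] + w * c(pa, pb)
      }
    }
  }
  list(genotype = gmat, slot_alt = amat)
}

#' Impute dense genotypes across a chromosome
#'
#' The full imputation step: for every dense marker, compute posterior
#' genotype and per-slot allele probabilities for all pedigree members from
#' the framework inheritance-vector realizations and the observed dense
#' genotypes of the WGS-designated individuals, then call genotypes by both
#' the "most likely" method (always two alleles) and the "threshold" method
#' (full call, half call, or no call).
#'
#' @param ped a [pedigree()].
#' @param ivs an `"iv_samples"` object on the framework panel.
#' @param dense_markers data frame of dense markers (`chrom`, `pos`, `ref`,
#'   `alt`, `alt_freq`), same chromosome as the framework panel.
#' @param dense_obs integer matrix (pedigree ids x dense markers) of
#'   observed alt dosages, `NA` where unobserved; typically only the donor
#'   rows are non-missing.
#' @param map a [genetic_map()].
#' @param thresholds a [call_thresholds()].
#' @param k_dense dense-bit draws per framework realization.
#' @param seed integer seed.
#' @param rule single-allele calling rule, see [call_threshold()].
#' @return An object of class `"imputation"`: posteriors (`p_rr`, `p_ra`,
#'   `p_aa`, `slot1_alt`, `slot2_alt`), calls (`ml_dose`,
#'   `thr_n_alleles`, `thr_dose`, `thr_allele`), `n_inconsistent` per site,
#'   plus the marker table, ids, donor ids and thresholds.
#' @export
impute_chromosome <- function(ped, ivs, dense_markers, dense_obs, map,
                              thresholds = call_thresholds(), k_dense = 1,
                              seed = 1, rule = c("genotype", "slot")) {
  rule <- match.arg(rule)
  stopifnot(nrow(dense_obs) == length(ped$id))
  D <- nrow(dense_markers)
  pc <- .ped_c(ped)
  dense_cm <- bp_to_cm(map, dense_markers$chrom[1], dense_markers$pos)
  obs <- ifelse(is.na(dense_obs), -1L, dense_obs)
  storage.mode(obs) <- "integer"
  set.seed(seed)
  res <- cpp_dense_posterior(pc$sire, pc$dam, pc$frank, pc$patm, pc$matm,
                             ivs$samples, ivs$cm, dense_cm, obs,
                             dense_markers$alt_freq, ped$n_meioses, k_dense)
  n <- length(ped$id)
  p <- dense_markers$alt_freq
  # individuals with an observed dense genotype are returned unchanged:
  # their posterior is a point mass at the observation (self-imputation
  # identity), independent of the sampled realizations
  seen <- which(obs >= 0L)
  if (length(seen)) {
    res$p_rr[seen] <- as.numeric(obs[seen] == 0L)
    res$p_ra[seen] <- as.numeric(obs[seen] == 1L)
    res$p_aa[seen] <- as.numeric(obs[seen] == 2L)
    res$slot1_alt[seen] <- obs[seen] / 2
    res$slot2_alt[seen] <- obs[seen] / 2
  }
  ml <- matrix(NA_integer_, n, D)
  thr_n <- matrix(0L, n, D)
  thr_dose <- matrix(NA_integer_, n, D)
  thr_allele <- matrix(NA_integer_, n, D)
  for (d in seq_len(D)) {
    gp <- cbind(res$p_rr[, d], res$p_ra[, d], res$p_aa[, d])
    valid <- !is.na(gp[, 1])  # NA rows: flagged site, no call
    if (!any(valid)) next
    gp[!valid, ] <- 1 / 3  # placeholder, masked out below
    ml[valid, d] <- call_most_likely(gp, p[d])[valid]
    gmax <- gp[cbind(seq_len(n), max.col(gp, ties.method = "first"))]
    full <- valid & gmax >= thresholds$t_both
    thr_n[full, d] <- 2L
    thr_dose[full, d] <- ml[full, d]
    if (rule == "genotype") {
      conf <- cbind(gp[, 1] + gp[, 2], gp[, 3] + gp[, 2])
      pass <- conf >= thresholds$t_single
      single <- valid & !full & (rowSums(pass) == 1L)
      if (any(single)) {
        thr_n[single, d] <- 1L
        thr_allele[single, d] <-
          as.integer(pass[single, 2])
      }
    } else {
      ap <- cbind(res$slot1_alt[, d], res$slot2_alt[, d])
      conf <- pmax(ap, 1 - ap)
      pass <- conf >= thresholds$t_single
      single <- valid & !full & (rowSums(pass) == 1L)
      if (any(single)) {
        sl <- max.col(pass, ties.method = "first")[single]
        thr_n[single, d] <- 1L
        thr_allele[single, d] <-
          as.integer(ap[cbind(which(single), sl)] >= 0.5)
      }
    }
  }
  donors <- ped$id[rowSums(!is.na(dense_obs)) > 0]
  structure(list(ids = ped$id, markers = dense_markers, donors = donors,
                 p_rr = res$p_rr, p_ra = res$p_ra, p_aa = res$p_aa,
                 slot1_alt = res$slot1_alt, slot2_alt = res$slot2_alt,
                 ml_dose = ml, thr_n_alleles = thr_n, thr_dose = thr_dose,
                 thr_allele = thr_allele,
                 n_inconsistent = res$n_inconsistent,
                 n_realizations = res$n_realizations,
                 thresholds = thresholds),
            class = "imputation")
}

#' @export
print.imputation <- function(x, ...) {
  cat("imputation: ", length(x$ids), " individuals x ", nrow(x$markers),
      " dense markers; donors: ", paste(x$donors, collapse = ", "), "\n",
      "threshold method: ", round(100 * mean(x$thr_n_alleles == 2L), 1),
      "% full calls, ", round(100 * mean(x$thr_n_alleles == 1L), 1),
      "% half calls\n", sep = "")
  invisible(x)
}

#' @export
summary.imputation <- function(object, ...) {
  rec <- setdiff(object$ids, object$donors)
  ri <- match(rec, object$ids)
  fi <- rowMeans(object$thr_n_alleles[ri, , drop = FALSE] > 0L)
  out <- data.frame(id = rec, marker_fraction_imputed = fi)
  class(out) <- c("summary.imputation", "data.frame")
  out
}

#' Write imputed calls to VCF
#'
#' Threshold-method calls as GT (half calls written as `x/.`), with
#' genotype posteriors (PRR/PRA/PAA) and per-slot alt posteriors (PS1/PS2)
#' as additional FORMAT fields.
#'
#' @param imp an `"imputation"` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_imputed_vcf <- function(imp, path) {
  D <- nrow(imp$markers)
  fmt <- function(i) {
    gt <- rep("./.", D)
    full <- imp$thr_n_alleles[i, ] == 2L
    gt[full] <- c("0/0", "0/1", "1/1")[imp$thr_dose[i, full] + 1L]
    half <- imp$thr_n_alleles[i, ] == 1L
    gt[half] <- paste0(imp$thr_allele[i, half], "/.")
    paste(gt,
          sprintf("%.4g", imp$p_rr[i, ]), sprintf("%.4g", imp$p_ra[i, ]),
          sprintf("%.4g", imp$p_aa[i, ]),
          sprintf("%.4g", imp$slot1_alt[i, ]),
          sprintf("%.4g", imp$slot2_alt[i, ]), sep = ":")
  }
  gt <- cbind(FORMAT = rep("GT:PRR:PRA:PAA:PS1:PS2", D),
              vapply(seq_along(imp$ids), fmt, character(D)))
  colnames(gt) <- c("FORMAT", imp$ids)
  fix <- cbind(CHROM = imp$markers$chrom,
               POS = format(imp$markers$pos, scientific = FALSE,
                            trim = TRUE),
               ID = rep(".", D), REF = imp$markers$ref,
               ALT = imp$markers$alt, QUAL = rep(".", D),
               FILTER = rep("PASS", D), INFO = rep(".", D))
  meta <- c("##fileformat=VCFv4.2",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Imputed genotype (half calls allowed)\">",
            "##FORMAT=<ID=PRR,Number=1,Type=Float,Description=\"P(hom ref)\">",
            "##FORMAT=<ID=PRA,Number=1,Type=Float,Description=\"P(het)\">",
            "##FORMAT=<ID=PAA,Number=1,Type=Float,Description=\"P(hom alt)\">",
            "##FORMAT=<ID=PS1,Number=1,Type=Float,Description=\"P(alt) paternal slot\">",
            "##FORMAT=<ID=PS2,Number=1,Type=Float,Description=\"P(alt) maternal slot\">")
  v <- methods::new(methods::getClass("vcfR", where = asNamespace("vcfR")), meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}
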