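#' Descent partition implied by an inheritance vector
#'
#' Given one inheritance vector (one bit per meiosis; 0 = the parent
#' transmitted its own paternal slot, 1 its maternal slot), every allele
#' slot in the pedigree maps to exactly one founder gene. Founders carry
#' their own two genes; each non-founder slot recursively copies the
#' parental slot selected by its meiosis bit.
#'
#' @param ped a [pedigree()].
#' @param iv integer vector of 0/1 bits, length `n_meioses(ped)`.
#' @return Integer matrix (individuals x 2 slots) of founder-gene ids in
#'   `1..2F`, with gene labels (`"<founder>:1"`, `"<founder>:2"`) as the
#'   `"gene_labels"` attribute and row names the individual ids.
#' @export
build_descent <- function(ped, iv) {
  if (length(iv) != ped$n_meioses) {
    stop("inheritance vector length ", length(iv),
         " does not match meiosis count ", ped$n_meioses)
  }
  pc <- .ped_c(ped)
  lab <- cpp_build_descent(pc$sire, pc$dam, pc$frank, pc$patm, pc$matm,
                           as.integer(iv)) + 1L
  out <- matrix(lab, ncol = 2, byrow = TRUE,
                dimnames = list(ped$id, c("paternal", "maternal")))
  attr(out, "gene_labels") <- .gene_labels(ped)
  out
}

#' Single-locus pedigree likelihood given a descent partition
#'
#' Probability of the observed unphased genotypes at one biallelic marker,
#' summing over all assignments of founder-gene alleles: each assignment
#' contributes the product of its allele frequencies if it reproduces every
#' observed genotype, and founder genes not carried by any observed
#' individual integrate out to a factor of 1. Internally the sum is
#' evaluated in closed form: homozygotes force their genes, heterozygotes
#' impose an unequal-allele constraint between their two genes, and the
#' likelihood factorizes over the resulting gene components.
#'
#' @param part descent matrix from [build_descent()], or a [pedigree()] (in
#'   which case `iv` must be given).
#' @param obs named integer vector of observed alt dosages (0/1/2; omit or
#'   `NA` for unobserved individuals), names being pedigree ids.
#' @param p alt-allele frequency at the marker, in (0,1).
#' @param iv inheritance vector, used when `part` is a pedigree.
#' @return Likelihood in `[0, 1]`.
#' @export
locus_likelihood <- function(part, obs, p, iv = NULL) {
  if (inherits(part, "pedigree")) part <- build_descent(part, iv)
  ids <- rownames(part)
  o <- rep(NA_integer_, length(ids))
  names(o) <- ids
  obs <- obs[!is.na(obs)]
  if (length(obs)) {
    if (is.null(names(obs))) stop("obs must be named by individual id")
    unknown <- setdiff(names(obs), ids)
    if (length(unknown)) stop("unknown id(s): ",
                              paste(unknown, collapse = ", "))
    o[names(obs)] <- as.integer(obs)
  }
  cpp_locus_likelihood(as.integer(t(part)) - 1L,
                       ifelse(is.na(o), -1L, o), p, max(part))
}

#' Inheritance-vector transition probability
#'
#' `theta^k * (1 - theta)^(m - k)` where `k` is the Hamming distance between
#' the two vectors: meioses recombine independently.
#'
#' @param iv_a,iv_b 0/1 bit vectors of equal length.
#' @param theta recombination fraction in `[0, 0.5]`.
#' @return Transition probability.
#' @export
transition_prob <- function(iv_a, iv_b, theta) {
  if (length(iv_a) != length(iv_b)) stop("inheritance vector length mismatch")
  k <- sum(iv_a != iv_b)
  theta^k * (1 - theta)^(length(iv_a) - k)
}

# shared preparation of HMM inputs from a framework genotype matrix
.iv_inputs <- function(ped, framework, map) {
  stopifnot(inherits(framework, "genotype_matrix"))
  if (nrow(framework$markers) < 1L) stop("need at least one framework marker")
  if (length(unique(framework$markers$chrom)) != 1L) {
    stop("one chromosome at a time; subset the framework matrix")
  }
  missing_ids <- setdiff(framework$ids, ped$id)
  if (length(missing_ids)) {
    stop("framework individuals absent from pedigree: ",
         paste(missing_ids, collapse = ", "))
  }
  cm <- bp_to_cm(map, framework$markers$chrom[1], framework$markers$pos)
  p <- framework$markers$alt_freq
  if (anyNA(p)) stop("framework markers need alt_freq")
  obs <- matrix(-1L, length(ped$id), nrow(framework$markers))
  ri <- match(framework$ids, ped$id)
  obs[ri, ] <- ifelse(is.na(framework$geno), -1L, framework$geno)
  list(obs = obs, cm = cm, theta = haldane(diff(cm)), p = p)
}

.new_ivset <- function(samples, ped, markers, cm, method, seed, pars,
                       marginals = NULL) {
  structure(list(samples = samples, m = ped$n_meioses,
                 n_markers = ncol(samples), markers = markers, cm = cm,
                 method = method, seed = seed, pars = pars,
                 marginals = marginals),
            class = "iv_samples")
}

#' @export
print.iv_samples <- function(x, ...) {
  cat("iv_samples: ", nrow(x$samples), " ", x$method,
      " realizations over ", x$n_markers, " markers (",
      x$m, " meioses)\n", sep = "")
  invisible(x)
}

#' Unpack an inheritance-vector realization
#'
#' @param ivs an `"iv_samples"` object.
#' @param sample realization index.
#' @return Integer bit matrix (meioses x markers).
#' @export
iv_bits <- function(ivs, sample = 1) {
  v <- ivs$samples[sample, ]
  out <- matrix(0L, ivs$m, length(v))
  for (j in seq_len(ivs$m)) {
    out[j, ] <- bitwAnd(bitwShiftR(v, j - 1L), 1L)
  }
  out
}

#' Exact inheritance-vector posterior at framework markers
#'
#' Runs forward-backward over the full `2^m` inheritance-vector state space
#' with single-locus pedigree likelihoods as emissions and per-meiosis
#' independent Haldane transitions, then draws i.i.d. joint realizations by
#' backward sampling. Exact work is limited to pedigrees with
#' `m <= m_max` meioses; larger pedigrees use [sample_iv_mcmc()].
#'
#' @param ped a [pedigree()].
#' @param framework a [genotype_matrix()] of framework genotypes (one
#'   chromosome), treated as error-free; Mendelian-inconsistent data is an
#'   error (pre-screen with [mendelian_errors()]).
#' @param map a [genetic_map()].
#' @param n_samples number of joint realizations to draw.
#' @param seed integer seed.
#' @param m_max guard on the exact state-space size (default 16).
#' @param marginals also return per-locus marginal distributions (memory
#'   `n_markers x 2^m`; keep for small pedigrees).
#' @return An `"iv_samples"` object; if requested, `$marginals` is the
#'   markers x `2^m` matrix of per-locus IV posteriors.
#' @export
exact_iv_posterior <- function(ped, framework, map, n_samples = 1000,
                               seed = 1, m_max = 16, marginals = TRUE) {
  m <- ped$n_meioses
  if (m > m_max) {
    stop("pedigree has ", m, " meioses; exact mode is limited to m_max = ",
         m_max, " (use sample_iv_mcmc)")
  }
  inp <- .iv_inputs(ped, framework, map)
  pc <- .ped_c(ped)
  set.seed(seed)
  res <- cpp_exact_fb(pc$sire, pc$dam, pc$frank, pc$patm, pc$matm,
                      inp$obs, inp$theta, inp$p, m, n_samples, marginals)
  .new_ivset(res$samples, ped, framework$markers, inp$cm, "exact", seed,
             list(n_samples = n_samples),
             marginals = if (marginals) res$marginals else NULL)
}

#' MCMC sampling of inheritance vectors
#'
#' Meiosis-wise Gibbs sampler for pedigrees too large for exact
#' forward-backward: each update resamples one meiosis' entire bit sequence
#' along the chromosome from its conditional two-state HMM, holding all
#' other meioses fixed; one sweep updates every meiosis in random order.
#' The chain is initialized marker-by-marker with a conditional gene drop
#' (founder alleles drawn consistent with the founder's observed genotype,
#' meiosis bits drawn from the combinations consistent with the offspring's
#' genotype), so a Mendelian-consistent state is found without global
#' rejection.
#'
#' @inheritParams exact_iv_posterior
#' @param burn_in discarded initial sweeps (default 1000).
#' @param thin keep one sample per `thin` sweeps (default 5).
#' @param max_restarts bound on per-marker initialization attempts; failure
#'   signals Mendelian-impossible data.
#' @return An `"iv_samples"` object.
#' @export
sample_iv_mcmc <- function(ped, framework, map, n_samples = 1000,
                           burn_in = 1000, thin = 5, seed = 1,
                           max_restarts = 10000) {
  m <- ped$n_meioses
  if (m > 30L) stop("packed inheritance vectors support at most 30 meioses")
  inp <- .iv_inputs(ped, framework, map)
  pc <- .ped_c(ped)
  set.seed(seed)
  res <- cpp_mcmc(pc$sire, pc$dam, pc$frank, pc$patm, pc$matm,
                  inp$obs, inp$theta, inp$p, m, n_samples, burn_in, thin,
                  max_restarts)
  .new_ivset(res$samples, ped, framework$markers, inp$cm, "mcmc", seed,
             list(n_samples = n_samples, burn_in = burn_in, thin = thin,
                  init_attempts = res$init_attempts))
}

#' Serialize inheritance-vector samples as TSV
#'
#' One row per (realization, marker) with the bit string (meiosis 1 first).
#'
#' @param ivs an `"iv_samples"` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_iv_tsv <- function(ivs, path) {
  rows <- lapply(seq_len(nrow(ivs$samples)), function(s) {
    bits <- iv_bits(ivs, s)
    data.frame(sample = s, marker = seq_len(ivs$n_markers),
               bits = apply(bits, 2, paste, collapse = ""))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
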