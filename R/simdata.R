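#' Sixteen-member breeding-colony pedigree template
#'
#' A fixed two-generation, 16-member pedigree (ids `A`..`P`) emulating the
#' study cohort: a few heavily-used sires with offspring by several dams,
#' containing parent/offspring, half-sibling, half-avuncular, half-cousin
#' and grandparent/grandchild pairs — the most common relationships in
#' macaque breeding colonies. The exact topology of the real cohort is not
#' published; this template is one consistent instantiation of its
#' documented constraints:
#'
#' * `A`, `B`, `C`, `D`, `E` are founders (as are the dams `G`, `I`, `L`,
#'   so that the prolific sires `B` and `D` have offspring by several
#'   unrelated dams);
#' * `K` is a child of `D`;
#' * `E`'s only descendant is the childless `N`, so `E` shares no genetic
#'   material with any of the nine sequencing candidates;
#' * `M`, `P` and `K` are the childless bottom generation;
#' * ranked by descendant count, the three most prolific founders are `B`,
#'   `C`, `D`.
#'
#' The nine whole-genome sequencing candidates used throughout the worked
#' examples are `B, C, D, F, H, J, K, M, P` (see [wgs_candidates()]).
#'
#' @return A [pedigree()] with 16 members, 8 founders and 16 meioses.
#' @export
colony_pedigree <- function() {
  df <- data.frame(
    id   = c("A", "B", "C", "D", "E", "G", "I", "L",
             "F", "H", "J", "N", "O",
             "K", "M", "P"),
    sire = c(NA, NA, NA, NA, NA, NA, NA, NA,
             "B", "B", "B", "E", "D",
             "D", "O", "H"),
    dam  = c(NA, NA, NA, NA, NA, NA, NA, NA,
             "A", "G", "I", "C", "C",
             "J", "J", "L"),
    sex  = c("female", "male", "female", "male", "male", "female",
             "female", "female",
             "male", "male", "female", "male", "male",
             "female", "male", "female"),
    stringsAsFactors = FALSE
  )
  pedigree(df$id, df$sire, df$dam, df$sex)
}

#' Whole-genome sequencing candidates of the colony template
#'
#' The nine members of [colony_pedigree()] holding dense (WGS) data in the
#' worked examples; the remaining seven carry sparse GBS data only.
#'
#' @return Character vector of nine ids.
#' @export
wgs_candidates <- function() c("B", "C", "D", "F", "H", "J", "K", "M", "P")

#' Read-depth observation model
#'
#' Per-cell sequencing model: read depth is Poisson(`mean_depth`); each read
#' reports the alternate allele with probability `error_rate`, `0.5`, or
#' `1 - error_rate` for 0/1/2 true alt copies. Genotypes are called by
#' maximum binomial likelihood under a flat prior, GQ is the phred of
#' `1 - posterior` of the call, and calls failing `depth >= min_dp` or
#' `gq >= min_gq` are set missing — the standard hard genotype-level filter
#' (DP >= 10, GQ >= 20).
#'
#' @param mean_depth expected read depth (lambda, reads).
#' @param error_rate per-read miscall probability in `[0, 0.5)`.
#' @param min_dp,min_gq genotype-level filters.
#' @return An object of class `"coverage_model"`.
#' @export
coverage_model <- function(mean_depth = 30, error_rate = 0.01,
                           min_dp = 10, min_gq = 20) {
  stopifnot(mean_depth >= 0, error_rate >= 0, error_rate < 0.5)
  structure(list(mean_depth = mean_depth, error_rate = error_rate,
                 min_dp = min_dp, min_gq = min_gq),
            class = "coverage_model")
}

#' Gene-drop phased haplotypes through a pedigree
#'
#' Simulates founder haplotypes and Mendelian transmission with map-based
#' recombination, recording the full latent truth: phased alleles, founder
#' gene labels for both slots of every individual, and the true inheritance
#' vector at every marker. Founder slot alleles are independent Bernoulli
#' draws with the marker's alt frequency (linkage equilibrium among
#' founders, the same assumption the imputation model makes). Each meiosis
#' is a Markov chain along the chromosome whose indicator flips between
#' adjacent markers with probability `haldane(distance)` (no interference).
#'
#' @param ped a [pedigree()].
#' @param markers data frame with `chrom`, `pos`, `ref`, `alt`, `alt_freq`
#'   (sorted by chrom, pos; a single chromosome per call).
#' @param map a [genetic_map()].
#' @param seed integer seed.
#' @return An object of class `"truth_panel"`: list with `ped`, `markers`,
#'   allele matrices `pat_allele`/`mat_allele` (individuals x markers,
#'   0 = ref, 1 = alt), founder-gene label matrices `pat_label`/`mat_label`
#'   (integer gene ids 1..2F), and `iv` (meioses x markers bit matrix).
#' @export
simulate_truth <- function(ped, markers, map, seed = 1) {
  stopifnot(length(unique(markers$chrom)) == 1L)
  set.seed(seed)
  n <- length(ped$id)
  M <- nrow(markers)
  m <- ped$n_meioses
  cm <- bp_to_cm(map, markers$chrom[1], markers$pos)
  theta <- haldane(diff(cm))
  p <- markers$alt_freq
  if (anyNA(p)) stop("alt_freq must be set for all markers")

  # inheritance vectors: per meiosis, a flip-chain along the chromosome
  iv <- matrix(0L, m, M)
  if (m > 0) {
    start <- stats::rbinom(m, 1, 0.5)
    if (M > 1) {
      flips <- matrix(stats::rbinom(m * (M - 1), 1, rep(theta, each = m)),
                      m, M - 1)
      if (M > 2) {
        for (t in 2:(M - 1)) flips[, t] <- flips[, t - 1] + flips[, t]
      }
      iv <- (start + cbind(0L, flips)) %% 2L
    } else {
      iv <- matrix(start, m, 1)
    }
    storage.mode(iv) <- "integer"
  }

  pat_a <- mat_a <- matrix(0L, n, M, dimnames = list(ped$id, NULL))
  pat_l <- mat_l <- matrix(0L, n, M, dimnames = list(ped$id, NULL))
  for (i in seq_len(n)) {
    if (ped$founder[i]) {
      fr <- ped$founder_rank[i]
      pat_l[i, ] <- 2L * fr - 1L
      mat_l[i, ] <- 2L * fr
      pat_a[i, ] <- stats::rbinom(M, 1, p)
      mat_a[i, ] <- stats::rbinom(M, 1, p)
    } else {
      bp <- iv[ped$pat_meiosis[i], ]
      bm <- iv[ped$mat_meiosis[i], ]
      s <- ped$sire[i]; d <- ped$dam[i]
      pat_a[i, ] <- ifelse(bp == 0L, pat_a[s, ], mat_a[s, ])
      pat_l[i, ] <- ifelse(bp == 0L, pat_l[s, ], mat_l[s, ])
      mat_a[i, ] <- ifelse(bm == 0L, pat_a[d, ], mat_a[d, ])
      mat_l[i, ] <- ifelse(bm == 0L, pat_l[d, ], mat_l[d, ])
    }
  }
  structure(list(ped = ped, markers = markers,
                 pat_allele = pat_a, mat_allele = mat_a,
                 pat_label = pat_l, mat_label = mat_l, iv = iv,
                 seed = seed),
            class = "truth_panel")
}

#' True unphased genotypes of a truth panel
#' @param truth a `"truth_panel"` from [simulate_truth()].
#' @return Integer matrix (individuals x markers) of alt dosages.
#' @export
truth_genotypes <- function(truth) truth$pat_allele + truth$mat_allele

#' Simulate sequencing observation of a truth panel
#'
#' Applies a [coverage_model()] cell-wise: Poisson depth, binomial alt-read
#' counts, flat-prior maximum-likelihood genotype calls with phred-scaled
#' GQ, and the DP/GQ hard filters.
#'
#' @param truth a `"truth_panel"`.
#' @param model a [coverage_model()].
#' @param seed integer seed.
#' @return A [genotype_matrix()] (filtered cells are `NA` but retain their
#'   DP/GQ).
#' @export
simulate_observation <- function(truth, model = coverage_model(), seed = 1) {
  set.seed(seed)
  g <- truth_genotypes(truth)
  n <- nrow(g); M <- ncol(g)
  eps <- model$error_rate
  depth <- matrix(stats::rpois(n * M, model$mean_depth), n, M)
  mu <- matrix(c(eps, 0.5, 1 - eps)[g + 1L], n, M)
  altr <- matrix(stats::rbinom(n * M, as.vector(depth), as.vector(mu)), n, M)
  l0 <- stats::dbinom(altr, depth, eps)
  l1 <- stats::dbinom(altr, depth, 0.5)
  l2 <- stats::dbinom(altr, depth, 1 - eps)
  tot <- l0 + l1 + l2
  post <- pmax(l0, l1, l2) / tot
  call <- max.col(cbind(as.vector(l0), as.vector(l1), as.vector(l2)),
                  ties.method = "first") - 1L
  call <- matrix(call, n, M)
  gq <- matrix(pmin(99L, as.integer(round(-10 * log10(pmax(1 - post,
                                                           1e-10))))), n, M)
  miss <- depth < model$min_dp | gq < model$min_gq
  call[miss] <- NA_integer_
  genotype_matrix(truth$ped$id, truth$markers, call, depth, gq)
}

#' GBS design: observed marker subset and per-site call rate
#'
#' @param marker_idx integer or logical index of markers retained by the
#'   assay (e.g. markers falling in sequenced restriction fragments).
#' @param call_rate per-cell retention probability in (0, 1]; the default
#'   0.69 emulates the per-site callability observed for a PstI GBS panel.
#' @return An object of class `"gbs_design"`.
#' @export
gbs_design <- function(marker_idx, call_rate = 0.69) {
  stopifnot(call_rate > 0, call_rate <= 1)
  structure(list(marker_idx = marker_idx, call_rate = call_rate),
            class = "gbs_design")
}

#' Apply a GBS design to a genotype matrix
#'
#' Markers outside the design's subset become missing for all individuals;
#' within the subset each cell is independently retained with the design's
#' call rate.
#'
#' @param g a [genotype_matrix()].
#' @param design a [gbs_design()].
#' @param seed integer seed.
#' @return A [genotype_matrix()] with added missingness.
#' @export
apply_gbs_design <- function(g, design, seed = 1) {
  set.seed(seed)
  M <- nrow(g$markers)
  keep <- rep(FALSE, M)
  keep[design$marker_idx] <- TRUE
  geno <- g$geno
  geno[, !keep] <- NA_integer_
  if (design$call_rate < 1) {
    drop <- matrix(stats::runif(length(geno)) > design$call_rate,
                   nrow(geno), ncol(geno))
    drop[, !keep] <- FALSE  # already masked
    geno[drop] <- NA_integer_
  }
  genotype_matrix(g$ids, g$markers, geno, g$depth, g$gq)
}

#' Synthesize a genome with planted cut sites and repeat blocks
#'
#' Builds a random background sequence that is rejection-sampled to be free
#' of spurious motif occurrences (on both strands for non-palindromic
#' motifs), plants exactly `n_sites` concrete motif instances at recorded
#' non-overlapping positions, and lowercases the requested repeat blocks.
#'
#' @param length total sequence length (bp).
#' @param enzyme a [restriction_enzyme()].
#' @param n_sites number of motif instances to plant.
#' @param repeat_blocks optional list of `c(start, end)` 0-based half-open
#'   intervals to soft-mask.
#' @param seed integer seed.
#' @param max_tries bound on rejection attempts.
#' @return List with `seq` (named character vector of length 1, case
#'   preserved), `site_starts` (0-based motif starts) and `cut_positions`
#'   (0-based, as [scan_sites()] reports them).
#' @export
synth_genome <- function(length, enzyme, n_sites, repeat_blocks = list(),
                         seed = 1, max_tries = 200) {
  set.seed(seed)
  mlen <- nchar(enzyme$motif)
  if (n_sites * mlen >= length) stop("n_sites * motif length must be < length")
  rc <- .revcomp_iupac(enzyme$motif)
  concrete <- function(motif) {
    # instantiate IUPAC codes with concrete bases
    sets <- list(A = "A", C = "C", G = "G", T = "T",
                 R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                 W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                 B = c("C", "G", "T"), D = c("A", "G", "T"),
                 H = c("A", "C", "T"), V = c("A", "C", "G"),
                 N = c("A", "C", "G", "T"))
    paste(vapply(strsplit(motif, "")[[1]],
                 function(ch) sample(sets[[ch]], 1), character(1)),
          collapse = "")
  }
  for (try in seq_len(max_tries)) {
    s <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
               collapse = "")
    # scrub spurious occurrences
    for (scrub in 1:50) {
      occ <- scan_sites(s, enzyme)
      if (!base::length(occ)) break
      # overwrite each occurrence window with fresh random bases
      starts <- unique(pmax(0L, occ - mlen))
      for (st in starts) {
        w <- min(2L * mlen, length - st)
        substr(s, st + 1L, st + w) <-
          paste(sample(c("A", "C", "G", "T"), w, replace = TRUE),
                collapse = "")
      }
    }
    if (base::length(scan_sites(s, enzyme))) next
    # plant non-overlapping motif instances
    gap <- (length - n_sites * mlen) %/% (n_sites + 1L)
    if (gap < 1L) stop("cannot place sites without overlap")
    slots <- sort(sample(seq(mlen, length - 2L * mlen, by = mlen),
                         n_sites))
    # enforce non-adjacency
    if (any(diff(slots) < mlen)) next
    for (st in slots) substr(s, st + 1L, st + mlen) <- concrete(enzyme$motif)
    found <- scan_sites(s, enzyme)
    if (base::length(found) != n_sites) next
    for (blk in repeat_blocks) {
      substr(s, blk[1] + 1L, blk[2]) <-
        tolower(substr(s, blk[1] + 1L, blk[2]))
    }
    out <- c(synth = s)
    return(list(seq = out, site_starts = slots,
                cut_positions = found))
  }
  stop("could not satisfy constraints in ", max_tries, " attempts")
}
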