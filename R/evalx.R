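#' Simulation scenario configuration
#'
#' Bundles the study conditions for an end-to-end imputation experiment on
#' one simulated chromosome. The defaults mirror the canonical test-case
#' dimensions: a 16-member colony pedigree, 833 framework markers spaced
#' ~65 kb apart with minor-allele frequency above 0.25, and 5,010 dense
#' markers spaced ~10 kb apart on a ~55 Mb chromosome with a 1 cM/Mb map.
#' Dense-site alt frequencies follow a Beta(1, 3) truncated to
#' [0.02, 0.98], a right-skewed spectrum resembling variants discovered in
#' a small sequencing panel.
#'
#' @param ped a [pedigree()] (default [colony_pedigree()]).
#' @param n_framework,n_dense marker counts.
#' @param chrom_length chromosome length in bp.
#' @param chrom chromosome name.
#' @param map a [genetic_map()].
#' @param error_free if TRUE (default) genotypes are taken from the
#'   gene-dropped truth without sequencing noise; otherwise the coverage
#'   models below apply.
#' @param wgs_model,gbs_model [coverage_model()]s for dense and framework
#'   assays.
#' @param gbs_call_rate per-cell framework call rate; the default 0.69
#'   emulates the per-site callability of a PstI GBS assay (set 1 for a
#'   fully observed framework).
#' @param n_iv_samples,burn_in,thin MCMC settings for IV sampling.
#' @param k_dense dense-bit draws per IV realization.
#' @param thresholds a [call_thresholds()].
#' @return An object of class `"sim_scenario"`.
#' @export
sim_scenario <- function(ped = colony_pedigree(), n_framework = 833,
                         n_dense = 5010, chrom_length = 55e6,
                         chrom = "chrS", map = constant_map(1),
                         error_free = TRUE,
                         wgs_model = coverage_model(30, 0.01),
                         gbs_model = coverage_model(30, 0.01),
                         gbs_call_rate = 0.69,
                         n_iv_samples = 1000, burn_in = 1000, thin = 5,
                         k_dense = 1, thresholds = call_thresholds()) {
  structure(list(ped = ped, n_framework = n_framework, n_dense = n_dense,
                 chrom_length = chrom_length, chrom = chrom, map = map,
                 error_free = error_free, wgs_model = wgs_model,
                 gbs_model = gbs_model, gbs_call_rate = gbs_call_rate,
                 n_iv_samples = n_iv_samples, burn_in = burn_in,
                 thin = thin, k_dense = k_dense, thresholds = thresholds),
            class = "sim_scenario")
}

# Marker tables for a scenario: evenly spaced framework sites with
# MAF > 0.25, dense sites offset so positions never collide.
.scenario_markers <- function(scen, seed) {
  set.seed(seed)
  fw_space <- scen$chrom_length / (scen$n_framework + 1)
  fw_pos <- round(fw_space * seq_len(scen$n_framework))
  dn_space <- scen$chrom_length / (scen$n_dense + 1)
  dn_pos <- round(dn_space * seq_len(scen$n_dense)) + 3
  dn_pos <- setdiff(dn_pos, fw_pos)
  fw <- data.frame(chrom = scen$chrom, pos = fw_pos, ref = "A", alt = "G",
                   alt_freq = stats::runif(length(fw_pos), 0.25, 0.75),
                   panel = "framework", stringsAsFactors = FALSE)
  dn <- data.frame(chrom = scen$chrom, pos = dn_pos, ref = "C", alt = "T",
                   alt_freq = pmin(pmax(stats::rbeta(length(dn_pos), 1, 3),
                                        0.02), 0.98),
                   panel = "dense", stringsAsFactors = FALSE)
  all <- rbind(fw, dn)
  all[order(all$pos), ]
}

#' Simulate one realization of a scenario
#'
#' Gene-drops the combined framework + dense marker panel (one linkage
#' chain, so framework and dense sites share their recombination history),
#' then derives the observed framework matrix for all pedigree members and
#' the dense truth.
#'
#' @param scen a [sim_scenario()].
#' @param seed integer seed.
#' @return List: `truth` (truth panel over all markers), `framework`
#'   ([genotype_matrix()] for all members), `dense_markers`, `dense_truth`
#'   (individuals x dense dose matrix), `fw_idx`/`dn_idx` (indices into the
#'   combined panel).
#' @export
simulate_scenario <- function(scen, seed = 1) {
  markers <- .scenario_markers(scen, seed)
  truth <- simulate_truth(scen$ped, markers, scen$map, seed = seed + 1)
  fw_idx <- which(markers$panel == "framework")
  dn_idx <- which(markers$panel == "dense")
  if (scen$error_free) {
    g <- genotype_matrix(scen$ped$id, markers, truth_genotypes(truth))
  } else {
    g <- simulate_observation(truth, scen$gbs_model, seed = seed + 2)
  }
  fw <- subset_genotypes(g, markers = fw_idx)
  if (scen$gbs_call_rate < 1) {
    fw <- apply_gbs_design(fw, gbs_design(seq_len(nrow(fw$markers)),
                                          scen$gbs_call_rate),
                           seed = seed + 3)
  }
  dense_truth <- truth_genotypes(truth)[, dn_idx, drop = FALSE]
  dense_obs_src <- if (scen$error_free) {
    dense_truth
  } else {
    simulate_observation(truth, scen$wgs_model,
                         seed = seed + 4)$geno[, dn_idx, drop = FALSE]
  }
  list(truth = truth, framework = fw,
       dense_markers = markers[dn_idx, setdiff(names(markers), "panel")],
       dense_truth = dense_truth, dense_obs_src = dense_obs_src,
       fw_idx = fw_idx, dn_idx = dn_idx)
}

#' Mask non-framework genotypes
#'
#' Sets every genotype at non-framework markers to missing, retaining the
#' originals as the truth store for later comparison of imputed versus
#' masked genotypes.
#'
#' @param g a [genotype_matrix()].
#' @param framework framework marker data frame (matched on chrom + pos).
#' @return List: `masked` (the matrix with dense cells missing) and
#'   `truth` (original dose matrix restricted to the masked markers) with
#'   attribute `"marker_idx"`.
#' @export
mask_nonframework <- function(g, framework) {
  key <- function(m) paste(m$chrom, m$pos)
  is_fw <- key(g$markers) %in% key(framework)
  geno <- g$geno
  truth <- geno[, !is_fw, drop = FALSE]
  geno[, !is_fw] <- NA_integer_
  out <- list(masked = genotype_matrix(g$ids, g$markers, geno, g$depth,
                                       g$gq),
              truth = truth)
  attr(out$truth, "marker_idx") <- which(!is_fw)
  out
}

# per-individual allele matching of one calling method against truth
.acc_one <- function(imp, truth_dose, i, method) {
  t <- truth_dose[i, ]
  known <- !is.na(t)
  if (method == "most_likely") {
    c2 <- imp$ml_dose[i, ]
    done <- known & !is.na(c2)
    attempted <- 2L * sum(done)
    correct <- sum(2L - abs(c2[done] - t[done]))
    n_alleles <- ifelse(is.na(imp$ml_dose[i, ]), 0L, 2L)
  } else {
    nall <- imp$thr_n_alleles[i, ]
    full <- known & nall == 2L
    half <- known & nall == 1L
    attempted <- 2L * sum(full) + sum(half)
    correct <- sum(2L - abs(imp$thr_dose[i, full] - t[full]))
    al <- imp$thr_allele[i, half]
    correct <- correct + sum(ifelse(al == 1L, t[half] >= 1L,
                                    t[half] <= 1L))
    n_alleles <- nall
  }
  D <- sum(known)
  list(attempted = attempted, correct = correct,
       accuracy = if (attempted > 0) correct / attempted else NA_real_,
       marker_fraction = sum(n_alleles[known] > 0L) / D,
       allele_fraction = sum(n_alleles[known]) / (2 * D))
}

#' Allele-level imputation accuracy
#'
#' The proportion of alleles imputed correctly among all attempted allele
#' calls, matched by multiset containment against the true unphased
#' genotype: a two-allele call scores each allele against the true pair
#' (RA against true AA counts 1 correct of 2 attempted), a single-allele
#' call scores 1 attempted and is correct when the allele occurs in the
#' true pair.
#'
#' @param imp an `"imputation"` object.
#' @param truth_dose integer matrix (individuals x dense markers) of true
#'   alt dosages (`NA` cells are excluded from both numerator and
#'   denominator).
#' @param ids individuals to report (default: non-donors).
#' @param method `"threshold"` or `"most_likely"`.
#' @return Data frame: `id`, `method`, `attempted`, `correct`, `accuracy`,
#'   `marker_fraction` (markers with at least one called allele),
#'   `allele_fraction` (called alleles over twice the markers).
#' @export
allele_accuracy <- function(imp, truth_dose, ids = NULL,
                            method = c("threshold", "most_likely")) {
  method <- match.arg(method)
  if (is.null(ids)) ids <- setdiff(imp$ids, imp$donors)
  out <- lapply(ids, function(id) {
    i <- match(id, imp$ids)
    a <- .acc_one(imp, truth_dose, i, method)
    data.frame(id = id, method = method, attempted = a$attempted,
               correct = a$correct, accuracy = a$accuracy,
               marker_fraction = a$marker_fraction,
               allele_fraction = a$allele_fraction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fraction of markers and alleles imputed
#'
#' Marker-level: markers with at least one called allele over attempted
#' markers. Allele-level: called alleles over twice the attempted markers.
#' The most-likely method always has marker-level fraction 1.
#'
#' @param imp an `"imputation"` object.
#' @param ids individuals to report (default: non-donors).
#' @param method calling method.
#' @return Data frame: `id`, `marker_fraction`, `allele_fraction`.
#' @export
fraction_imputed <- function(imp, ids = NULL,
                             method = c("threshold", "most_likely")) {
  method <- match.arg(method)
  if (is.null(ids)) ids <- setdiff(imp$ids, imp$donors)
  D <- nrow(imp$markers)
  out <- lapply(ids, function(id) {
    i <- match(id, imp$ids)
    n_alleles <- if (method == "most_likely") {
      ifelse(is.na(imp$ml_dose[i, ]), 0L, 2L)
    } else {
      imp$thr_n_alleles[i, ]
    }
    data.frame(id = id, marker_fraction = mean(n_alleles > 0L),
               allele_fraction = sum(n_alleles) / (2 * D),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Imputation rate and accuracy stratified by allele frequency
#'
#' Every true allele copy (two per individual-site) is binned by its
#' population frequency (the alt copy by `p`, each ref copy by `1 - p`).
#' For each bin: the imputation rate (correctly called copies over true
#' copies) and the accuracy among called copies. Singleton alleles —
#' exactly one copy among `ref_chroms` reference chromosomes — are reported
#' as their own row.
#'
#' @param imp an `"imputation"` object.
#' @param truth_dose true dose matrix as in [allele_accuracy()].
#' @param ids individuals to report (default: non-donors).
#' @param bins frequency bin edges (half-open, last bin closed).
#' @param ref_chroms reference chromosome count for the singleton rule
#'   (default 30).
#' @return Data frame: `bin`, `n_true`, `n_called`, `n_correct`, `rate`,
#'   `accuracy`; the last row is the singleton stratum.
#' @export
stratify_by_freq <- function(imp, truth_dose, ids = NULL,
                             bins = c(0, 0.25, 0.5, 0.75, 1),
                             ref_chroms = 30) {
  if (is.null(ids)) ids <- setdiff(imp$ids, imp$donors)
  ri <- match(ids, imp$ids)
  p <- imp$markers$alt_freq
  nb <- length(bins) - 1
  lab <- paste0("[", bins[-length(bins)], ",", bins[-1],
                c(rep(")", nb - 1), "]"))
  acc <- matrix(0, nb + 1, 3,
                dimnames = list(c(lab, "singleton"),
                                c("n_true", "n_called", "n_correct")))
  bin_of <- function(f) pmin(findInterval(f, bins, rightmost.closed = TRUE),
                             nb)
  for (i in ri) {
    t <- truth_dose[i, ]
    known <- which(!is.na(t))
    nall <- imp$thr_n_alleles[i, ]
    # called copies per allele type
    ca <- integer(length(t)); cr <- integer(length(t))
    full <- nall == 2L
    ca[full] <- imp$thr_dose[i, full]
    cr[full] <- 2L - imp$thr_dose[i, full]
    half <- nall == 1L
    ca[half] <- as.integer(imp$thr_allele[i, half] == 1L)
    cr[half] <- as.integer(imp$thr_allele[i, half] == 0L)
    for (j in known) {
      tt <- t[j]
      add <- function(row, n_true, n_called, n_correct) {
        acc[row, ] <<- acc[row, ] + c(n_true, n_called, n_correct)
      }
      alt_rows <- bin_of(p[j])
      ref_rows <- bin_of(1 - p[j])
      add(alt_rows, tt, ca[j], min(ca[j], tt))
      add(ref_rows, 2L - tt, cr[j], min(cr[j], 2L - tt))
      if (round(p[j] * ref_chroms) == 1) {
        add(nb + 1, tt, ca[j], min(ca[j], tt))
      }
      if (round((1 - p[j]) * ref_chroms) == 1) {
        add(nb + 1, 2L - tt, cr[j], min(cr[j], 2L - tt))
      }
    }
  }
  out <- as.data.frame(acc)
  out$bin <- rownames(acc)
  out$rate <- ifelse(out$n_true > 0, out$n_correct / out$n_true, NA)
  out$accuracy <- ifelse(out$n_called > 0, out$n_correct / out$n_called, NA)
  rownames(out) <- NULL
  out[, c("bin", "n_true", "n_called", "n_correct", "rate", "accuracy")]
}

#' Genotype concordance between two matrices
#'
#' Fraction of identical genotype calls among cells non-missing in both
#' matrices, over the shared (individual, marker) universe.
#'
#' @param a,b [genotype_matrix()] objects.
#' @return List: `concordance`, `n_both`, `n_callable_a`, `n_callable_b`.
#' @export
genotype_concordance <- function(a, b) {
  key <- function(m) paste(m$chrom, m$pos, m$ref, m$alt)
  shared <- intersect(key(a$markers), key(b$markers))
  ids <- intersect(a$ids, b$ids)
  if (!length(shared) || !length(ids)) {
    stop("no shared markers/individuals")
  }
  ga <- a$geno[ids, match(shared, key(a$markers)), drop = FALSE]
  gb <- b$geno[ids, match(shared, key(b$markers)), drop = FALSE]
  both <- !is.na(ga) & !is.na(gb)
  if (!any(both)) stop("no cells non-missing in both matrices")
  list(concordance = mean(ga[both] == gb[both]), n_both = sum(both),
       n_callable_a = sum(!is.na(ga)), n_callable_b = sum(!is.na(gb)))
}

# shared engine: IV inference once, then imputation + evaluation per donor
# set
.impute_and_score <- function(scen, data, donors, ivs, seed) {
  dense_obs <- matrix(NA_integer_, length(scen$ped$id),
                      nrow(data$dense_markers))
  di <- match(donors, scen$ped$id)
  dense_obs[di, ] <- data$dense_obs_src[di, ]
  imp <- impute_chromosome(scen$ped, ivs, data$dense_markers, dense_obs,
                           scen$map, thresholds = scen$thresholds,
                           k_dense = scen$k_dense, seed = seed)
  rec <- setdiff(scen$ped$id, donors)
  rbind(allele_accuracy(imp, data$dense_truth, rec, "threshold"),
        allele_accuracy(imp, data$dense_truth, rec, "most_likely"))
}

.infer_ivs <- function(scen, framework, seed) {
  sample_iv_mcmc(scen$ped, framework, scen$map,
                 n_samples = scen$n_iv_samples, burn_in = scen$burn_in,
                 thin = scen$thin, seed = seed)
}

#' Compare donor-selection strategies
#'
#' For each replicate, simulates the scenario once, infers inheritance
#' vectors once, then imputes and scores with each donor set: the greedy
#' coverage ranking (`gigi_pick`), the most prolific founders
#' (`founders`), and the deepest childless generation (`bottom`).
#'
#' @param scen a [sim_scenario()].
#' @param n_donors donors per strategy (default 3).
#' @param n_replicates seeded replicates.
#' @param seed base seed; replicate `r` uses `seed + 1000 * r` offsets.
#' @param candidates sequencing candidates for the greedy ranking
#'   (default [wgs_candidates()]).
#' @return Tidy data frame: `replicate`, `strategy`, `method`, `id`,
#'   accuracy and fraction columns from [allele_accuracy()].
#' @export
run_strategy_comparison <- function(scen, n_donors = 3, n_replicates = 1,
                                    seed = 1,
                                    candidates = wgs_candidates()) {
  pick <- gigi_pick_rank(scen$ped, n_donors, candidates = candidates,
                         seed = seed)$id
  sets <- list(gigi_pick = pick,
               founders = heuristic_founders(scen$ped, n_donors),
               bottom = heuristic_bottom(scen$ped, n_donors))
  out <- list()
  for (r in seq_len(n_replicates)) {
    s <- seed + 1000L * r
    data <- simulate_scenario(scen, seed = s)
    ivs <- .infer_ivs(scen, data$framework, seed = s + 10L)
    for (nm in names(sets)) {
      res <- .impute_and_score(scen, data, sets[[nm]], ivs, seed = s + 20L)
      res$replicate <- r
      res$strategy <- nm
      out[[length(out) + 1L]] <- res
    }
  }
  do.call(rbind, out)
}

#' Donor-number sweep
#'
#' Imputation accuracy and fraction imputed as donors are added
#' consecutively in a given ranking (default: the greedy coverage ranking
#' of the sequencing candidates).
#'
#' @param scen a [sim_scenario()].
#' @param donor_order character vector; donors `1..n` are its prefixes.
#' @param n_donors vector of donor counts to evaluate.
#' @param n_replicates,seed replication settings.
#' @return Tidy data frame with a `n_donors` column.
#' @export
run_wgs_ratio_sweep <- function(scen, donor_order = NULL, n_donors = 1:9,
                                n_replicates = 1, seed = 1) {
  if (is.null(donor_order)) {
    donor_order <- gigi_pick_rank(scen$ped, length(wgs_candidates()),
                                  candidates = wgs_candidates(),
                                  seed = seed)$id
  }
  stopifnot(max(n_donors) <= length(donor_order))
  out <- list()
  for (r in seq_len(n_replicates)) {
    s <- seed + 1000L * r
    data <- simulate_scenario(scen, seed = s)
    ivs <- .infer_ivs(scen, data$framework, seed = s + 10L)
    for (k in n_donors) {
      res <- .impute_and_score(scen, data, donor_order[seq_len(k)], ivs,
                               seed = s + 20L + k)
      res$replicate <- r
      res$n_donors <- k
      out[[length(out) + 1L]] <- res
    }
  }
  do.call(rbind, out)
}

#' Framework panel density sweep
#'
#' Re-runs inheritance-vector inference and imputation on nested framework
#' panels defined by per-site callability thresholds (sites called in at
#' least `min_called` individuals), emulating panels built at decreasing
#' stringency from missing data.
#'
#' @param scen a [sim_scenario()] (use `gbs_call_rate < 1` so panels
#'   differ).
#' @param min_called vector of per-site called-individual thresholds.
#' @param donors donor ids (default: greedy top 4 of the candidates).
#' @param n_replicates,seed replication settings.
#' @return Tidy data frame with `min_called` and `n_markers` columns.
#' @export
run_panel_density_sweep <- function(scen, min_called = c(16, 8, 4, 1),
                                    donors = NULL, n_replicates = 1,
                                    seed = 1) {
  if (is.null(donors)) {
    donors <- gigi_pick_rank(scen$ped, 4, candidates = wgs_candidates(),
                             seed = seed)$id
  }
  out <- list()
  for (r in seq_len(n_replicates)) {
    s <- seed + 1000L * r
    data <- simulate_scenario(scen, seed = s)
    n_called <- colSums(!is.na(data$framework$geno))
    for (mc in min_called) {
      keep <- which(n_called >= mc)
      if (length(keep) < 2L) next
      fw <- subset_genotypes(data$framework, markers = keep)
      ivs <- .infer_ivs(scen, fw, seed = s + 10L + mc)
      res <- .impute_and_score(scen, data, donors, ivs,
                               seed = s + 200L + mc)
      res$replicate <- r
      res$min_called <- mc
      res$n_markers <- length(keep)
      out[[length(out) + 1L]] <- res
    }
  }
  do.call(rbind, out)
}
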