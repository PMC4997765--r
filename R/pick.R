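#' Expected imputation coverage of a donor set
#'
#' The coverage of a set `S` of sequenced individuals is the expected
#' fraction of allele slots in the pedigree whose founder gene is carried by
#' some member of `S`, at a single unlinked locus ("genome-wide" mode,
#' requiring only the pedigree structure). A slot whose gene is carried by a
#' sequenced individual can be imputed from that individual's genotype.
#' Computed by exact enumeration over all `2^m` inheritance vectors when
#' `m <= exact_max`, else by Monte-Carlo gene dropping.
#'
#' This descent-based metric scores a slot as covered as soon as its gene is
#' carried by a selected individual; it does not integrate over genotype
#' configurations (a heterozygous carrier identifies its two gene alleles
#' only probabilistically), which makes it an optimistic but monotone and
#' fast screening criterion.
#'
#' @param ped a [pedigree()].
#' @param S character vector of selected individual ids.
#' @param n_draws Monte-Carlo draws (when enumeration is infeasible, or
#'   always for the genotype-integrated metric).
#' @param seed integer seed.
#' @param exact_max enumerate exactly up to this meiosis count (default 16;
#'   descent metric only).
#' @param include_selected count the selected individuals' own slots
#'   (default TRUE; they contribute coverage 1).
#' @param metric `"descent"` (default): a slot is covered when its gene is
#'   carried by a donor; `"genotype"`: Monte-Carlo over gene drops and
#'   founder alleles, a slot is covered only when the donors' genotypes
#'   determine its gene's allele (integrating over genotype
#'   configurations).
#' @param p founder alt-allele frequency for the genotype-integrated
#'   metric (default 0.5, the least informative case).
#' @return List: `coverage`, `se` (0 for exact), `n_draws`, `exact`.
#' @examples
#' trio <- pedigree(c("F1", "M1", "C1"), c(NA, NA, "F1"), c(NA, NA, "M1"))
#' expected_coverage(trio, "C1")$coverage  # 2/3
#' @export
expected_coverage <- function(ped, S, n_draws = 10000, seed = 1,
                              exact_max = 16, include_selected = TRUE,
                              metric = c("descent", "genotype"), p = 0.5) {
  metric <- match.arg(metric)
  if (length(ped$id) == 0L) stop("empty pedigree")
  bad <- setdiff(S, ped$id)
  if (length(bad)) stop("unknown id(s): ", paste(bad, collapse = ", "))
  pc <- .ped_c(ped)
  set.seed(seed)
  if (metric == "genotype") {
    res <- cpp_coverage_geno(pc$sire, pc$dam, pc$frank, pc$patm, pc$matm,
                             ped$id %in% S, ped$n_meioses, n_draws, p,
                             include_selected)
    return(list(coverage = res$coverage, se = res$se,
                n_draws = res$n_draws, exact = FALSE))
  }
  exact <- ped$n_meioses <= exact_max
  res <- cpp_coverage(pc$sire, pc$dam, pc$frank, pc$patm, pc$matm,
                      ped$id %in% S, ped$n_meioses, exact, n_draws,
                      include_selected)
  list(coverage = res$coverage, se = res$se, n_draws = res$n_draws,
       exact = exact)
}

#' Greedy coverage-based ranking of sequencing candidates
#'
#' Iteratively adds the candidate whose inclusion maximizes
#' [expected_coverage()] of the augmented set (ties broken by id order),
#' optionally restricted to a candidate subset (e.g. the individuals for
#' which DNA of sequencing grade is available).
#'
#' @param ped a [pedigree()].
#' @param k number of individuals to rank.
#' @param candidates optional id subset to rank within (default: all).
#' @param n_draws,seed,exact_max,metric,p passed to [expected_coverage()];
#'   the ranking defaults to the genotype-integrated metric, which scores a
#'   slot only when the donors' genotypes determine its allele.
#' @return Data frame: `rank`, `id`, `gain` (marginal coverage gain),
#'   `coverage` (cumulative), `se`.
#' @export
gigi_pick_rank <- function(ped, k, candidates = NULL, n_draws = 10000,
                           seed = 1, exact_max = 16,
                           metric = c("genotype", "descent"), p = 0.5) {
  metric <- match.arg(metric)
  if (is.null(candidates)) candidates <- ped$id
  candidates <- candidates[order(match(candidates, ped$id))]
  stopifnot(k >= 1, k <= length(candidates))
  chosen <- character(0)
  prev <- 0
  out <- data.frame(rank = integer(0), id = character(0), gain = numeric(0),
                    coverage = numeric(0), se = numeric(0))
  for (step in seq_len(k)) {
    rest <- setdiff(candidates, chosen)
    # one fixed seed per step so all candidate evaluations share draws
    cov <- vapply(rest, function(x) {
      expected_coverage(ped, c(chosen, x), n_draws = n_draws,
                        seed = seed + step, exact_max = exact_max,
                        metric = metric, p = p)$coverage
    }, numeric(1))
    best <- rest[which.max(cov)]  # ties: first in id order
    est <- expected_coverage(ped, c(chosen, best), n_draws = n_draws,
                             seed = seed + step, exact_max = exact_max,
                             metric = metric, p = p)
    out <- rbind(out, data.frame(rank = step, id = best,
                                 gain = est$coverage - prev,
                                 coverage = est$coverage, se = est$se))
    prev <- est$coverage
    chosen <- c(chosen, best)
  }
  rownames(out) <- NULL
  out
}

#' Bottom-of-pedigree selection heuristic
#'
#' Selects `k` childless individuals (the most recent generation), ranked
#' by the number of in-pedigree ancestors (descending; deeper individuals
#' summarize more meioses) and then by id. In an all-founder pedigree every
#' founder is childless and founders are returned.
#'
#' @param ped a [pedigree()].
#' @param k number of individuals.
#' @return Character vector of `k` ids.
#' @export
heuristic_bottom <- function(ped, k) {
  cl <- childless(ped)
  if (length(cl) < k) {
    stop("fewer than k = ", k, " childless individuals")
  }
  n_anc <- vapply(match(cl, ped$id),
                  function(i) length(.ancestor_set(ped, i)), integer(1))
  cl[order(-n_anc, cl)][seq_len(k)]
}

#' Founders selection heuristic
#'
#' Selects `k` founders ranked by descendant count (descending) then id.
#'
#' @param ped a [pedigree()].
#' @param k number of founders.
#' @return Character vector of `k` ids (empty for `k = 0`).
#' @export
heuristic_founders <- function(ped, k) {
  f <- founders(ped)
  if (length(f) < k) stop("fewer than k = ", k, " founders")
  if (k == 0L) return(character(0))
  n_desc <- vapply(match(f, ped$id),
                   function(i) length(.descendant_set(ped, i)), integer(1))
  f[order(-n_desc, f)][seq_len(k)]
}
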