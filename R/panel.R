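#' Framework panel filtering criteria
#'
#' Quality criteria for markers suitable to anchor imputation: reliably
#' sequenced (site depth), callable in a majority of individuals, common
#' (high minor-allele frequency, so most individuals are informative), and
#' optionally concordant between the sparse (GBS) and dense (WGS) assays.
#' "Majority of libraries at depth" is implemented with the same 50%
#' threshold as callability.
#'
#' @param min_site_depth minimum per-genotype depth for a call to count
#'   (default 20).
#' @param min_call_rate minimum fraction of individuals with a qualifying
#'   call (default 0.5).
#' @param min_maf minimum minor-allele frequency, exclusive (default 0.25).
#' @param require_concordance require every individual with both GBS and
#'   WGS calls to agree (default TRUE).
#' @param target_spacing marker spacing target in bp (default 65000,
#'   about 0.5-1 cM on a 1 cM/Mb map).
#' @return An object of class `"panel_spec"`.
#' @export
panel_spec <- function(min_site_depth = 20, min_call_rate = 0.5,
                       min_maf = 0.25, require_concordance = TRUE,
                       target_spacing = 65000) {
  stopifnot(min_call_rate > 0, min_call_rate <= 1, target_spacing > 0)
  structure(list(min_site_depth = min_site_depth,
                 min_call_rate = min_call_rate, min_maf = min_maf,
                 require_concordance = require_concordance,
                 target_spacing = target_spacing),
            class = "panel_spec")
}

#' Candidate framework sites
#'
#' Filters the shared marker universe of a GBS and a WGS genotype matrix to
#' sites that (a) have a qualifying GBS call (non-missing, depth at least
#' `min_site_depth`) in at least `min_call_rate` of individuals, (b) have
#' sample minor-allele frequency above `min_maf` (computed from non-missing
#' GBS calls), and (c), if required, show no GBS/WGS discordance in any
#' individual carrying both calls (strict any-discordance rule; the
#' rate-based alternative is controlled by `max_discordant`).
#'
#' @param gbs,wgs [genotype_matrix()] objects sharing a marker universe.
#' @param spec a [panel_spec()].
#' @param max_discordant maximum number of discordant individuals tolerated
#'   per site when concordance is required (default 0).
#' @return The marker data frame of retained sites, with `alt_freq` set to
#'   the GBS sample frequency, plus an index attribute `"gbs_idx"`.
#' @export
candidate_framework_sites <- function(gbs, wgs, spec = panel_spec(),
                                      max_discordant = 0) {
  key <- function(m) paste(m$chrom, m$pos, m$ref, m$alt)
  shared <- intersect(key(gbs$markers), key(wgs$markers))
  if (!length(shared)) stop("no shared markers between GBS and WGS matrices")
  gi <- match(shared, key(gbs$markers))
  wi <- match(shared, key(wgs$markers))
  geno <- gbs$geno[, gi, drop = FALSE]
  depth <- gbs$depth[, gi, drop = FALSE]
  qual_call <- !is.na(geno) & !is.na(depth) & depth >= spec$min_site_depth
  call_rate <- colMeans(qual_call)
  called <- colSums(!is.na(geno))
  alt <- colSums(geno, na.rm = TRUE)
  freq <- ifelse(called > 0, alt / (2 * called), NA)
  maf <- pmin(freq, 1 - freq)
  keep <- call_rate >= spec$min_call_rate & !is.na(maf) & maf > spec$min_maf
  if (spec$require_concordance) {
    common_ids <- intersect(gbs$ids, wgs$ids)
    gg <- geno[common_ids, , drop = FALSE]
    ww <- wgs$geno[common_ids, wi, drop = FALSE]
    disc <- colSums(!is.na(gg) & !is.na(ww) & gg != ww)
    keep <- keep & disc <= max_discordant
  }
  out <- gbs$markers[gi[keep], , drop = FALSE]
  out$alt_freq <- freq[keep]
  rownames(out) <- NULL
  attr(out, "gbs_idx") <- gi[keep]
  out
}

#' Greedy even-spacing marker selection
#'
#' Left-to-right per chromosome: keep the first candidate, then every next
#' candidate at least `target_spacing` from the last kept one (bp, or cM
#' when a map is given).
#'
#' @param candidates marker data frame sorted by (chrom, pos).
#' @param target_spacing minimum spacing (bp, or cM with `units = "cM"`).
#' @param map a [genetic_map()], required for cM spacing.
#' @param units `"bp"` or `"cM"`.
#' @return The retained subset of `candidates`.
#' @export
select_spaced_markers <- function(candidates, target_spacing, map = NULL,
                                  units = c("bp", "cM")) {
  units <- match.arg(units)
  if (nrow(candidates) == 0L) return(candidates)
  keep <- logical(nrow(candidates))
  for (ch in unique(candidates$chrom)) {
    idx <- which(candidates$chrom == ch)
    pos <- candidates$pos[idx]
    if (units == "cM") {
      if (is.null(map)) stop("cM spacing needs a genetic map")
      pos <- bp_to_cm(map, ch, pos)
    }
    last <- -Inf
    for (j in seq_along(idx)) {
      if (pos[j] - last >= target_spacing || is.infinite(last)) {
        keep[idx[j]] <- TRUE
        last <- pos[j]
      }
    }
  }
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select dense markers for imputation
#'
#' Applies [select_spaced_markers()] to the WGS site pool after excluding
#' framework positions, yielding the dense panel whose genotypes are to be
#' imputed.
#'
#' @param wgs_sites marker data frame of WGS-discovered sites.
#' @param spacing minimum spacing in bp (default 10000).
#' @param framework optional framework marker data frame to exclude.
#' @return The dense marker subset.
#' @export
select_dense_markers <- function(wgs_sites, spacing = 10000,
                                 framework = NULL) {
  if (!is.null(framework) && nrow(framework)) {
    key <- function(m) paste(m$chrom, m$pos)
    wgs_sites <- wgs_sites[!key(wgs_sites) %in% key(framework), ,
                           drop = FALSE]
  }
  select_spaced_markers(wgs_sites, spacing)
}

#' Estimate allele frequencies from a reference cohort
#'
#' Alt frequency per marker as alt-allele count over non-missing allele
#' count among non-excluded reference individuals (the study pedigree is
#' excluded so that imputation priors are independent of the analysis
#' cohort). With `pseudo_clamp`, frequencies are clamped to
#' `[1/(2N+2), 1 - 1/(2N+2)]` so monomorphic reference markers still yield
#' proper imputation priors.
#'
#' @param reference a [genotype_matrix()] of reference individuals.
#' @param exclude ids to drop (e.g. relatives of the study cohort).
#' @param pseudo_clamp clamp frequencies away from 0/1 (default TRUE).
#' @return Numeric vector of alt frequencies (NA where no calls remain,
#'   with a warning).
#' @export
estimate_allele_freqs <- function(reference, exclude = character(0),
                                  pseudo_clamp = TRUE) {
  keep <- !reference$ids %in% exclude
  if (!any(keep)) stop("no reference individuals left after exclusions")
  geno <- reference$geno[keep, , drop = FALSE]
  called <- colSums(!is.na(geno))
  freq <- ifelse(called > 0, colSums(geno, na.rm = TRUE) / (2 * called), NA)
  if (any(is.na(freq))) {
    warning(sum(is.na(freq)), " marker(s) with no non-missing reference call")
  }
  if (pseudo_clamp) {
    n <- sum(keep)
    lo <- 1 / (2 * n + 2)
    freq <- pmin(pmax(freq, lo), 1 - lo)
  }
  freq
}

#' Write a marker panel as TSV
#'
#' @param framework,dense marker data frames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel_tsv <- function(framework, dense, path) {
  fw <- cbind(framework[, c("chrom", "pos", "ref", "alt", "alt_freq")],
              panel = "framework")
  dn <- cbind(dense[, c("chrom", "pos", "ref", "alt", "alt_freq")],
              panel = "dense")
  utils::write.table(rbind(fw, dn), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
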