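#' Genotype matrix container
#'
#' Individuals by biallelic-SNV markers, with per-cell alt-allele dosage
#' (0/1/2, `NA` = missing), read depth and genotype quality. Markers are kept
#' sorted by (chrom, pos). Depth and quality may be recorded even where the
#' genotype itself is missing (a filtered call retains its DP/GQ).
#'
#' @param ids character vector of individual ids (rows).
#' @param markers data frame with columns `chrom`, `pos`, `ref`, `alt` and
#'   optionally `alt_freq` (population alt-allele frequency in (0,1)).
#' @param geno integer matrix `length(ids) x nrow(markers)` of alt dosages.
#' @param depth,gq optional integer matrices of the same shape.
#' @return An object of class `"genotype_matrix"`.
#' @export
genotype_matrix <- function(ids, markers, geno, depth = NULL, gq = NULL) {
  ids <- as.character(ids)
  stopifnot(is.data.frame(markers),
            all(c("chrom", "pos", "ref", "alt") %in% names(markers)))
  geno <- as.matrix(geno)
  if (nrow(geno) != length(ids) || ncol(geno) != nrow(markers)) {
    stop("geno must be length(ids) x nrow(markers)")
  }
  ord <- order(markers$chrom, markers$pos)
  if (any(ord != seq_along(ord))) {
    markers <- markers[ord, , drop = FALSE]
    geno <- geno[, ord, drop = FALSE]
    if (!is.null(depth)) depth <- depth[, ord, drop = FALSE]
    if (!is.null(gq)) gq <- gq[, ord, drop = FALSE]
  }
  rownames(markers) <- NULL
  if (is.null(depth)) depth <- matrix(NA_integer_, length(ids), nrow(markers))
  if (is.null(gq)) gq <- matrix(NA_integer_, length(ids), nrow(markers))
  if (!"alt_freq" %in% names(markers)) markers$alt_freq <- NA_real_
  dimnames(geno) <- list(ids, NULL)
  structure(list(ids = ids, markers = markers,
                 geno = geno, depth = as.matrix(depth), gq = as.matrix(gq)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", length(x$ids), " individuals x ",
      nrow(x$markers), " markers; ",
      round(100 * mean(is.na(x$geno)), 1), "% missing\n", sep = "")
  invisible(x)
}

#' Subset a genotype matrix by markers and/or individuals
#' @param g a [genotype_matrix()].
#' @param markers integer or logical index into the marker list.
#' @param ids character vector of individual ids to keep.
#' @return A [genotype_matrix()].
#' @export
subset_genotypes <- function(g, markers = NULL, ids = NULL) {
  mi <- if (is.null(markers)) seq_len(nrow(g$markers)) else markers
  ri <- if (is.null(ids)) seq_along(g$ids) else match(ids, g$ids)
  if (anyNA(ri)) stop("unknown individual id(s)")
  genotype_matrix(g$ids[ri], g$markers[mi, , drop = FALSE],
                  g$geno[ri, mi, drop = FALSE],
                  g$depth[ri, mi, drop = FALSE],
                  g$gq[ri, mi, drop = FALSE])
}

#' Mendelian-consistency check
#'
#' Lists every non-missing trio/duo genotype combination that is impossible
#' under Mendelian transmission of a biallelic marker. With both parents
#' observed, the offspring dosage must be expressible as one transmitted
#' allele per parent; with one parent observed, only the opposite-homozygote
#' combinations (parent 0 with child 2, parent 2 with child 0) are
#' impossible. Missing genotypes never trigger violations.
#'
#' @param ped a [pedigree()].
#' @param g a [genotype_matrix()] whose ids are all present in `ped`.
#' @return A data frame with one row per violation: `marker` (index),
#'   `chrom`, `pos`, `id`, `sire`, `dam`.
#' @export
mendelian_errors <- function(ped, g) {
  missing_ids <- setdiff(g$ids, ped$id)
  if (length(missing_ids)) {
    stop("individual(s) in genotype matrix absent from pedigree: ",
         paste(missing_ids, collapse = ", "))
  }
  out <- list()
  for (i in which(!ped$founder)) {
    cid <- ped$id[i]
    if (!cid %in% g$ids) next
    sid <- ped$id[ped$sire[i]]
    did <- ped$id[ped$dam[i]]
    child <- g$geno[cid, ]
    f <- if (sid %in% g$ids) g$geno[sid, ] else rep(NA_integer_, ncol(g$geno))
    m <- if (did %in% g$ids) g$geno[did, ] else rep(NA_integer_, ncol(g$geno))
    both <- !is.na(child) & !is.na(f) & !is.na(m)
    # transmissible allele sets: from 0 -> {0}, 1 -> {0,1}, 2 -> {1}
    lo <- (f == 2) + (m == 2)
    hi <- 2L - ((f == 0) + (m == 0))
    bad_trio <- both & (child < lo | child > hi)
    duo_f <- !is.na(child) & !is.na(f) & is.na(m) & (abs(child - f) == 2L)
    duo_m <- !is.na(child) & is.na(f) & !is.na(m) & (abs(child - m) == 2L)
    bad <- which(bad_trio | duo_f | duo_m)
    if (length(bad)) {
      out[[length(out) + 1L]] <- data.frame(
        marker = bad, chrom = g$markers$chrom[bad], pos = g$markers$pos[bad],
        id = cid, sire = sid, dam = did, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else {
    data.frame(marker = integer(0), chrom = character(0), pos = numeric(0),
               id = character(0), sire = character(0), dam = character(0),
               stringsAsFactors = FALSE)
  }
}

#' Read genotypes from a VCF
#'
#' Reads a VCF (v4.2, plain or gzipped) into a [genotype_matrix()]. Only
#' biallelic SNV records are used; multi-allelic and non-SNV records are
#' skipped and counted (reported via `attr(, "n_skipped")` and a message).
#' GT is converted to alt dosage (any call containing `.` is missing); DP
#' and GQ are kept when present.
#'
#' @param path path to a VCF file.
#' @param pedigree optional [pedigree()]; if supplied, sample names must all
#'   be pedigree members.
#' @return A [genotype_matrix()] with attribute `n_skipped`.
#' @export
read_genotypes_vcf <- function(path, pedigree = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- !is.na(alt) & ref %in% c("A", "C", "G", "T") &
    alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    message(n_skipped, " multi-allelic or non-SNV record(s) skipped")
  }
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  dp <- tryCatch(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE),
                 error = function(e) NULL)
  gq <- tryCatch(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE),
                 error = function(e) NULL)
  if (!is.null(dp)) dp <- dp[keep, , drop = FALSE]
  if (!is.null(gq)) gq <- gq[keep, , drop = FALSE]
  ids <- colnames(v@gt)[-1L]
  if (!is.null(pedigree)) {
    extra <- setdiff(ids, pedigree$id)
    if (length(extra)) {
      stop("VCF sample(s) not in pedigree: ", paste(extra, collapse = ", "))
    }
  }
  dose <- function(s) {
    out <- rep(NA_integer_, length(s))
    ok <- !is.na(s) & !grepl("\\.", s)
    if (any(ok)) {
      out[ok] <- vapply(strsplit(gsub("\\|", "/", s[ok]), "/"),
                        function(a) sum(as.integer(a)), integer(1))
    }
    out
  }
  geno <- matrix(NA_integer_, length(ids), nrow(gt))
  for (j in seq_along(ids)) geno[j, ] <- dose(gt[, j])
  markers <- data.frame(chrom = fix[keep, "CHROM"],
                        pos = as.numeric(fix[keep, "POS"]),
                        ref = ref[keep], alt = alt[keep],
                        stringsAsFactors = FALSE)
  g <- genotype_matrix(ids, markers, geno,
                       if (is.null(dp)) NULL else t(dp),
                       if (is.null(gq)) NULL else t(gq))
  attr(g, "n_skipped") <- n_skipped
  g
}

#' Write genotypes to a VCF
#'
#' Writes a [genotype_matrix()] as VCF v4.2 with FORMAT `GT:DP:GQ`
#' (gzip-compressed, as produced by [vcfR::write.vcf]). Writing is
#' deterministic, so write-read-write round trips produce byte-identical
#' body records.
#'
#' @param g a [genotype_matrix()].
#' @param path output path (a `.vcf.gz` suffix is conventional).
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(g, path) {
  m <- nrow(g$markers)
  gt_str <- function(i) {
    geno <- g$geno[i, ]
    gt <- c("0/0", "0/1", "1/1")[geno + 1L]
    gt[is.na(geno)] <- "./."
    dp <- ifelse(is.na(g$depth[i, ]), ".", as.character(g$depth[i, ]))
    gq <- ifelse(is.na(g$gq[i, ]), ".", as.character(g$gq[i, ]))
    paste(gt, dp, gq, sep = ":")
  }
  gt <- cbind(FORMAT = rep("GT:DP:GQ", m),
              vapply(seq_along(g$ids), gt_str, character(m)))
  colnames(gt) <- c("FORMAT", g$ids)
  fix <- cbind(CHROM = g$markers$chrom,
               POS = format(g$markers$pos, scientific = FALSE, trim = TRUE),
               ID = rep(".", m), REF = g$markers$ref, ALT = g$markers$alt,
               QUAL = rep(".", m), FILTER = rep("PASS", m),
               INFO = rep(".", m))
  meta <- c("##fileformat=VCFv4.2",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
            paste0("##FORMAT=<ID=GQ,Number=1,Type=Integer,",
                   "Description=\"Genotype quality\">"))
  v <- methods::new(methods::getClass("vcfR", where = asNamespace("vcfR")), meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}
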