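#' Restriction enzymes
#'
#' An enzyme is a recognition motif (IUPAC codes allowed) plus the 0-based
#' offset of the top-strand cut within the motif. The offset is immaterial
#' for fragment counting but is kept consistent so that cut coordinates are
#' reproducible across enzymes.
#'
#' @param name enzyme name.
#' @param motif recognition sequence, IUPAC codes allowed.
#' @param cut_offset integer in `[0, nchar(motif)]`: cut position relative to
#'   the motif start on the top strand.
#' @return An object of class `"restriction_enzyme"`.
#' @examples
#' restriction_enzyme("PstI", "CTGCAG", 5)
#' @export
restriction_enzyme <- function(name, motif, cut_offset) {
  motif <- toupper(motif)
  iupac <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
             "B", "D", "H", "V", "N")
  bad <- setdiff(strsplit(motif, "")[[1]], iupac)
  if (length(bad)) {
    stop("invalid IUPAC code(s) in motif: ", paste(bad, collapse = ", "))
  }
  stopifnot(cut_offset >= 0, cut_offset <= nchar(motif))
  structure(list(name = name, motif = motif,
                 cut_offset = as.integer(cut_offset)),
            class = "restriction_enzyme")
}

#' Built-in GBS enzymes
#'
#' The enzymes commonly screened for reduced-representation genotyping
#' panels. PstI (CTGCAG, cut after position 5) is the 6-cutter that yields
#' fragment counts in the useful range for many mammalian genomes.
#'
#' @param name optional enzyme name; if omitted, the full named list is
#'   returned.
#' @return A `"restriction_enzyme"` or a named list of them.
#' @export
gbs_enzymes <- function(name = NULL) {
  all <- list(
    PstI = restriction_enzyme("PstI", "CTGCAG", 5L),
    BglII = restriction_enzyme("BglII", "AGATCT", 1L),
    ApeKI = restriction_enzyme("ApeKI", "GCWGC", 1L),
    EcoRI = restriction_enzyme("EcoRI", "GAATTC", 1L),
    HindIII = restriction_enzyme("HindIII", "AAGCTT", 1L)
  )
  if (is.null(name)) return(all)
  if (!name %in% names(all)) stop("unknown built-in enzyme: ", name)
  all[[name]]
}

.revcomp_iupac <- function(motif) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
}

#' Scan a sequence for enzyme cut sites
#'
#' Finds every motif occurrence (case-insensitively; `N` in the sequence
#' never matches) and reports the 0-based cut position
#' `occurrence start + cut_offset`. Palindromic motifs are scanned on the
#' forward strand only (reverse-complement occurrences coincide);
#' non-palindromic motifs are scanned on both strands, with reverse-strand
#' cuts placed at `start + (motif length - cut_offset)`, and the merged
#' positions de-duplicated. Overlapping occurrences are all reported.
#'
#' @param seq a nucleotide character string.
#' @param enzyme a [restriction_enzyme()].
#' @return Sorted integer vector of 0-based cut positions.
#' @export
scan_sites <- function(seq, enzyme) {
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  subject <- Biostrings::DNAString(toupper(seq))
  hits <- function(motif) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(motif), subject,
                                  fixed = "subject")
    Biostrings::start(m) - 1L  # to 0-based
  }
  fwd <- hits(enzyme$motif) + enzyme$cut_offset
  rc <- .revcomp_iupac(enzyme$motif)
  if (rc == enzyme$motif) return(sort(fwd))
  rev <- hits(rc) + (nchar(enzyme$motif) - enzyme$cut_offset)
  sort(unique(c(fwd, rev)))
}

#' In silico digest of a genome
#'
#' Cuts every contig at the enzyme's predicted cut sites. A contig with `k`
#' cut sites yields exactly `k + 1` fragments tiling `[0, contig length)`
#' (0-based half-open); terminal fragments are retained. The fraction of
#' soft-masked (lowercase) bases is recorded per fragment, standing in for a
#' repeat annotation.
#'
#' @param fasta path to a (soft-masked) FASTA file, or a named character
#'   vector of sequences with original case preserved.
#' @param enzyme a [restriction_enzyme()].
#' @return Data frame of fragments: `contig`, `start`, `end` (0-based
#'   half-open), `length`, `masked_fraction`.
#' @export
digest_genome <- function(fasta, enzyme) {
  seqs <- if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    read_fasta(fasta)
  } else fasta
  if (length(seqs) == 0L) stop("empty FASTA")
  out <- lapply(names(seqs), function(ctg) {
    s <- seqs[[ctg]]
    len <- nchar(s)
    cuts <- scan_sites(s, enzyme)
    cuts <- cuts[cuts > 0L & cuts < len]
    bounds <- c(0L, cuts, len)
    start <- bounds[-length(bounds)]
    end <- bounds[-1L]
    # cumulative lowercase count for masked fractions
    raw <- charToRaw(s)
    lower <- cumsum(raw >= charToRaw("a") & raw <= charToRaw("z"))
    nmask <- lower[end] - c(0L, lower[start[-1L]])
    data.frame(contig = ctg, start = start, end = end,
               length = end - start,
               masked_fraction = as.numeric(nmask) / (end - start),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Size-select fragments
#'
#' Keeps fragments whose length lies in `[min_bp, max_bp]` (both bounds
#' inclusive), preserving order. The 200-500 bp default window is the
#' sequencing-library size selection typical for GBS.
#'
#' @param fragments a fragment data frame from [digest_genome()].
#' @param min_bp,max_bp inclusive length bounds.
#' @return The subset of `fragments` within bounds.
#' @export
size_select <- function(fragments, min_bp = 200, max_bp = 500) {
  if (min_bp > max_bp) stop("min_bp must not exceed max_bp")
  fragments[fragments$length >= min_bp & fragments$length <= max_bp, ,
            drop = FALSE]
}

#' Filter fragments by repeat content
#'
#' Drops fragments whose soft-masked fraction exceeds the threshold
#' (inclusive bound: a fragment exactly at the threshold is kept).
#'
#' @param fragments a fragment data frame.
#' @param max_masked_fraction threshold in `[0, 1]` (default 0.5).
#' @return The subset of `fragments` passing the filter.
#' @export
mask_filter <- function(fragments, max_masked_fraction = 0.5) {
  stopifnot(max_masked_fraction >= 0, max_masked_fraction <= 1)
  fragments[fragments$masked_fraction <= max_masked_fraction, , drop = FALSE]
}

#' Summarize a digest for enzyme ranking
#'
#' @param enzyme_name enzyme name.
#' @param fragments all fragments from [digest_genome()].
#' @param genome_length total genome length in bp.
#' @param min_bp,max_bp size-selection window.
#' @param max_masked_fraction repeat filter threshold (applied within the
#'   size window).
#' @return One-row data frame: `enzyme`, `n_fragments_total`,
#'   `n_in_size_range`, `bp_in_range`, `genome_fraction`.
#' @export
digest_summary <- function(enzyme_name, fragments, genome_length,
                           min_bp = 200, max_bp = 500,
                           max_masked_fraction = 0.5) {
  sel <- mask_filter(size_select(fragments, min_bp, max_bp),
                     max_masked_fraction)
  data.frame(enzyme = enzyme_name,
             n_fragments_total = nrow(fragments),
             n_in_size_range = nrow(sel),
             bp_in_range = sum(sel$length),
             genome_fraction = sum(sel$length) / genome_length,
             stringsAsFactors = FALSE)
}

#' Rank enzymes for GBS panel design
#'
#' Enzymes whose in-window fragment count falls inside the target range
#' rank first (among them, larger captured bp first: more sequence per
#' library); enzymes outside the range are ordered by their distance to the
#' nearest bound. Ties break by enzyme name. The 60,000-100,000 fragment
#' target is the count at which a size-selected library yields dense but
#' affordable marker panels for a ~3 Gb genome.
#'
#' @param summaries data frame of [digest_summary()] rows.
#' @param target_min,target_max target fragment-count range.
#' @return `summaries` reordered, with a `rank` column.
#' @export
rank_enzymes <- function(summaries, target_min = 60000, target_max = 100000) {
  if (nrow(summaries) < 1L) stop("need at least one digest summary")
  n <- summaries$n_in_size_range
  in_range <- n >= target_min & n <= target_max
  dist <- pmax(target_min - n, n - target_max, 0)
  ord <- order(!in_range, dist, -summaries$bp_in_range, summaries$enzyme)
  out <- summaries[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Read a FASTA file preserving case
#'
#' Soft-masked (lowercase) bases carry the repeat annotation, so sequences
#' are returned with their original case.
#'
#' @param path path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  s <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  out <- vapply(s, function(x) as.character(x)[1], character(1))
  names(out) <- names(s)
  out
}

#' Write sequences to FASTA
#' @param seqs named character vector of sequences (case preserved).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  seqinr::write.fasta(as.list(unname(seqs)), names = names(seqs),
                      file.out = path, as.string = TRUE, nbchar = 70)
  invisible(path)
}

#' Write fragments as BED
#'
#' 0-based half-open intervals, tab-delimited, with the masked fraction in
#' the score column.
#'
#' @param fragments a fragment data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(fragments, path) {
  bed <- data.frame(fragments$contig, fragments$start, fragments$end,
                    name = paste0("frag", seq_len(nrow(fragments))),
                    score = round(fragments$masked_fraction, 4))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
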