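#' Genetic maps
#'
#' A genetic map converts physical positions (bp) to genetic positions (cM)
#' by linear interpolation between anchor points, with constant-rate
#' extrapolation beyond the first/last anchor using the nearest interval's
#' rate. When no anchors are available for a species, a constant-rate map is
#' used; the default rate of 1 cM/Mb is the canonical mammalian average.
#'
#' @param anchors a data frame with columns `chrom`, `pos_bp`, `pos_cm`;
#'   `pos_bp` must be strictly increasing and `pos_cm` non-decreasing within
#'   each chromosome.
#' @return An object of class `"genetic_map"`.
#' @seealso [constant_map()], [bp_to_cm()], [read_map()]
#' @export
genetic_map <- function(anchors) {
  stopifnot(is.data.frame(anchors),
            all(c("chrom", "pos_bp", "pos_cm") %in% names(anchors)))
  anchors <- anchors[order(anchors$chrom, anchors$pos_bp), , drop = FALSE]
  for (ch in unique(anchors$chrom)) {
    a <- anchors[anchors$chrom == ch, ]
    if (any(diff(a$pos_bp) <= 0)) {
      stop("anchor bp positions must be strictly increasing on ", ch)
    }
    if (any(diff(a$pos_cm) < 0)) {
      stop("anchor cM positions must be non-decreasing on ", ch)
    }
  }
  structure(list(anchors = anchors, rate = NULL), class = "genetic_map")
}

#' Constant-rate genetic map
#'
#' @param rate_cm_per_mb recombination rate in cM per Mb (default 1).
#' @return A `"genetic_map"` valid for any chromosome, with
#'   `pos_cm = pos_bp * rate`.
#' @export
constant_map <- function(rate_cm_per_mb = 1) {
  stopifnot(rate_cm_per_mb > 0)
  structure(list(anchors = NULL, rate = rate_cm_per_mb / 1e6),
            class = "genetic_map")
}

#' Convert physical to genetic position
#'
#' @param map a [genetic_map()] or [constant_map()].
#' @param chrom chromosome name (scalar).
#' @param pos_bp integer vector of 1-based physical positions.
#' @return Numeric vector of genetic positions in cM.
#' @examples
#' bp_to_cm(constant_map(1), "chr1", 65000)  # 0.065 cM
#' @export
bp_to_cm <- function(map, chrom, pos_bp) {
  stopifnot(inherits(map, "genetic_map"))
  if (!is.null(map$rate)) return(pos_bp * map$rate)
  a <- map$anchors[map$anchors$chrom == chrom, , drop = FALSE]
  if (nrow(a) == 0L) stop("unknown chromosome '", chrom, "' in genetic map")
  if (nrow(a) == 1L) stop("need at least two anchors on ", chrom)
  out <- stats::approx(a$pos_bp, a$pos_cm, xout = pos_bp, rule = 1)$y
  # constant-rate extrapolation with the nearest interval's rate
  k <- nrow(a)
  r_lo <- (a$pos_cm[2] - a$pos_cm[1]) / (a$pos_bp[2] - a$pos_bp[1])
  r_hi <- (a$pos_cm[k] - a$pos_cm[k - 1]) / (a$pos_bp[k] - a$pos_bp[k - 1])
  lo <- pos_bp < a$pos_bp[1]
  hi <- pos_bp > a$pos_bp[k]
  out[lo] <- a$pos_cm[1] + (pos_bp[lo] - a$pos_bp[1]) * r_lo
  out[hi] <- a$pos_cm[k] + (pos_bp[hi] - a$pos_bp[k]) * r_hi
  out
}

#' Read a PLINK-style .map file
#'
#' Columns: chromosome, marker id, genetic position (cM), physical position
#' (bp). Rows become interpolation anchors.
#'
#' @param path path to a .map file.
#' @return A [genetic_map()].
#' @export
read_map <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 4L) stop(".map file must have 4 columns")
  genetic_map(data.frame(chrom = as.character(tab[[1L]]),
                         pos_bp = as.numeric(tab[[4L]]),
                         pos_cm = as.numeric(tab[[3L]]),
                         stringsAsFactors = FALSE))
}

#' Haldane map function
#'
#' Converts a genetic distance to a recombination fraction assuming no
#' crossover interference: `theta = (1 - exp(-2 d)) / 2` with `d` in Morgans.
#'
#' @param d_cm genetic distance in centiMorgans (non-negative).
#' @return Recombination fraction in `[0, 0.5)`.
#' @examples
#' haldane(0)    # 0
#' haldane(50)   # (1 - exp(-1)) / 2
#' @export
haldane <- function(d_cm) {
  if (any(d_cm < 0)) stop("genetic distance must be non-negative")
  (1 - exp(-2 * d_cm / 100)) / 2
}
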