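#' Construct a pedigree
#'
#' A pedigree is an ordered set of individuals with optional sire/dam links.
#' Individuals are stored in topological order (parents before offspring).
#' Each non-founder contributes two meioses (one paternal, one maternal
#' gamete); a pedigree with `f` founders among `n` members therefore has
#' `m = 2 * (n - f)` meioses, the length of its inheritance vectors.
#'
#' Both parents must be present or both absent: half-specified parentage is
#' an error rather than silently padded with a dummy founder, because adding
#' a founder changes the meiosis count and hence the likelihood. Pedigrees in
#' which any individual's parents are themselves related (inbreeding loops)
#' are rejected.
#'
#' @param id character vector of unique, non-empty individual ids.
#' @param sire,dam character vectors of parent ids; `NA` or `"0"` for absent.
#' @param sex optional character vector (`"male"`, `"female"`, `"unknown"`);
#'   carried but unused (autosomal analyses only).
#' @return An object of class `"pedigree"`: a list with elements `id`,
#'   `sire`/`dam` (integer indices, `NA` for founders), `sex`, `founder`
#'   (logical), `founder_rank`, `pat_meiosis`/`mat_meiosis` (1-based meiosis
#'   indices, `NA` for founders) and `n_meioses`.
#' @examples
#' trio <- pedigree(c("F1", "M1", "C1"), c(NA, NA, "F1"), c(NA, NA, "M1"))
#' n_meioses(trio)
#' @export
pedigree <- function(id, sire, dam, sex = NULL) {
  id <- as.character(id)
  sire <- as.character(sire)
  dam <- as.character(dam)
  sire[sire %in% c("0", "")] <- NA_character_
  dam[dam %in% c("0", "")] <- NA_character_
  n <- length(id)
  if (n == 0L) stop("empty pedigree")
  if (any(is.na(id) | id == "")) stop("individual ids must be non-empty")
  if (anyDuplicated(id)) {
    stop("duplicate individual id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  one_parent <- xor(is.na(sire), is.na(dam))
  if (any(one_parent)) {
    stop("one-parent-only individual(s): ",
         paste(id[one_parent], collapse = ", "),
         " (both parents must be present or both absent)")
  }
  missing_parent <- setdiff(stats::na.omit(c(sire, dam)), id)
  if (length(missing_parent)) {
    stop("parent id(s) not in pedigree: ",
         paste(missing_parent, collapse = ", "))
  }
  if (is.null(sex)) sex <- rep("unknown", n)
  sex <- as.character(sex)
  if (length(sex) != n) stop("sex must have one entry per individual")
  if (!all(sex %in% c("male", "female", "unknown"))) {
    stop("sex must be one of 'male', 'female', 'unknown'")
  }

  ord <- .topo_order(id, sire, dam)
  id <- id[ord]; sire <- sire[ord]; dam <- dam[ord]; sex <- sex[ord]
  sire_i <- match(sire, id)
  dam_i <- match(dam, id)
  founder <- is.na(sire_i)
  founder_rank <- ifelse(founder, cumsum(founder), NA_integer_)
  nonf_rank <- ifelse(!founder, cumsum(!founder), NA_integer_)
  ped <- structure(list(
    id = id, sire = sire_i, dam = dam_i, sex = sex,
    founder = founder,
    founder_rank = as.integer(founder_rank),
    pat_meiosis = as.integer(2L * nonf_rank - 1L),
    mat_meiosis = as.integer(2L * nonf_rank),
    n_meioses = 2L * sum(!founder)
  ), class = "pedigree")
  .check_no_inbreeding(ped)
  ped
}

# Kahn topological sort; errors on cycles.
.topo_order <- function(id, sire, dam) {
  n <- length(id)
  si <- match(sire, id)
  di <- match(dam, id)
  indeg <- integer(n)
  for (i in seq_len(n)) {
    if (!is.na(si[i])) indeg[i] <- indeg[i] + 1L
    if (!is.na(di[i])) indeg[i] <- indeg[i] + 1L
  }
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != n) stop("cycle detected in pedigree")
  out
}

.check_no_inbreeding <- function(ped) {
  for (i in which(!ped$founder)) {
    anc_s <- c(ped$sire[i], .ancestor_set(ped, ped$sire[i]))
    anc_d <- c(ped$dam[i], .ancestor_set(ped, ped$dam[i]))
    if (length(intersect(anc_s, anc_d))) {
      stop("inbreeding loop: parents of '", ped$id[i],
           "' share a common ancestor; inbred pedigrees are not supported")
    }
  }
  invisible(ped)
}

# integer indices of all ancestors of individual index i
.ancestor_set <- function(ped, i) {
  out <- integer(0)
  stack <- c(ped$sire[i], ped$dam[i])
  stack <- stack[!is.na(stack)]
  while (length(stack)) {
    v <- stack[1L]; stack <- stack[-1L]
    if (v %in% out) next
    out <- c(out, v)
    more <- c(ped$sire[v], ped$dam[v])
    stack <- c(stack, more[!is.na(more)])
  }
  out
}

.descendant_set <- function(ped, i) {
  n <- length(ped$id)
  children <- vector("list", n)
  for (j in seq_len(n)) {
    for (p in c(ped$sire[j], ped$dam[j])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], j)
    }
  }
  out <- integer(0)
  stack <- children[[i]]
  while (length(stack)) {
    v <- stack[1L]; stack <- stack[-1L]
    if (v %in% out) next
    out <- c(out, v)
    stack <- c(stack, children[[v]])
  }
  out
}

#' Read a pedigree from a PED file
#'
#' Reads the standard 6-column whitespace-delimited PED format
#' (family, individual, sire, dam, sex, phenotype); `"0"` denotes an absent
#' parent. Sex codes 1/2 are mapped to male/female, anything else to unknown.
#' The returned individuals are in topological order.
#'
#' @param path path to a PED file.
#' @return A [pedigree] object.
#' @export
read_pedigree <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 4L) stop("PED file must have at least 4 columns")
  sex <- if (ncol(tab) >= 5L) {
    c("1" = "male", "2" = "female")[tab[[5L]]]
  } else NULL
  if (!is.null(sex)) sex[is.na(sex)] <- "unknown"
  pedigree(tab[[2L]], tab[[3L]], tab[[4L]], sex)
}

#' @export
print.pedigree <- function(x, ...) {
  cat("pedigree: ", length(x$id), " individuals (",
      sum(x$founder), " founders), ", x$n_meioses, " meioses\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.pedigree <- function(x, ...) {
  data.frame(id = x$id,
             sire = ifelse(is.na(x$sire), NA_character_, x$id[x$sire]),
             dam = ifelse(is.na(x$dam), NA_character_, x$id[x$dam]),
             sex = x$sex, founder = x$founder,
             stringsAsFactors = FALSE)
}

#' Number of meioses in a pedigree
#' @param ped a [pedigree].
#' @return Integer, `2 * (number of non-founders)`.
#' @export
n_meioses <- function(ped) ped$n_meioses

#' Founder ids of a pedigree
#' @param ped a [pedigree].
#' @return Character vector of founder ids.
#' @export
founders <- function(ped) ped$id[ped$founder]

#' Childless individuals of a pedigree
#' @param ped a [pedigree].
#' @return Character vector of ids with no offspring in the pedigree.
#' @export
childless <- function(ped) {
  has_child <- ped$id %in% ped$id[stats::na.omit(c(ped$sire, ped$dam))]
  ped$id[!has_child]
}

#' Classify the relationship between two pedigree members
#'
#' Returns the structural relationship classes that apply to an (unordered)
#' pair: `parent_offspring`, `full_sibling`, `half_sibling`,
#' `grandparent_grandchild`, `avuncular`, `half_avuncular`, `cousin`,
#' `half_cousin`, plus `related` whenever the pair shares genetic material at
#' all, or `unrelated`. A pair may carry several classes (common in breeding
#' colonies where one sire has offspring with several dams).
#'
#' @param ped a [pedigree].
#' @param a,b individual ids.
#' @return Character vector of relationship class labels.
#' @export
relationship_classes <- function(ped, a, b) {
  i <- match(a, ped$id); j <- match(b, ped$id)
  if (is.na(i) || is.na(j)) stop("unknown individual id")
  if (i == j) return("self")
  out <- character(0)
  parents <- function(k) stats::na.omit(c(ped$sire[k], ped$dam[k]))
  shared <- intersect(parents(i), parents(j))
  if (i %in% parents(j) || j %in% parents(i)) out <- c(out, "parent_offspring")
  if (length(shared) == 2L) out <- c(out, "full_sibling")
  if (length(shared) == 1L &&
      length(parents(i)) == 2L && length(parents(j)) == 2L) {
    out <- c(out, "half_sibling")
  }
  gp <- function(k) unique(unlist(lapply(parents(k), parents)))
  if (i %in% gp(j) || j %in% gp(i)) out <- c(out, "grandparent_grandchild")
  # (half-)avuncular: one is a (half-)sibling of the other's parent
  sib_class <- function(u, v) {
    s <- intersect(parents(u), parents(v))
    if (length(s) == 2L) "full" else if (length(s) == 1L) "half" else NA
  }
  for (pr in list(c(i, j), c(j, i))) {
    for (par in parents(pr[2L])) {
      cl <- sib_class(pr[1L], par)
      if (identical(cl, "full")) out <- c(out, "avuncular")
      if (identical(cl, "half")) out <- c(out, "half_avuncular")
    }
  }
  # (half-)cousin: a parent of each are (half-)siblings
  for (pi in parents(i)) {
    for (pj in parents(j)) {
      cl <- sib_class(pi, pj)
      if (identical(cl, "full")) out <- c(out, "cousin")
      if (identical(cl, "half")) out <- c(out, "half_cousin")
    }
  }
  related <- length(intersect(c(i, .ancestor_set(ped, i)),
                              c(j, .ancestor_set(ped, j)))) > 0
  out <- unique(out)
  if (related) c(out, "related") else "unrelated"
}

# 0-based arrays handed to the compiled core.
.ped_c <- function(ped) {
  list(sire = as.integer(ifelse(is.na(ped$sire), -1L, ped$sire - 1L)),
       dam = as.integer(ifelse(is.na(ped$dam), -1L, ped$dam - 1L)),
       frank = as.integer(ifelse(is.na(ped$founder_rank), -1L,
                                 ped$founder_rank - 1L)),
       patm = as.integer(ifelse(is.na(ped$pat_meiosis), -1L,
                                ped$pat_meiosis - 1L)),
       matm = as.integer(ifelse(is.na(ped$mat_meiosis), -1L,
                                ped$mat_meiosis - 1L)))
}

# Human-readable founder-gene labels "F:1", "F:2" in gene-id order.
.gene_labels <- function(ped) {
  f <- founders(ped)
  as.vector(rbind(paste0(f, ":1"), paste0(f, ":2")))
}
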