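test_that("scan_sites places cuts at motif start + offset", {
  pst <- gbs_enzymes("PstI")
  expect_equal(scan_sites("AAAACTGCAGAAAA", pst), 9L)
  # IUPAC degeneracy: ApeKI's W matches A and T; the overlapping middle
  # occurrence is reported too
  apek <- gbs_enzymes("ApeKI")
  expect_equal(scan_sites("GCAGCAGCTGC", apek), c(1L, 4L, 7L))
  # case-insensitive; N never matches
  expect_equal(scan_sites("aaaactgcagaaaa", pst), 9L)
  expect_equal(length(scan_sites("AAAACTGCNGAAAA", pst)), 0L)
  expect_error(restriction_enzyme("bad", "CTGXAG", 1), "invalid IUPAC")
})

test_that("scan_sites equals the naive oracle on random sequences", {
  set.seed(31)
  for (enz in list(gbs_enzymes("PstI"), gbs_enzymes("ApeKI"),
                   restriction_enzyme("nonpal", "GACGTG", 2))) {
    seq <- paste(sample(c("A", "C", "G", "T", "N"), 100000,
                        replace = TRUE, prob = c(rep(0.2475, 4), 0.01)),
                 collapse = "")
    expect_equal(scan_sites(seq, enz), oracle_scan(seq, enz),
                 info = enz$name)
  }
})

test_that("digest fragments tile each contig exactly", {
  pst <- gbs_enzymes("PstI")
  f <- digest_genome(c(c1 = strrep("A", 100)), pst)
  expect_equal(nrow(f), 1L)
  expect_equal(f$length, 100L)

  seq2 <- paste0(strrep("A", 50), "CTGCAG", strrep("G", 40), "CTGCAG",
                 strrep("T", 30))
  f2 <- digest_genome(c(c1 = seq2), pst)
  expect_equal(nrow(f2), 3L)
  expect_equal(sum(f2$length), nchar(seq2))
  expect_equal(f2$start[-1], f2$end[-3])  # disjoint, tiling
  expect_error(digest_genome(character(0), pst), "empty FASTA")

  # invariance to contig order
  both <- digest_genome(c(a = seq2, b = strrep("A", 100)), pst)
  swapped <- digest_genome(c(b = strrep("A", 100), a = seq2), pst)
  expect_equal(nrow(size_select(both, 10, 60)),
               nrow(size_select(swapped, 10, 60)))
})

test_that("size selection keeps the inclusive 200-500 bp window", {
  f <- data.frame(contig = "c", start = 0, end = 1,
                  length = c(100, 200, 350, 500, 501), masked_fraction = 0)
  expect_equal(size_select(f)$length, c(200, 350, 500))
  expect_equal(nrow(size_select(f[0, ])), 0L)
  expect_error(size_select(f, 300, 200), "must not exceed")
  set.seed(8)
  f2 <- data.frame(contig = "c", start = 0, end = 1,
                   length = sample(1:1000, 500, TRUE), masked_fraction = 0)
  expect_equal(nrow(size_select(f2)),
               sum(f2$length >= 200 & f2$length <= 500))
})

test_that("mask filter drops repeat-heavy fragments at the threshold", {
  f <- data.frame(contig = "c", start = 0, end = 1, length = 100,
                  masked_fraction = c(0, 0.5, 0.51, 1))
  expect_equal(mask_filter(f)$masked_fraction, c(0, 0.5))
  expect_equal(nrow(mask_filter(f, 0.99)), 3L)  # fully-masked removed
  expect_equal(nrow(mask_filter(f, 1)), 4L)     # fully-unmasked kept always
})

test_that("masked fractions match per-base lowercase counts", {
  pst <- gbs_enzymes("PstI")
  sg <- synth_genome(6000, pst, n_sites = 4,
                     repeat_blocks = list(c(100, 400), c(2000, 2600)),
                     seed = 21)
  frags <- digest_genome(sg$seq, pst)
  s <- strsplit(sg$seq[[1]], "")[[1]]
  for (r in seq_len(nrow(frags))) {
    expected <- mean(s[(frags$start[r] + 1):frags$end[r]] %in% letters)
    expect_equal(frags$masked_fraction[r], expected)
  }
})

test_that("enzyme ranking prefers the target window, then captured bp", {
  mk <- function(enz, n, bp) {
    data.frame(enzyme = enz, n_fragments_total = n * 2, n_in_size_range = n,
               bp_in_range = bp, genome_fraction = bp / 3e9)
  }
  r <- rank_enzymes(rbind(mk("a", 80000, 5e6), mk("b", 20000, 9e6)))
  expect_equal(r$enzyme, c("a", "b"))
  r <- rank_enzymes(rbind(mk("lowbp", 70000, 4e6), mk("highbp", 90000, 9e6)))
  expect_equal(r$enzyme, c("highbp", "lowbp"))
  r <- rank_enzymes(rbind(mk("far", 150000, 9e6), mk("near", 110000, 1e6)))
  expect_equal(r$enzyme, c("near", "far"))
  expect_equal(rank_enzymes(mk("solo", 1, 1))$enzyme, "solo")
})

test_that("synthetic genomes contain exactly the planted sites", {
  pst <- gbs_enzymes("PstI")
  sg <- synth_genome(20000, pst, n_sites = 50, seed = 3)
  expect_equal(length(sg$cut_positions), 50L)
  expect_equal(sg$cut_positions, sg$site_starts + pst$cut_offset)
  frags <- digest_genome(sg$seq, pst)
  expect_equal(nrow(frags), 51L)  # k cuts -> k + 1 fragments
  expect_equal(sum(frags$length), 20000L)
  expect_equal(scan_sites(sg$seq[[1]], pst), sg$cut_positions)
})
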