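test_that("VCF round trip preserves GT/DP/GQ on biallelic SNVs", {
  ped <- colony_pedigree()
  sim <- small_framework(ped, 60, seed = 11)
  g <- sim$g
  g$depth[] <- 15L + (seq_along(g$depth) %% 20L)
  g$gq[] <- 30L + (seq_along(g$gq) %% 60L)
  g$geno[1, 3] <- NA_integer_  # missing cell with recorded DP/GQ

  path <- withr::local_tempfile(fileext = ".vcf.gz")
  write_genotypes_vcf(g, path)
  g2 <- read_genotypes_vcf(path, pedigree = ped)
  expect_equal(g2$geno, g$geno, ignore_attr = TRUE)
  expect_equal(g2$depth, g$depth, ignore_attr = TRUE)
  expect_equal(g2$gq, g$gq, ignore_attr = TRUE)
  expect_equal(g2$markers$pos, g$markers$pos)
  expect_identical(g2$ids, g$ids)

  # write(read(write(x))) is byte-identical in the body records
  path2 <- withr::local_tempfile(fileext = ".vcf.gz")
  write_genotypes_vcf(g2, path2)
  body <- function(p) grep("^#", readLines(p), invert = TRUE, value = TRUE)
  expect_identical(body(path2), body(path))
})

test_that("multi-allelic and non-SNV records are skipped with a count", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Qual\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    "c1\t100\t.\tA\tG\t.\tPASS\t.\tGT:DP:GQ\t0/1:15:40\t0/0:20:50\t1/1:9:10",
    "c1\t200\t.\tA\tG,T\t.\tPASS\t.\tGT:DP:GQ\t0/1:15:40\t0/0:8:9\t1/2:9:9",
    "c1\t300\t.\tAT\tA\t.\tPASS\t.\tGT:DP:GQ\t0/1:15:40\t0/0:8:9\t1/1:9:9"
  ), path)
  expect_message(g <- read_genotypes_vcf(path), "2 multi-allelic")
  expect_equal(attr(g, "n_skipped"), 2L)
  expect_equal(nrow(g$markers), 1L)
  expect_equal(unname(g$geno[, 1]), c(1L, 0L, 2L))
  expect_equal(unname(g$depth[, 1]), c(15, 20, 9))
  expect_equal(unname(g$gq[, 1]), c(40, 50, 10))
})

test_that("mendelian_errors flags impossible trios and duos only", {
  ped <- pedigree(c("F1", "M1", "C1"), c(NA, NA, "F1"), c(NA, NA, "M1"))
  mk <- data.frame(chrom = "c1", pos = 1:3 * 100, ref = "A", alt = "G")
  gm <- function(f, m, c) {
    genotype_matrix(c("F1", "M1", "C1"), mk, rbind(f, m, c))
  }
  # hom-ref x hom-ref cannot produce a het child; hom-alt mother forces
  # at least one alt copy in the child
  v <- mendelian_errors(ped, gm(c(0, 1, 0), c(0, 1, 2), c(1, 0, 0)))
  expect_equal(v$marker, c(1L, 3L))
  # het x het parents allow all child dosages
  v <- mendelian_errors(ped, gm(c(1, 1, 1), c(1, 1, 1), c(0, 1, 2)))
  expect_equal(nrow(v), 0L)
  # missing genotypes never trigger violations; duo rule applies
  v <- mendelian_errors(ped, gm(c(0, NA, 2), c(NA, NA, NA), c(2, 1, 0)))
  expect_equal(v$marker, c(1L, 3L))
  expect_error(mendelian_errors(
    ped, genotype_matrix(c("F1", "ZZ"), mk, matrix(0L, 2, 3))),
    "absent from pedigree")
})

test_that("violation counts match the exhaustive 27-combination oracle", {
  ped <- pedigree(c("F1", "M1", "C1"), c(NA, NA, "F1"), c(NA, NA, "M1"))
  combos <- expand.grid(f = 0:2, m = 0:2, c = 0:2)
  mk <- data.frame(chrom = "c1", pos = seq_len(nrow(combos)) * 10,
                   ref = "A", alt = "G")
  g <- genotype_matrix(c("F1", "M1", "C1"), mk,
                       rbind(combos$f, combos$m, combos$c))
  v <- mendelian_errors(ped, g)
  expected <- which(!mapply(oracle_trio_possible,
                            combos$f, combos$m, combos$c))
  expect_equal(sort(v$marker), expected)
})

test_that("gene-dropped error-free genotypes are Mendelian-consistent", {
  ped <- colony_pedigree()
  sim <- small_framework(ped, 120, seed = 5)
  expect_equal(nrow(mendelian_errors(ped, sim$g)), 0L)
})
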