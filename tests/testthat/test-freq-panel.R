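test_that("a well-formed panel file parses with ancestry order preserved", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "id\tchrom\tpos\tcounted_allele\tother_allele\tzulu\talpha",
    "rs1\t1\t100\tA\tC\t0.25\t0.75",
    "rs2\t2\t200\tG\tT\t0.10\t0.90"), tf)
  p <- read_frequency_panel(tf)
  expect_s3_class(p, "freq_panel")
  expect_equal(panel_ancestries(p), c("zulu", "alpha"))  # file order, not sorted
  fm <- panel_freq_matrix(p)
  expect_equal(dim(fm), c(2L, 2L))
  expect_equal(unname(fm["zulu", ]), c(0.25, 0.10))
})

test_that("panel validation errors name the offending line", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "id\tchrom\tpos\tcounted_allele\tother_allele\tanc1",
    "rs1\t1\t100\tA\tC\t0.5",
    "rs2\t1\t200\tA\tC\t1.3"), tf)
  expect_error(read_frequency_panel(tf), "line 2.*frequency outside")

  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "id\tchrom\tpos\tcounted_allele\tother_allele\tanc1",
    "rs1\t1\t100\tA\tC\t0.5",
    "rs1\t1\t200\tA\tC\t0.4"), tf2)
  expect_error(read_frequency_panel(tf2), "line 2.*duplicate marker id")

  tf3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "id\tchrom\tpos\tcounted_allele\tother_allele\tanc1",
    "rs1\t1\t100\tA\tA\t0.5"), tf3)
  expect_error(read_frequency_panel(tf3), "line 1.*alleles")
})

test_that("a simulated 21-ancestry panel round-trips through TSV", {
  panel <- simulate_panel(K = 21, M = 1000, fst = 0.1, seed = 42)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_frequency_panel(panel, tf)
  back <- read_frequency_panel(tf)
  expect_equal(panel_ancestries(back), panel_ancestries(panel))
  expect_equal(panel_freq_matrix(back), panel_freq_matrix(panel),
               tolerance = 1e-6)
  expect_equal(back$id, panel$id)
  expect_equal(back$pos, panel$pos)
})

test_that("VCF GT fields map to dosages, missing codes and ploidy flags", {
  tf <- withr::local_tempfile(fileext = ".vcf")
  mk <- data.frame(chrom = "1", pos = c(100, 200, 300),
                   id = c("s1", "s2", "s3"), ref = "A", alt = "G")
  gt <- rbind(c("0/1", "./.", "1"),
              c("1|1", "0/0", "0"),
              c("0/0", "1/1", "."))
  write_vcf_text(tf, mk, gt, c("dip1", "dip2", "hap1"))
  gm <- read_genotypes_vcf(tf)
  expect_equal(unname(gm$dosages["dip1", ]), c(1, 2, 0))
  expect_equal(unname(gm$dosages["dip2", ]), c(NA, 0, 2))
  expect_equal(unname(gm$dosages["hap1", ]), c(2, 0, NA))
  expect_equal(unname(gm$ploidy),
               c("diploid", "diploid", "pseudo_haploid"))
})

test_that("multi-allelic records are skipped with a warning", {
  tf <- withr::local_tempfile(fileext = ".vcf")
  mk <- data.frame(chrom = "1", pos = c(100, 200), id = c("s1", "s2"),
                   ref = "A", alt = c("G", "G,T"))
  gt <- rbind(c("0/1"), c("1/2"))
  write_vcf_text(tf, mk, gt, "ind1")
  expect_warning(gm <- read_genotypes_vcf(tf), "multi-allelic")
  expect_equal(ncol(gm$dosages), 1L)
  expect_equal(gm$markers$id, "s1")
})

test_that("simulator-written VCF reads back to the simulated dosage matrix", {
  panel <- simulate_panel(K = 2, M = 5, fst = 0.2, seed = 5)
  ts <- simulate_individuals(panel, 3, dirichlet_alpha = c(1, 1),
                             missing_rate = 0.2, seed = 6)
  tf <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes_vcf(ts$genotypes, tf)
  gm <- read_genotypes_vcf(tf)
  expect_equal(gm$dosages, ts$genotypes$dosages)
  expect_equal(gm$markers$pos, ts$genotypes$markers$pos)
})
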