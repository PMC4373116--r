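test_that("phased VCF reads into a haplotype panel, two rows per sample", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_mini_vcf(f, matrix(c("0|1", "1|1"), nrow = 1))
  panel <- read_haplotypes_vcf(f)
  expect_equal(dim(panel), c(4L, 1L))
  expect_equal(unname(panel$alleles[, 1]), c(0L, 1L, 1L, 1L))
  expect_equal(panel$snp_ids, "rs1")
})

test_that("unphased or missing GT is rejected with a clear error", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_mini_vcf(f, matrix(c("0|1", "0/1"), nrow = 1))
  expect_error(read_haplotypes_vcf(f), "unphased")
  write_mini_vcf(f, matrix(c("0|1", ".|."), nrow = 1))
  expect_error(read_haplotypes_vcf(f), "missing|invalid")
})

test_that("header-only VCF yields an empty panel without error", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "S1"), collapse = "\t")), f)
  expect_equal(dim(suppressWarnings(read_haplotypes_vcf(f))), c(0L, 0L))
})

test_that("multi-allelic records are rejected", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "S1"), collapse = "\t"),
               paste(c("1", "100", "rs1", "A", "G,T", ".", "PASS", ".", "GT",
                       "0|1"), collapse = "\t")), f)
  expect_error(read_haplotypes_vcf(f), "multi-allelic")
})

test_that("VCF genotypes sum GT alleles to additive coding", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_mini_vcf(f, matrix(c("0|1", "1/1", "0/0"), nrow = 1))
  G <- read_genotypes(f, "vcf")
  expect_equal(unname(G$genotypes[, 1]), c(1L, 2L, 0L))
})

test_that("TSV genotype entries outside 0/1/2 are rejected with location", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsA\trsB", "0\t1", "2\t3"), f)
  expect_error(read_genotypes(f, "tsv"), "row 2.*rsB")
})

test_that("genotype TSV round-trips through write+read unchanged", {
  G <- genotype_matrix(matrix(c(0, 1, 2, 2, 0, 1), 2, 3), c("a", "b", "c"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes_tsv(G, f)
  G2 <- read_genotypes(f, "tsv")
  expect_equal(G2$genotypes, G$genotypes)
  expect_equal(G2$snp_ids, G$snp_ids)
})

test_that("VCF -> panel -> VCF round trip preserves the allele matrix", {
  set.seed(5)
  panel <- haplotype_panel(matrix(rbinom(40, 1, 0.4), 8, 5))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_haplotypes_vcf(panel, f)
  back <- read_haplotypes_vcf(f)
  expect_equal(back$alleles, panel$alleles)
  expect_equal(back$snp_ids, panel$snp_ids)
})

test_that("summing haplotype pairs equals the VCF genotype reader", {
  set.seed(6)
  panel <- haplotype_panel(matrix(rbinom(60, 1, 0.5), 10, 6))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_haplotypes_vcf(panel, f)
  expect_equal(panel_to_genotypes(panel)$genotypes,
               read_genotypes(f, "vcf")$genotypes)
})

test_that("tag-set TSV writes, round-trips, and validates indices", {
  ts <- list(tags = 1L, clusters = list(c(1L, 2L)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tagset(ts, c("rsA", "rsB"), f)
  expect_equal(readLines(f), c("tag_snp_id\tcluster_members", "rsA\trsA,rsB"))
  back <- read_tagset(f, c("rsA", "rsB"))
  expect_equal(back$tags, 1L)
  expect_equal(back$clusters, list(c(1L, 2L)))

  write_tagset(list(tags = integer(0), clusters = list()), c("rsA"), f)
  expect_equal(readLines(f), "tag_snp_id\tcluster_members")

  expect_error(write_tagset(list(tags = 3L, clusters = list(3L)),
                            c("rsA", "rsB"), f), "out of range")
})

test_that("phenotype TSV reader returns classes and covariates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\ty\tage", "s1\t1\t30", "s2\t0\t40", "s3\t1\t50"), f)
  ph <- read_phenotype_tsv(f)
  expect_s3_class(ph, "phenotype")
  expect_equal(unname(ph$y), c(1L, 0L, 1L))
  expect_equal(ph$covariates[, "age"], c(30, 40, 50))
})

test_that("type constructors enforce their invariants", {
  expect_error(haplotype_panel(matrix(0:1, 3, 2)), "even")
  expect_error(haplotype_panel(matrix(2, 2, 1)), "0 or 1")
  expect_error(haplotype_panel(matrix(0:1, 2, 2), snp_ids = c("a", "a")), "unique")
  expect_error(genotype_matrix(matrix(3, 1, 1)), "0, 1 or 2")
  expect_error(phenotype(rep(1, 4)), "at least one case and one control")
})

test_that("polarize_minor flips majority-ALT columns and leaves r2 unchanged", {
  set.seed(9)
  a <- cbind(rbinom(20, 1, 0.8), rbinom(20, 1, 0.3))
  panel <- haplotype_panel(a)
  flipped <- polarize_minor(panel)
  expect_equal(attr(flipped, "flipped"), 1L)
  expect_true(all(colMeans(flipped$alleles) <= 0.5))
  expect_equal(ld_r2_matrix(flipped), ld_r2_matrix(panel))

  G <- genotype_matrix(matrix(c(2, 2, 1, 0, 0, 1), 3, 2))
  Gf <- polarize_minor(G)
  expect_equal(unname(Gf$genotypes[, 1]), c(0L, 0L, 1L))
})
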