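test_that("bit-packed storage round-trips every genotype state", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(1:37, 1)
    p <- sample(1:9, 1)
    g <- matrix(sample(c(0:2, NA), n * p, replace = TRUE), n, p)
    gm <- genotype_matrix(g)
    expect_identical(unname(geno(gm)), matrix(as.integer(g), n, p))
  }
})

test_that("packed payload is 2 bits per genotype", {
  expect_equal(packed_size_bytes(1000, 1e6), 250e6)
  expect_equal(packed_size_bytes(8, 1), 2)
  expect_equal(packed_size_bytes(5, 3), 2 * 3 * 1)
  expect_error(packed_size_bytes(0, 10), class = "treemwu_format_error")
  g <- matrix(0L, 13, 4)
  gm <- genotype_matrix(g)
  expect_equal(length(gm$bits1) + length(gm$bits2),
               packed_size_bytes(13, 4))
})

write_toy_plink <- function(prefix, bed_bytes, n_subj, phenos,
                            n_snp = 1L) {
  writeBin(c(as.raw(c(0x6c, 0x1b, 0x01)), as.raw(bed_bytes)),
           paste0(prefix, ".bed"))
  writeLines(paste(1L, paste0("rs", seq_len(n_snp)), 0L, seq_len(n_snp),
                   "A", "B"), paste0(prefix, ".bim"))
  writeLines(paste(seq_len(n_subj), paste0("I", seq_len(n_subj)),
                   0L, 0L, 0L, phenos), paste0(prefix, ".fam"))
  prefix
}

test_that(".bed 2-bit fields decode low-order first, missing as 01", {
  # byte 0b01101100: fields (low to high) 00, 11, 10, 01 -> 2, 0, 1, NA
  prefix <- write_toy_plink(tempfile(), 0x6c, 4L, c(2L, 1L, 2L, 1L))
  dat <- read_plink(prefix, recode_minor = FALSE)
  expect_equal(unname(geno(dat$genotypes)[, 1]), c(2L, 0L, 1L, NA))
  expect_equal(dat$phenotype$n_case, 2L)
  expect_equal(dat$phenotype$n_control, 2L)
  expect_equal(dat$phenotype$status, c(1L, 0L, 1L, 0L))
})

test_that(".bed header and mode bytes are enforced", {
  bad <- tempfile()
  writeBin(as.raw(c(0x6c, 0x00, 0x01, 0x00)), paste0(bad, ".bed"))
  writeLines("1 rs1 0 1 A B", paste0(bad, ".bim"))
  writeLines("1 I1 0 0 0 2", paste0(bad, ".fam"))
  expect_error(read_plink(bad), class = "treemwu_format_error")

  indmajor <- tempfile()
  writeBin(as.raw(c(0x6c, 0x1b, 0x00, 0x00)), paste0(indmajor, ".bed"))
  writeLines("1 rs1 0 1 A B", paste0(indmajor, ".bim"))
  writeLines("1 I1 0 0 0 2", paste0(indmajor, ".fam"))
  expect_error(read_plink(indmajor), "individual-major",
               class = "treemwu_format_error")
})

test_that("invalid .fam phenotypes exclude the subject with a warning", {
  # 4 subjects in one byte, phenotypes 2, -9, 1, 0 -> keep subjects 1 and 3
  prefix <- write_toy_plink(tempfile(), 0x6c, 4L, c(2L, -9L, 1L, 0L))
  expect_warning(dat <- read_plink(prefix, recode_minor = FALSE),
                 "excluding 2 subject")
  expect_equal(dat$genotypes$n_subjects, 2L)
  expect_equal(unname(geno(dat$genotypes)[, 1]), c(2L, 1L))
  expect_equal(dat$phenotype$status, c(1L, 0L))
})

test_that("written filesets have the documented sizes and round-trip", {
  pre1 <- tempfile()
  write_plink(genotype_matrix(matrix(1L, 1, 1)), 1L, pre1)
  expect_equal(file.size(paste0(pre1, ".bed")), 4)  # 3 header + 1 data byte

  gm5 <- genotype_matrix(matrix(sample(c(0:2, NA), 15, TRUE), 5, 3))
  pre5 <- tempfile()
  write_plink(gm5, phenotype(c(1L, 1L, 0L, 0L, 1L)), pre5)
  expect_equal(file.size(paste0(pre5, ".bed")), 3 + 2 * 3)  # ceil(5/4) = 2

  set.seed(7)
  g <- matrix(sample(c(0:2, NA), 23 * 6, TRUE,
                     prob = c(0.45, 0.3, 0.2, 0.05)), 23, 6)
  gm <- genotype_matrix(g)
  ph <- phenotype(sample(rep_len(0:1, 23)))
  pre <- tempfile()
  write_plink(gm, ph, pre)
  back <- read_plink(pre, recode_minor = FALSE)  # raw A1-count identity
  expect_identical(geno(back$genotypes), geno(gm))
  expect_identical(back$phenotype$status, ph$status)
  pre2 <- tempfile()
  write_plink(back$genotypes, back$phenotype, pre2)
  expect_identical(readBin(paste0(pre, ".bed"), "raw", 1e4),
                   readBin(paste0(pre2, ".bed"), "raw", 1e4))
})

test_that("minor-allele recoding flips majority-A1 SNPs and swaps labels", {
  # SNP counts A1 at freq 5/6 > 0.5 -> flipped to minor counts
  g <- matrix(c(2L, 2L, 1L), 3, 1)
  gm <- genotype_matrix(g, a1 = "C", a2 = "G",
                        map = data.frame(chr = 1, id = "SNP1", cm = 0,
                                         pos = 1, a1 = "C", a2 = "G"))
  pre <- tempfile()
  write_plink(gm, phenotype(c(1L, 0L, 1L)), pre)
  dat <- read_plink(pre)
  expect_equal(unname(geno(dat$genotypes)[, 1]), c(0L, 0L, 1L))
  expect_equal(dat$genotypes$a1, "G")
  raw <- read_plink(pre, recode_minor = FALSE)
  expect_equal(unname(geno(raw$genotypes)[, 1]), c(2L, 2L, 1L))
})

test_that("text dialect reads toy data, missing codes and errors", {
  f <- tempfile()
  writeLines(c("F1 I1 2 0 1",
               "F2 I2 1 NA 2",
               "F3 I3 2 1 0"), f)
  dat <- read_geno_text(f)
  expect_equal(dat$genotypes$n_subjects, 3L)
  expect_equal(dat$genotypes$n_snps, 2L)
  expect_equal(unname(geno(dat$genotypes)),
               matrix(c(0L, NA, 1L, 1L, 2L, 0L), 3, 2))
  expect_equal(dat$phenotype$status, c(1L, 0L, 1L))

  fm <- tempfile()
  writeLines(c("F1 I1 2 0 -1", "F2 I2 1 1 2"), fm)
  datm <- read_geno_text(fm, missing_code = "-1")
  expect_true(is.na(geno(datm$genotypes)[1, 2]))

  ragged <- tempfile()
  writeLines(c("F1 I1 2 0 1", "F2 I2 1 0"), ragged)
  expect_error(read_geno_text(ragged), "row 2",
               class = "treemwu_format_error")

  badtok <- tempfile()
  writeLines(c("F1 I1 2 0 7"), badtok)
  expect_error(read_geno_text(badtok), "\"7\"",
               class = "treemwu_format_error")
})

test_that("text and binary readers agree on the same underlying data", {
  set.seed(21)
  g <- matrix(sample(c(0:2, NA), 30 * 5, TRUE, prob = c(0.5, 0.3, 0.15, 0.05)),
              30, 5)
  gm <- genotype_matrix(g)
  ph <- phenotype(sample(rep_len(0:1, 30)))
  pre <- tempfile()
  txt <- tempfile()
  write_plink(gm, ph, pre)
  write_geno_text(gm, ph, txt)
  from_bed <- read_plink(pre, recode_minor = FALSE)
  from_txt <- read_geno_text(txt)
  expect_identical(unname(geno(from_bed$genotypes)),
                   unname(geno(from_txt$genotypes)))
  expect_identical(from_bed$phenotype$status, from_txt$phenotype$status)
})
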