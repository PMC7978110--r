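test_that("PLINK write -> read round-trip is lossless", {
  panel <- panel_2chr()
  g <- panel$genotypes
  g[5, 3] <- NA  # inject missingness
  panel2 <- genotype_panel(g, snp_ids = panel$snp_ids,
                           chromosomes = panel$chromosomes,
                           positions = panel$positions,
                           sample_ids = panel$sample_ids)
  prefix <- file.path(withr::local_tempdir(), "rt")
  write_plink(panel2, prefix)
  back <- read_plink(prefix)
  expect_identical(unname(back$genotypes), unname(panel2$genotypes))
  expect_identical(back$snp_ids, panel2$snp_ids)
  expect_identical(back$chromosomes, panel2$chromosomes)
  expect_identical(back$sample_ids, panel2$sample_ids)
})

test_that("bed files with bad magic or truncated payload are rejected", {
  prefix <- file.path(withr::local_tempdir(), "bad")
  write_plink(panel_2chr(), prefix)
  raw <- readBin(paste0(prefix, ".bed"), "raw", file.size(paste0(prefix, ".bed")))
  raw[1] <- as.raw(0x00)
  writeBin(raw, paste0(prefix, ".bed"))
  expect_error(read_plink(prefix), "magic")
  raw[1] <- as.raw(0x6c)
  writeBin(raw[-length(raw)], paste0(prefix, ".bed"))
  expect_error(read_plink(prefix), "corrupt")
  expect_error(read_plink(file.path(tempdir(), "nonexistent")), "missing")
})

test_that("hand-packed bed bytes decode to the hand-coded counts", {
  # 4 individuals x 3 SNPs, A1 counts per SNP:
  #   snp1: 2 1 0 NA -> codes 00 10 11 01 -> byte 0 + 4*2 + 16*3 + 64*1 = 120
  #   snp2: 0 0 1 2  -> codes 11 11 10 00 -> byte 3 + 4*3 + 16*2 + 64*0 = 47
  #   snp3: 1 1 2 0  -> codes 10 10 00 11 -> byte 2 + 4*2 + 16*0 + 64*3 = 202
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "hand")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 120, 47, 202)), paste0(prefix, ".bed"))
  writeLines(sprintf("f%d i%d 0 0 0 -9", 1:4, 1:4), paste0(prefix, ".fam"))
  writeLines(sprintf("1\tsnp%d\t0\t%d\tA\tC", 1:3, 1:3), paste0(prefix, ".bim"))
  panel <- read_plink(prefix)
  expected <- cbind(c(2L, 1L, 0L, NA), c(0L, 0L, 1L, 2L), c(1L, 1L, 2L, 0L))
  expect_identical(unname(panel$genotypes), expected)
})

test_that("filter_panel honors MAF threshold, regions and SNP lists", {
  g <- matrix(1L, 100, 10)
  g[, 1] <- c(1L, rep(0L, 99))               # p = 0.005: below MAF 0.01
  set.seed(9)
  for (j in 2:10) g[, j] <- rbinom(100, 2, 0.3)
  panel <- genotype_panel(g, chromosomes = rep("2", 10), positions = 1:10)

  expect_identical(dim(filter_panel(panel)), dim(panel))  # maf 0: identity
  f <- filter_panel(panel, maf_min = 0.01)
  expect_false("snp1" %in% f$snp_ids)
  expect_equal(ncol(f$genotypes), 9)

  f2 <- filter_panel(panel, exclude_regions = "2:4-6")   # 3 of 10 inside
  expect_equal(ncol(f2$genotypes), 7)
  expect_false(any(f2$positions %in% 4:6))

  f3 <- filter_panel(panel, exclude_snps = c("snp2", "snp3"))
  expect_equal(ncol(f3$genotypes), 8)

  # idempotence
  f4 <- filter_panel(f, maf_min = 0.01)
  expect_identical(f4$genotypes, f$genotypes)

  expect_error(filter_panel(panel, maf_min = 0.6), "maf_min")
  expect_error(filter_panel(panel, exclude_regions = "2:10"), "region")
})

test_that("phenotype tables round-trip and align to the panel", {
  panel <- panel_indep()
  y <- simulate_phenotype(panel, 0.3, seed = 61)
  path <- file.path(withr::local_tempdir(), "pheno.txt")
  write_pheno_table(panel, y, path)
  # shuffle rows to exercise IID matching
  lines <- readLines(path)
  writeLines(sample(lines), path)
  tab <- read_pheno_table(path, panel = panel)
  expect_equal(tab$V1, y, tolerance = 1e-10)
  expect_identical(tab$iid, panel$sample_ids)
})

test_that("GCTA GRM export writes the expected binary layout", {
  panel <- filter_panel(subset_panel(panel_indep(), individuals = 1:20,
                                     snps = 1:100), maf_min = 0)
  grm <- build_grm(panel)
  prefix <- file.path(withr::local_tempdir(), "gcta")
  write_gcta_grm(grm, panel, prefix)
  n <- 20
  vals <- readBin(paste0(prefix, ".grm.bin"), "numeric",
                  n = n * (n + 1) / 2, size = 4, endian = "little")
  # element order: lower triangle row-major including diagonal
  k <- 0
  for (i in 1:4) for (j in 1:i) {
    k <- k + 1
    expect_equal(vals[k], grm$values[i, j], tolerance = 1e-6)
  }
  ids <- read.table(paste0(prefix, ".grm.id"))
  expect_equal(nrow(ids), n)
})
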