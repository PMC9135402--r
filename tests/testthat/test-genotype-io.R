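test_that("VCF records convert to alternate-allele dosage with missing calls as NA", {
  path <- write_vcf_text(
    c("chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
      "chr1\t200\t.\tG\tC\t.\tPASS\t.\tGT\t./.\t0|1\t1/1"),
    c("s1", "s2", "s3")
  )
  gm <- read_vcf(path)
  expect_equal(unname(gm$calls[, 1]), c(0L, 1L, 2L))
  expect_equal(unname(gm$calls[, 2]), c(NA_integer_, 1L, 2L))
  expect_equal(gm$loci$position, c(100L, 200L))
  expect_equal(gm$samples$sample_id, c("s1", "s2", "s3"))
})

test_that("multiallelic and indel records are rejected, empty result errors", {
  path <- write_vcf_text(
    c("chr1\t100\t.\tA\tT,G\t.\tPASS\t.\tGT\t0/1\t0/0",
      "chr1\t150\t.\tAT\tA\t.\tPASS\t.\tGT\t0/1\t0/0",
      "chr1\t200\t.\tG\tC\t.\tPASS\t.\tGT\t0/0\t1/1"),
    c("s1", "s2")
  )
  expect_warning(gm <- read_vcf(path), "2 non-biallelic-SNP")
  expect_equal(ncol(gm$calls), 1L)

  only_tri <- write_vcf_text(
    "chr1\t100\t.\tA\tT,G\t.\tPASS\t.\tGT\t0/1\t0/0", c("s1", "s2"))
  expect_warning(expect_error(read_vcf(only_tri), "no biallelic SNP"))
})

test_that("write_vcf / read_vcf round-trip preserves the 012 matrix exactly", {
  set.seed(11)
  calls <- matrix(sample(c(0:2, NA), 60, replace = TRUE), nrow = 6)
  gm <- toy_gm(calls)
  path <- tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  back <- read_vcf(path)
  expect_identical(unname(back$calls), unname(gm$calls))
  expect_equal(back$loci$position, gm$loci$position)
})

test_that("site filters apply MAF and call-rate thresholds with inclusive boundaries", {
  # locus 1: one het among 10 samples -> MAF = 0.05, kept at the boundary
  # locus 2: MAF 0.25 but 2/10 missing -> call rate 0.8 < 0.85, removed
  # locus 3: monomorphic -> MAF 0, removed
  calls <- cbind(
    c(1L, rep(0L, 9)),
    c(1L, 1L, 1L, 2L, 0L, 0L, 0L, 0L, NA, NA),
    rep(0L, 10)
  )
  gm <- toy_gm(calls)
  kept <- filter_sites(gm, maf_min = 0.05, max_missing = 0.85)
  expect_equal(ncol(kept$calls), 1L)
  expect_equal(kept$loci$position, gm$loci$position[1])
  expect_error(filter_sites(gm, maf_min = 0.4), "all loci removed")
})

test_that("filtered locus set matches a direct allele-count oracle and is idempotent", {
  set.seed(42)
  calls <- matrix(sample(c(0:2, NA), 20 * 50, replace = TRUE,
                         prob = c(0.45, 0.3, 0.15, 0.1)), nrow = 20)
  gm <- toy_gm(calls)
  kept <- filter_sites(gm, maf_min = 0.2, max_missing = 0.8)

  oracle_keep <- vapply(seq_len(50), function(j) {
    g <- calls[, j]
    ok <- !is.na(g)
    if (mean(ok) < 0.8) return(FALSE)
    p <- sum(g[ok]) / (2 * sum(ok))
    min(p, 1 - p) >= 0.2
  }, logical(1))
  expect_equal(kept$loci$position, gm$loci$position[oracle_keep])

  twice <- filter_sites(kept, maf_min = 0.2, max_missing = 0.8)
  expect_identical(twice$calls, kept$calls)
})

test_that("mean-depth bounds filter when depth is present and warn when absent", {
  calls <- matrix(c(0L, 1L, 2L, 1L), 2, 2)
  depth <- matrix(c(3, 5, 50, 40), 2, 2)
  gm <- genotype_matrix(calls, depth = depth)
  kept <- filter_sites(gm, maf_min = 0, max_missing = 0, mean_dp_range = c(7, 100))
  expect_equal(ncol(kept$calls), 1L)
  gm2 <- genotype_matrix(calls)
  expect_warning(filter_sites(gm2, maf_min = 0, max_missing = 0,
                              mean_dp_range = c(7, 100)), "depth")
})

test_that("adaptive-locus selection partitions by source and mirrors the study counts", {
  m <- 380
  loci <- data.frame(
    scaffold = "sc1", position = seq_len(m), ref = "A", alt = "T",
    swept_in = "molluscivore",
    source = c(rep("SGV", 364), rep("introgression", 16)),
    fst = 1, stringsAsFactors = FALSE
  )
  calls <- matrix(0L, 2, m)
  gm <- toy_gm(calls, loci = loci)

  expect_length(select_adaptive_loci(gm, "molluscivore", "SGV"), 364)
  expect_length(select_adaptive_loci(gm, "molluscivore", "introgression"), 16)
  expect_length(
    select_adaptive_loci(gm, "molluscivore", c("SGV", "introgression", "de_novo")),
    380
  )
  # disjoint source counts sum to the union count
  expect_equal(
    length(select_adaptive_loci(gm, "molluscivore", "SGV")) +
      length(select_adaptive_loci(gm, "molluscivore", "introgression")),
    length(select_adaptive_loci(gm, "molluscivore", c("SGV", "introgression")))
  )
  expect_error(select_adaptive_loci(gm, "molluscivore", "de_novo"), "empty")
})

test_that("metadata invariants are enforced at construction", {
  calls <- matrix(0L, 2, 2)
  expect_error(
    genotype_matrix(calls, samples = data.frame(
      sample_id = c("a", "b"), species = "hybrid", lake = NA,
      experiment = "none", role = "hybrid")),
    "experiment"
  )
  loci <- default_loci <- data.frame(
    scaffold = "s", position = 1:2, ref = "A", alt = "T",
    swept_in = "molluscivore", source = "de_novo", fst = NA_real_)
  expect_error(genotype_matrix(calls, loci = loci), "de novo")
})
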