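test_that("QC rules apply strict thresholds in the stated order", {
  m <- toy_markers()
  res <- filter_markers(m)
  rep <- res$report

  # 0.85 missing removed, exactly 0.80 kept (strict inequality)
  expect_identical(rep$removed_missing, "m1")
  expect_true(all(c("m2", "m3", "m6") %in% colnames(res$markers)))
  # monomorphic marker removed by the MAF rule
  expect_identical(rep$removed_maf, "m4")
  # 15% heterozygotes with healthy MAF removed by the het rule
  expect_identical(rep$removed_het, "m5")
  expect_equal(rep$n_input_markers,
               rep$n_retained + rep$n_removed_missing +
                 rep$n_removed_maf + rep$n_removed_het)
})

test_that("the retained marker set is order independent", {
  m <- toy_markers()
  perm <- c(4, 2, 6, 1, 5, 3)
  r1 <- filter_markers(m)
  r2 <- filter_markers(m[, perm])
  expect_setequal(colnames(r1$markers), colnames(r2$markers))
})

test_that("rule attribution follows missing -> MAF -> het", {
  # a marker failing both missing and MAF is attributed to missing
  m <- toy_markers()
  m[3:20, 1] <- NA
  m[1:2, 1] <- 0  # all-zero calls: would also fail MAF
  rep <- filter_markers(m)$report
  expect_true("m1" %in% rep$removed_missing)
  expect_false("m1" %in% rep$removed_maf)
})

test_that("mean imputation fills exactly the missing cells", {
  m <- matrix(c(0, 2, NA,
                1, 1, 1,
                2, NA, NA), nrow = 3,
              dimnames = list(paste0("g", 1:3), paste0("m", 1:3)))
  out <- impute_mean(m)
  expect_equal(out["g3", "m1"], 1)       # mean of 0 and 2
  expect_equal(out[, "m2"], c(g1 = 1, g2 = 1, g3 = 1))
  expect_equal(out["g2", "m3"], 2)       # single non-missing call
  full <- matrix(0:5, 2)
  expect_identical(impute_mean(full), full)
  bad <- m; bad[, 2] <- NA
  expect_error(impute_mean(bad), "m2")
})

test_that("VanRaden G matches a brute-force double loop", {
  set.seed(4)
  m <- matrix(sample(0:2, 24, replace = TRUE), 4, 6,
              dimnames = list(paste0("g", 1:4), paste0("m", 1:6)))
  g <- as.matrix(vanraden_g(m))
  # independent entry-by-entry computation
  p <- colMeans(m) / 2
  denom <- 2 * sum(p * (1 - p))
  ref <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    s <- 0
    for (k in 1:6) s <- s + (m[i, k] - 2 * p[k]) * (m[j, k] - 2 * p[k])
    ref[i, j] <- s / denom
  }
  expect_lt(max(abs(g - ref)), 1e-12)
  expect_lt(max(abs(g - t(g))), 1e-15)
})

test_that("identical genotypes have off-diagonal equal to their diagonal", {
  set.seed(5)
  m <- matrix(sample(0:2, 30, replace = TRUE), 5, 6,
              dimnames = list(paste0("g", 1:5), paste0("m", 1:6)))
  m[2, ] <- m[1, ]
  g <- as.matrix(vanraden_g(m))
  expect_equal(g[1, 2], g[1, 1], tolerance = 1e-12)
  expect_equal(g[1, 2], g[2, 2], tolerance = 1e-12)
  expect_error(vanraden_g(matrix(2, 3, 4,
                                 dimnames = list(paste0("g", 1:3), NULL))),
               "monomorphic")
})

test_that("G is PSD and labels survive a disk round-trip", {
  s <- small_sim()
  m <- impute_mean(filter_markers(s$markers)$markers)
  g <- vanraden_g(m)
  ev <- eigen(as.matrix(g), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * max(ev))
  # mean diagonal near 1 for an unstructured outbred population (for the
  # simulator's inbred lines it sits near 1 + F instead)
  set.seed(10)
  p <- runif(400, 0.1, 0.5)
  hwe <- sapply(p, function(pp) rbinom(80, 1, pp) + rbinom(80, 1, pp))
  dimnames(hwe) <- list(paste0("g", 1:80), paste0("m", 1:400))
  g_hwe <- vanraden_g(hwe)
  expect_lt(abs(mean(diag(as.matrix(g_hwe))) - 1), 0.2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_kernel_tsv(g, path)
  g2 <- read_kernel_tsv(path)
  expect_identical(g2$labels, g$labels)
  expect_equal(as.matrix(g2), as.matrix(g), tolerance = 1e-9)
  expect_identical(g2$level, "genotype")
})

test_that("dosage matrices round-trip through TSV with NA markers", {
  m <- toy_markers()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dosage_tsv(m, path)
  expect_equal(read_dosage_tsv(path), m)
})

test_that("VCF genotypes map to minor-allele dosages", {
  skip_if_not_installed("vcfR")
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", "s4", sep = "\t"),
    paste("1", "100", "snp1", "A", "G", ".", ".", ".", "GT",
          "0/0", "0/1", "1/1", "./.", sep = "\t"),
    paste("1", "200", "snp2", "C", "T", ".", ".", ".", "GT",
          "1/1", "1/1", "1/1", "0/1", sep = "\t"))
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  d <- suppressMessages(read_vcf_dosage(path))
  expect_equal(d[, "snp1"], c(s1 = 0, s2 = 1, s3 = 2, s4 = NA))
  # snp2: ALT is the major allele, so dosages are folded to count REF
  expect_equal(d[, "snp2"], c(s1 = 0, s2 = 0, s3 = 0, s4 = 1))
})
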