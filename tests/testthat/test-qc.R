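test_that("exact HWE test matches closed-form enumeration and handles edges", {
  # perfect HWE proportions: observed het count is modal
  expect_equal(hwe_test(25, 50, 25), 1, tolerance = 1e-12)
  # total heterozygote deficit: far below the study threshold
  p_extreme <- hwe_test(100, 0, 100)
  expect_lt(p_extreme, 1e-6)
  expect_equal(p_extreme, hwe_enum_oracle(100, 0, 100), tolerance = 1e-10)
  # monomorphic
  expect_identical(hwe_test(0, 0, 50), 1.0)
  expect_identical(hwe_test(50, 0, 0), 1.0)
  # general agreement with the independent enumeration oracle
  cases <- list(c(30, 20, 10), c(5, 40, 55), c(88, 10, 2), c(1, 1, 98),
                c(12, 36, 27), c(0, 10, 90))
  for (cs in cases) {
    expect_equal(hwe_test(cs[1], cs[2], cs[3]),
                 hwe_enum_oracle(cs[1], cs[2], cs[3]), tolerance = 1e-9)
  }
  expect_error(hwe_test(-1, 5, 5), "non-negative")
  expect_error(hwe_test(0, 0, 0), "positive")
})

test_that("exact HWE p stays within a factor 3 of chi-square when cells are large", {
  cases <- list(c(120, 220, 110), c(300, 350, 150), c(80, 250, 170),
                c(200, 180, 60))
  for (cs in cases) {
    n <- sum(cs)
    p_hat <- (2 * cs[1] + cs[2]) / (2 * n)
    expected <- n * c(p_hat^2, 2 * p_hat * (1 - p_hat), (1 - p_hat)^2)
    expect_true(all(expected >= 20)) # cases built to respect the envelope
    chi <- sum((cs - expected)^2 / expected)
    p_asym <- pchisq(chi, df = 1, lower.tail = FALSE)
    p_exact <- hwe_test(cs[1], cs[2], cs[3])
    expect_lt(p_exact / p_asym, 3)
    expect_gt(p_exact / p_asym, 1 / 3)
  }
})

test_that("hand-built 10-SNP fixture yields the enumerated fates", {
  g <- hand_qc_fixture()
  out <- qc_filter(g, qc_thresholds())
  expect_identical(out$report$n_input, 10L)
  expect_identical(out$report$n_pass, 6L)
  expect_identical(out$genotypes$snps$id, paste0("s", 5:10))
  fr <- out$report$fail_reason
  expect_identical(unname(fr[paste0("s", 1:4)]),
                   c("info", "missingness", "maf", "hwe"))
  expect_true(all(is.na(fr[paste0("s", 5:10)])))
  expect_identical(unname(out$report$excluded),
                   c(1L, 1L, 1L, 1L)) # info, missingness, maf, hwe
  # uniquely-attributed exclusions + survivors = input SNPs
  expect_identical(sum(out$report$excluded) + out$report$n_pass,
                   out$report$n_input)
})

test_that("threshold edges follow the strict/non-strict contract", {
  g <- hand_qc_fixture()
  out <- qc_filter(g)
  st <- snp_stats(g)
  # MAF exactly 0.01 retained (failure requires strictly lower than 1%)
  expect_equal(st$maf[6], 0.01)
  expect_true("s6" %in% out$genotypes$snps$id)
  # missing rate exactly 3% retained (failure requires strictly larger)
  expect_equal(st$miss_rate[7], 0.03)
  expect_true("s7" %in% out$genotypes$snps$id)
  # 8% missing excluded
  expect_false("s2" %in% out$genotypes$snps$id)
  expect_error(qc_thresholds(min_maf = 0), "0, 1")
})

test_that("qc_filter is idempotent and order does not change survivors", {
  g <- random_geno(120, 150, seed = 8, miss_rate = 0.02)
  g$snps$info <- runif(150, 0.4, 1)
  once <- qc_filter(g)
  twice <- qc_filter(once$genotypes)
  expect_identical(twice$genotypes$snps$id, once$genotypes$snps$id)
  expect_identical(twice$report$n_pass, twice$report$n_input)
  # survivors are exactly the SNPs failing no filter, independent of the
  # attribution order
  st <- snp_stats(g)
  hw <- sapply(seq_len(ncol(g$X)), function(j) {
    x <- g$X[, j]
    hwe_test(sum(x == 2, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
             sum(x == 0, na.rm = TRUE))
  })
  th <- qc_thresholds()
  survive <- g$snps$info > th$min_info & st$miss_rate <= th$max_missing_rate &
    st$maf >= th$min_maf & hw >= th$hwe_p_floor
  expect_identical(once$genotypes$snps$id, g$snps$id[survive])
})

test_that("merge keeps the SNP intersection and rejects shared ids", {
  ga <- random_geno(30, 20, seed = 10)
  gb <- random_geno(25, 20, seed = 11)
  gb$fam$iid <- paste0("b", gb$fam$iid)
  gb$fam$fid <- paste0("b", gb$fam$fid)
  # drop some SNPs from each side
  ga2 <- gremlite:::subset_geno(ga, j = 1:15)
  gb2 <- gremlite:::subset_geno(gb, j = 6:20)
  out <- merge_cohorts(ga2, gb2, qc_thresholds(min_maf = 0.01))
  expect_true(all(out$genotypes$snps$id %in%
                    intersect(ga2$snps$id, gb2$snps$id)))
  expect_identical(attr(out$report, "n_intersection"), 10L)
  expect_identical(nrow(out$genotypes$X), 55L)
  expect_error(merge_cohorts(ga, ga), "disjoint")
})

test_that("swapped A1/A2 alleles are flipped so frequencies agree", {
  set.seed(12)
  Xa <- matrix(rbinom(40 * 6, 2, 0.3), 40, 6)
  Xb <- matrix(rbinom(40 * 6, 2, 0.3), 40, 6)
  ga <- make_geno(Xa, a1 = rep("A", 6), a2 = rep("G", 6))
  gb <- make_geno(2 - Xb, a1 = rep("G", 6), a2 = rep("A", 6)) # swapped
  gb$fam$iid <- paste0("b", gb$fam$iid)
  f_b_pre <- colMeans(gb$X) / 2
  out <- merge_cohorts(ga, gb, qc_thresholds())
  expect_identical(attr(out$report, "n_flipped"), 6L)
  # after the flip, cohort b dosages count the same allele as cohort a:
  # its A-allele frequency equals 1 - (pre-flip frequency)
  merged_b <- out$genotypes$X[41:80, , drop = FALSE]
  keep <- match(out$genotypes$snps$id, ga$snps$id)
  expect_equal(unname(colMeans(merged_b) / 2), unname((1 - f_b_pre)[keep]),
               tolerance = 1e-12)
})

test_that("strand-ambiguous SNPs are dropped at merge", {
  set.seed(13)
  X <- matrix(rbinom(30 * 4, 2, 0.4), 30, 4)
  ga <- make_geno(X, a1 = c("A", "C", "A", "G"), a2 = c("T", "G", "C", "A"))
  gb <- make_geno(X, a1 = c("A", "C", "A", "G"), a2 = c("T", "G", "C", "A"))
  gb$fam$iid <- paste0("b", gb$fam$iid)
  out <- merge_cohorts(ga, gb)
  expect_identical(attr(out$report, "n_ambiguous_dropped"), 2L)
  expect_false(any(c("s001", "s002") %in% out$genotypes$snps$id))
})

test_that("pooled MAF can fail a SNP that passed per-cohort QC", {
  # cohort a: maf 3/200 = 0.015 passes alone; cohort b: 4/800 = 0.005;
  # n-weighted pooled frequency (3 + 4)/(200 + 800) = 0.007 < 0.01, so the
  # SNP is excluded at the merge stage even though it passed in cohort a
  set.seed(14)
  xa <- c(rep(1, 3), rep(0, 97))
  xb <- c(rep(1, 4), rep(0, 396))
  filler_a <- matrix(rbinom(100 * 3, 2, 0.3), 100, 3)
  filler_b <- matrix(rbinom(400 * 3, 2, 0.3), 400, 3)
  ga <- make_geno(cbind(filler_a, rare = xa), ids = paste0("s", 1:4))
  gb <- make_geno(cbind(filler_b, rare = xb), ids = paste0("s", 1:4))
  gb$fam$iid <- paste0("b", gb$fam$iid)
  # cohort a passes its own MAF filter
  expect_true("s4" %in% qc_filter(ga)$genotypes$snps$id)
  out <- merge_cohorts(ga, gb)
  expect_false("s4" %in% out$genotypes$snps$id)
  expect_identical(unname(out$report$fail_reason["s4"]), "maf")
})
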