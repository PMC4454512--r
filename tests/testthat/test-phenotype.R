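raw_pheno <- function() {
  data.frame(
    FID = paste0("f", 1:8), IID = paste0("i", 1:8),
    #        35yo mother | 50yo childless | IVF | complete | young childless
    AFB = c(28,            NA,              30,   24, 26, 31, NA,  22),
    NEB = c(1L,            0L,              2L,   3L, 2L, 1L,  0L, 4L),
    BIRTHYEAR = c(1975, 1960, 1950, 1948, 1952, 1940, 1980, 1955),
    COUNTRY = c("UK", "UK", "UK", "NL", "NL", "NL", "NL", "UK"),
    DZ = c(0L, 1L, 0L, 0L, 0L, 0L, 0L, 1L),
    IVF = c(0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L),
    stringsAsFactors = FALSE
  )
}

test_that("inclusion rules follow the study design", {
  tab <- build_analysis_set(raw_pheno(), interview_year = 2010)
  # IVF user absent from both analyses
  expect_false("i3" %in% tab$IID)
  # a 35-year-old mother contributes AFB but not NEB
  r1 <- tab[tab$IID == "i1", ]
  expect_identical(r1$AFB, 28)
  expect_true(is.na(r1$NEB))
  # a 50-year-old childless woman contributes NEB = 0, AFB missing
  r2 <- tab[tab$IID == "i2", ]
  expect_identical(r2$NEB, 0L)
  expect_true(is.na(r2$AFB))
  # a 30-year-old childless woman contributes neither
  r7 <- tab[tab$IID == "i7", ]
  expect_true(is.na(r7$NEB) && is.na(r7$AFB))
  # retained values are never altered, only availability
  expect_identical(tab$AFB[tab$IID == "i4"], 24)
  expect_identical(tab$NEB[tab$IID == "i4"], 3L)
  expect_identical(attr(tab, "n_ivf_excluded"), 1L)
  expect_identical(attr(tab, "n_afb"), sum(!is.na(tab$AFB)))
})

test_that("rows with non-missing NEB but missing age are rejected and logged", {
  raw <- raw_pheno()
  raw$BIRTHYEAR[4] <- NA
  expect_message(tab <- build_analysis_set(raw), "missing age")
  expect_false("i4" %in% tab$IID)
  expect_identical(attr(tab, "n_age_rejected"), 1L)
})

test_that("NEB log transform is anchored at zero, monotone and de-skews", {
  expect_identical(transform_neb(0L), 0)
  x <- c(0L, 1L, 2L, 5L, 9L)
  expect_identical(rank(transform_neb(x)), rank(x))
  expect_error(transform_neb(c(1L, -2L)), "non-negative")
  # skewness strictly shrinks on a right-skewed synthetic count vector
  set.seed(2)
  neb <- pmin(rpois(2000, 1.2), 9L)
  skew <- function(v) mean((v - mean(v))^3) / sd(v)^3 # direct third moment
  expect_lt(abs(skew(transform_neb(neb))), abs(skew(neb)))
})

test_that("within-country standardization gives mean 0, SD 1 per country", {
  set.seed(4)
  country <- rep(c("UK", "NL"), c(400, 400))
  afb <- c(rnorm(400, 25.70, 4), rnorm(400, 26.83, 4))
  afb[c(3, 500)] <- NA
  z <- standardize_by_country(afb, country)
  for (cc in c("UK", "NL")) {
    expect_equal(mean(z[country == cc], na.rm = TRUE), 0, tolerance = 1e-12)
    expect_equal(sd(z[country == cc], na.rm = TRUE), 1, tolerance = 1e-12)
  }
  expect_identical(is.na(z), is.na(afb))
  # the ~1-year cross-country AFB gap is removed in the pooled vector
  gap_raw <- mean(afb[country == "NL"], na.rm = TRUE) -
    mean(afb[country == "UK"], na.rm = TRUE)
  expect_gt(abs(gap_raw), 0.5)
  # single-country input is an ordinary Z-score
  z1 <- standardize_by_country(afb[1:60], country[1:60])
  v <- afb[1:60]
  expect_equal(z1, (v - mean(v, na.rm = TRUE)) / sd(v, na.rm = TRUE))
  expect_error(standardize_by_country(rep(1, 10), rep("UK", 10)),
               "variance")
})

test_that("standardize-then-pool equals pool-then-standardize per country", {
  set.seed(5)
  country <- rep(c("UK", "NL"), c(50, 70))
  v <- rnorm(120, ifelse(country == "UK", 10, 12), 2)
  # per-country standardization is local, so doing it on the pooled vector
  # or cohort-by-cohort then concatenating must agree exactly
  pooled <- standardize_by_country(v, country)
  bycohort <- c(standardize_by_country(v[1:50], country[1:50]),
                standardize_by_country(v[51:120], country[51:120]))
  expect_equal(pooled, bycohort, tolerance = 1e-12)
})

test_that("covariate design has the documented columns and full rank", {
  cfg <- sim_config(n_per_cohort = c(60, 60), m_snps = 600, seed = 19)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g, cfg)$phenotypes
  grm <- compute_grm(qc_filter(g)$genotypes)
  pcs <- compute_pcs(grm, k = 20)
  X <- build_covariates(ph, pcs, k = 20)
  n_decades <- length(unique(10 * (ph$BIRTHYEAR %/% 10)))
  expect_lte(ncol(X), 1 + 20 + 1 + (n_decades - 1) + 1)
  expect_identical(qr(X)$rank, ncol(X))
  expect_identical(rownames(X), ph$IID)
  # degenerate factors: one decade, one country, constant DZ
  one <- ph[1:30, ]
  one$COUNTRY <- "UK"; one$BIRTHYEAR <- 1955L; one$DZ <- 0L
  X1 <- build_covariates(one, NULL)
  expect_identical(colnames(X1), "intercept")
  expect_identical(qr(X1)$rank, 1L)
  # unmatched ids are rejected with the offending ids listed
  bad <- ph[1:5, ]; bad$IID <- paste0("missing", 1:5)
  expect_error(build_covariates(bad, pcs), "missing1")
})

test_that("regressing on the design removes cohort stratification", {
  cfg <- sim_config(n_per_cohort = c(250, 250), m_snps = 4000,
                    fst_between_cohorts = 0.05, h2_afb = 0, h2_neb = 0,
                    missing_geno_rate = 0, maf_range = c(0.05, 0.5),
                    childless_prop = 0, seed = 27)
  g <- simulate_genotypes(cfg)
  grm <- compute_grm(g)
  pcs <- compute_pcs(grm, k = 10)
  ph <- simulate_phenotypes(g, cfg)$phenotypes
  # cohort-confounded trait: pure mean shift along the cohort split
  y <- ifelse(ph$COUNTRY == "UK", 1, 0) + rnorm(500, 0, 1)
  expect_gt(abs(cor(y, pcs$vectors[, 1])), 0.3)
  X <- build_covariates(ph, pcs, k = 10)
  res <- lm.fit(X, y)$residuals
  expect_lt(abs(cor(res, pcs$vectors[, 1])), 0.05)
})

test_that("observed correlation matches hand Pearson arithmetic", {
  # 4 complete pairs, textbook formula by hand
  afb <- c(20, 25, 30, 35)
  neb <- c(4, 3, 2, 0)
  num <- sum((afb - mean(afb)) * (neb - mean(neb)))
  den <- sqrt(sum((afb - mean(afb))^2) * sum((neb - mean(neb))^2))
  out <- observed_correlation(afb = afb, neb = neb)
  expect_equal(out$r, num / den, tolerance = 1e-14)
  expect_identical(out$n, 4L)
  expect_equal(observed_correlation(afb = 1:5, neb = 1:5)$r, 1)
  expect_error(observed_correlation(afb = c(1, 2, NA), neb = c(1, NA, 2)),
               "fewer than 3")
})

test_that("synthetic pooled AFB-NEB correlation lands in the plausible band", {
  cfg <- sim_config(n_per_cohort = c(400, 500), m_snps = 2000,
                    missing_geno_rate = 0, seed = 33)
  g <- simulate_genotypes(cfg)
  gq <- qc_filter(g)$genotypes
  ph <- simulate_phenotypes(gq, cfg)$phenotypes
  tab <- build_analysis_set(ph)
  afb <- standardize_by_country(tab$AFB, tab$COUNTRY)
  neb <- standardize_by_country(transform_neb(tab$NEB), tab$COUNTRY)
  out <- observed_correlation(afb = afb, neb = neb)
  expect_lt(out$r, -0.1)
  expect_gt(out$r, -0.45)
  expect_gt(out$n, 100)
})
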