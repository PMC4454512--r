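# random PSD component sets (2x2 genetic + residual matrices)
random_components <- function(seed) {
  set.seed(seed)
  rpsd <- function() {
    L <- matrix(c(runif(1, 0.1, 1), rnorm(1, 0, 0.5), 0,
                  runif(1, 0.1, 1)), 2, byrow = TRUE)
    crossprod(L)
  }
  G <- rpsd(); E <- rpsd()
  structure(list(
    sigma_g2 = c(trait1 = G[1, 1], trait2 = G[2, 2]),
    sigma_e2 = c(trait1 = E[1, 1], trait2 = E[2, 2]),
    cov_g = G[1, 2], cov_e = E[1, 2],
    log_likelihood = NA_real_, sampling_cov = matrix(NA_real_, 6, 6),
    n1 = NA_integer_, n2 = NA_integer_, n_overlap = NA_integer_,
    converged = TRUE, boundary = FALSE, iterations = 0L
  ), class = "bivar_fit")
}

test_that("genetic correlation reproduces its defining arithmetic", {
  # unit genetic variances: r_g is the genetic covariance itself
  f <- bivariate_components(h2_1 = 0.5, h2_2 = 0.5, r_g = -0.62, r_e = 0)
  f$sigma_g2 <- c(trait1 = 1, trait2 = 1); f$cov_g <- -0.62
  expect_equal(genetic_correlation(f)$r_g, -0.62)
  # zero covariance gives zero correlation
  f0 <- bivariate_components(0.3, 0.4, r_g = 0, r_e = 0.1)
  expect_equal(genetic_correlation(f0)$r_g, 0)
  # PSD sweep: |r_g| <= 1 always, PSD-ness checked by eigenvalues
  for (s in 1:50) {
    f <- random_components(s)
    G <- matrix(c(f$sigma_g2[1], f$cov_g, f$cov_g, f$sigma_g2[2]), 2)
    expect_gte(min(eigen(G)$values), -1e-12)
    expect_lte(abs(genetic_correlation(f)$r_g), 1 + 1e-12)
  }
})

test_that("genetic correlation is invariant to rescaling the traits", {
  f <- random_components(7)
  r0 <- genetic_correlation(f)$r_g
  # rescale trait 1 by a^2, trait 2 by b^2 (variances scale quadratically,
  # the covariance by a*b)
  a <- 2.7; b <- 0.4
  f2 <- f
  f2$sigma_g2 <- f$sigma_g2 * c(a^2, b^2)
  f2$sigma_e2 <- f$sigma_e2 * c(a^2, b^2)
  f2$cov_g <- f$cov_g * a * b
  f2$cov_e <- f$cov_e * a * b
  expect_equal(genetic_correlation(f2)$r_g, r0, tolerance = 1e-12)
})

test_that("decomposition reproduces the published worked example", {
  # components as printed: h2 = 0.08 / 0.15, r(G) = -0.62, overall -0.38
  f <- bivariate_components(h2_1 = 0.08, h2_2 = 0.15, r_g = -0.62,
                            r_p_overall = -0.38)
  d <- decompose_phenotypic_correlation(f)
  expect_equal(d$r_p_genetic, sqrt(0.08) * (-0.62) * sqrt(0.15),
               tolerance = 1e-12)
  expect_equal(round(d$r_p_genetic, 2), -0.07)
  expect_equal(d$r_p_overall, -0.38, tolerance = 1e-12)
  expect_equal(d$genetic_share_rounded_pct, 20)
  expect_equal(d$e2_1, 0.92, tolerance = 1e-12)
  expect_equal(d$e2_2, 0.85, tolerance = 1e-12)
})

test_that("decomposition identity and limits hold across a property sweep", {
  for (s in 1:1000) {
    f <- random_components(s + 2000)
    d <- decompose_phenotypic_correlation(f)
    expect_lt(abs(d$r_p_overall - (d$r_p_genetic + d$r_p_environmental)),
              1e-10)
    expect_lt(abs(d$e2_1 - (1 - d$h2_1)), 1e-10)
    expect_lt(abs(d$e2_2 - (1 - d$h2_2)), 1e-10)
  }
  # zero correlations: all parts zero
  f0 <- bivariate_components(0.3, 0.2, r_g = 0, r_e = 0)
  d0 <- suppressWarnings(decompose_phenotypic_correlation(f0))
  expect_equal(d0$r_p_overall, 0)
  expect_equal(d0$r_p_genetic, 0)
  # perfect correlations with equal heritabilities: overall = 1
  f1 <- bivariate_components(0.4, 0.4, r_g = 1, r_e = 1)
  d1 <- decompose_phenotypic_correlation(f1)
  expect_equal(d1$r_p_overall, 1, tolerance = 1e-12)
})

test_that("delta method matches closed forms and Monte-Carlo propagation", {
  set.seed(61)
  k <- 6
  # sampling covariance at a realistic scale (component SEs well below
  # the estimates; first-order propagation needs that regime)
  L <- matrix(rnorm(k * k, 0, 0.025), k); S <- crossprod(L) + diag(1e-5, k)
  th <- c(0.5, 0.4, 0.5, 0.6, -0.1, -0.2)
  # constant function: SE = 0
  expect_equal(delta_se(function(x) 7, th, S), 0)
  # linear functional: exact closed form a' S a
  a <- c(1, -2, 0.5, 0, 3, 1)
  expect_equal(delta_se(function(x) sum(a * x), th, S),
               sqrt(drop(t(a) %*% S %*% a)), tolerance = 1e-8)
  # r_g of a 6-component fit: within 15% of MC propagation (2000 draws)
  rg_fn <- function(x) x[5] / sqrt(x[1] * x[2])
  se_delta <- delta_se(rg_fn, th, S)
  draws <- MASS::mvrnorm(2000, th, S)
  ok <- draws[, 1] > 0 & draws[, 2] > 0
  se_mc <- sd(apply(draws[ok, ], 1, rg_fn))
  expect_lt(abs(se_delta - se_mc) / se_mc, 0.15)
  # exact-gradient and finite-difference modes agree for the builtin
  f <- random_components(3)
  f$sampling_cov <- S
  d <- decompose_phenotypic_correlation(f)
  th_f <- c(f$sigma_g2, f$sigma_e2, f$cov_g, f$cov_e)
  expect_equal(d$se_r_g, delta_se(rg_fn, th_f, S), tolerance = 1e-4)
})

test_that("delta_se across random PSD covariances stays near Monte Carlo", {
  set.seed(62)
  rg_fn <- function(x) x[5] / sqrt(x[1] * x[2])
  for (s in 1:5) {
    L <- matrix(rnorm(36, 0, 0.02), 6); S <- crossprod(L) + diag(2e-5, 6)
    th <- c(runif(4, 0.3, 1), runif(2, -0.2, 0.2))
    se_delta <- delta_se(rg_fn, th, S)
    draws <- MASS::mvrnorm(4000, th, S)
    ok <- draws[, 1] > 0 & draws[, 2] > 0
    se_mc <- sd(apply(draws[ok, ], 1, rg_fn))
    expect_lt(abs(se_delta - se_mc) / se_mc, 0.15)
  }
})

test_that("reports carry two univariate rows, one bivariate row and flags", {
  g <- random_geno(100, 800, seed = 63)
  grm <- compute_grm(g)
  y1 <- draw_mvn_pheno(grm$A, 0.5, 0.5, seed = 63)
  y2 <- 0.5 * y1 + draw_mvn_pheno(grm$A, 0.3, 0.7, seed = 64)
  f1 <- fit_univariate(y1, NULL, grm)
  f2 <- fit_univariate(y2, NULL, grm)
  bf <- fit_bivariate(y1, y2, NULL, NULL, grm)
  dir <- withr::local_tempdir()
  rep <- render_report(list(AFB = f1, NEB = f2), bf,
                       prefix = file.path(dir, "out"))
  expect_identical(nrow(rep$heritability), 2L)
  expect_identical(nrow(rep$bivariate), 1L)
  expect_identical(rep$heritability$trait, c("AFB", "NEB"))
  expect_true(all(c("se", "lrt_p", "n") %in% names(rep$heritability)))
  # files written and readable
  hs <- read.delim(file.path(dir, "out.hsq.txt"))
  bv <- read.delim(file.path(dir, "out.bivar.txt"))
  expect_identical(nrow(hs), 2L)
  expect_identical(nrow(bv), 1L)
  # printed decomposition identity after 2-decimal rounding
  d <- decompose_phenotypic_correlation(bf)
  expect_lte(abs(round(d$r_p_genetic, 2) + round(d$r_p_environmental, 2) -
                   round(d$r_p_overall, 2)), 0.011)
  # GCTA-style .hsq layout: variance rows then logL, p, n
  hsq <- file.path(dir, "afb.hsq")
  write_hsq(f1, hsq)
  lines <- readLines(hsq)
  expect_identical(sub("\t.*", "", lines),
                   c("Source", "V(G)", "V(e)", "Vp", "V(G)/Vp", "logL",
                     "Pval", "n"))
  vg <- as.numeric(strsplit(lines[2], "\t")[[1]][2])
  expect_equal(vg, f1$sigma_g2, tolerance = 1e-6)
})
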