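# Parameter-recovery machinery shared by the acceptance tests.
# Replicates hold the genotype panel (hence the GRM) fixed and redraw SNP
# effects, residuals and censoring; this conditional-on-genotype design is
# the standard sampling frame for GREML calibration studies.

# simulate a genotype panel (optionally QC'd) and build its GRM once;
# recovery runs keep the full nominal panel so the architecture lives
# exactly on the SNPs the GRM sees
build_panel <- function(cfg, panel_seed, qc = FALSE) {
  cfg$seed <- as.integer(panel_seed)
  g <- simulate_genotypes(cfg)
  if (qc) g <- qc_filter(g)$genotypes
  grm <- compute_grm(g)
  list(genotypes = g, grm = grm, cfg = cfg)
}

# one univariate AFB recovery replicate on a fixed panel
replicate_univariate <- function(panel, rep_seed, eig = NULL) {
  cfg <- panel$cfg
  cfg$seed <- as.integer(rep_seed)
  ph <- simulate_phenotypes(panel$genotypes, cfg)$phenotypes
  y <- standardize_by_country(ph$AFB, ph$COUNTRY)
  X <- cbind(intercept = 1,
             country = as.numeric(ph$COUNTRY == ph$COUNTRY[1]))
  fit_univariate(y, X, panel$grm$A, eig = eig)
}

# one bivariate recovery replicate on a fixed panel. The estimator is fit
# on the *latent* trait pair (whose architecture carries the target h2s
# and r_g exactly) under the study's observability pattern -- AFB missing
# for childless women, NEB missing under 45 -- so the check isolates the
# GREML estimator from the integer/censoring distortions of the
# observable mapping (those are exercised by the pipeline tests).
replicate_bivariate <- function(panel, rep_seed) {
  cfg <- panel$cfg
  cfg$seed <- as.integer(rep_seed)
  sim <- simulate_phenotypes(panel$genotypes, cfg)
  ph <- sim$phenotypes
  tab <- build_analysis_set(ph)
  idx <- match(tab$IID, panel$grm$ids$iid)
  A <- panel$grm$A[idx, idx]
  lat <- sim$true$latent[match(tab$IID, ph$IID), ]
  y1 <- ifelse(is.na(tab$AFB), NA_real_, lat[, 1])
  y2 <- ifelse(is.na(tab$NEB), NA_real_, lat[, 2])
  X <- cbind(intercept = 1,
             country = as.numeric(tab$COUNTRY == tab$COUNTRY[1]))
  bf <- fit_bivariate(y1, y2, X, X, A)
  list(fit = bf,
       r_g = bf$cov_g / sqrt(prod(bf$sigma_g2)),
       realized_r_g = sim$true$realized_r_g,
       n1 = bf$n1, n2 = bf$n2)
}
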