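#!/usr/bin/env Rscript
# Stage 5: univariate and bivariate GREML.
#
# Univariate AI-REML per trait gives SNP heritabilities with
# likelihood-ratio p-values (one-tailed boundary mixture). The bivariate
# model adds the cross-trait genetic and residual covariances; its LRT for
# the genetic covariance refits with Cov(G) fixed at 0.

library(gremlite)

grm <- read_grm("results/merged")
ph <- read.delim("results/phenotypes_analysis.tsv")
cv <- read.delim("results/covariates.tsv", check.names = FALSE)

idx <- match(ph$IID, grm$ids$iid)
stopifnot(!anyNA(idx))
A <- subset_grm(grm, idx)
X <- as.matrix(cv[match(ph$IID, cv$IID), -1])

f_afb <- suppressWarnings(fit_univariate(ph$AFB_Z, X, A))
f_neb <- suppressWarnings(fit_univariate(ph$NEB_Z, X, A))
cat("-- AFB --\n"); print(f_afb)
cat("-- NEB --\n"); print(f_neb)
write_hsq(f_afb, "results/afb.hsq")
write_hsq(f_neb, "results/neb.hsq")

bf <- suppressWarnings(fit_bivariate(ph$AFB_Z, ph$NEB_Z, X, X, A))
bf0 <- suppressWarnings(fit_bivariate(ph$AFB_Z, ph$NEB_Z, X, X, A,
                                      fix_cov_g = TRUE))
p_rg <- lrt_p(bf$log_likelihood, bf0$log_likelihood, boundary = FALSE)
cat("-- bivariate --\n"); print(bf)
cat(sprintf("LRT p for Cov(G): %.4g\n", p_rg))

# persist fitted components as plain text for stage 6
comp <- data.frame(
  component = c("sg_afb", "sg_neb", "se_afb", "se_neb", "cov_g", "cov_e",
                "logL", "logL_null_covg", "n_afb", "n_neb", "n_overlap"),
  value = c(bf$sigma_g2, bf$sigma_e2, bf$cov_g, bf$cov_e,
            bf$log_likelihood, bf0$log_likelihood, bf$n1, bf$n2,
            bf$n_overlap)
)
write.table(comp, "results/bivariate_components.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
S <- bf$sampling_cov
write.table(data.frame(S), "results/bivariate_sampling_cov.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
uni <- data.frame(
  trait = c("AFB", "NEB"),
  h2 = c(f_afb$h2, f_neb$h2), se = c(f_afb$se_h2, f_neb$se_h2),
  lrt_p = c(f_afb$lrt_p, f_neb$lrt_p),
  n = c(f_afb$n_used, f_neb$n_used)
)
write.table(uni, "results/univariate_h2.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
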