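#!/usr/bin/env Rscript
# Stage 1: generate the two synthetic cohorts.
#
# Two cohorts of women (a UK-style twin-registry cohort and a larger
# Dutch-style population cohort) with an additive bivariate architecture
# for age at first birth (AFB) and number of children ever born (NEB):
# h2(AFB) = 0.15, h2(NEB) = 0.10, genetic correlation -0.62, residual
# correlation -0.35, mild allele-frequency drift between cohorts, 15%
# childless women and birth years 1919-1989 so that part of the sample has
# incomplete fertility. Desk scale: 700 + 900 women, 8000 SNPs.
# Writes PLINK bed/bim/fam + info + phenotype files per cohort.

library(gremlite)

dir.create("results/cohorts", recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(n_per_cohort = c(700L, 900L), m_snps = 8000L,
                  h2_afb = 0.15, h2_neb = 0.10, r_g = -0.62, r_e = -0.35,
                  maf_range = c(0.01, 0.5), fst_between_cohorts = 0.005,
                  childless_prop = 0.15, missing_geno_rate = 0.01,
                  seed = 20260925L)

geno <- simulate_genotypes(cfg)
sim <- simulate_phenotypes(geno, cfg)

is_uk <- geno$fam$cohort == "UK"
for (cc in c("UK", "NL")) {
  keep <- which(geno$fam$cohort == cc)
  g_c <- gremlite:::subset_geno(geno, i = keep)
  write_cohort(g_c, sim$phenotypes[keep, ],
               prefix = file.path("results/cohorts", tolower(cc)),
               overwrite = TRUE)
}

cat("cohorts written:", sum(is_uk), "UK +", sum(!is_uk), "NL women,",
    ncol(geno$X), "SNPs\n")
cat(sprintf("realized h2: AFB %.3f, NEB %.3f; breeding-value r_g %.3f\n",
            sim$true$realized_h2["afb"], sim$true$realized_h2["neb"],
            sim$true$realized_r_g))
cat(sprintf("childless: %d women (AFB missing for all of them)\n",
            sum(sim$phenotypes$NEB == 0)))
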