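#!/usr/bin/env Rscript
# Stage 4: analysis-ready phenotypes and covariates.
#
# Inclusion rules: NEB only for women aged 45+ (completed fertility);
# AFB missing for childless women; IVF users excluded. NEB is then
# log(x+1)-transformed and both traits are Z-standardized within country
# before pooling. Covariates: intercept, 20 PCs, country, birth decade,
# DZ-twin status.

library(gremlite)

ph_uk <- read.delim("results/cohorts/uk.pheno.txt")
ph_nl <- read.delim("results/cohorts/nl.pheno.txt")
raw <- rbind(ph_uk, ph_nl)
kept_ids <- readLines("results/kept_ids.txt")
raw <- raw[raw$IID %in% kept_ids, ]

tab <- build_analysis_set(raw, interview_year = 2010)
cat(sprintf("analysis set: %d women; AFB n = %d, NEB n = %d (IVF excluded: %d)\n",
            nrow(tab), attr(tab, "n_afb"), attr(tab, "n_neb"),
            attr(tab, "n_ivf_excluded")))

afb_z <- standardize_by_country(tab$AFB, tab$COUNTRY)
neb_z <- standardize_by_country(transform_neb(tab$NEB), tab$COUNTRY)

obs <- observed_correlation(afb = afb_z, neb = neb_z)
cat(sprintf("observed AFB-NEB correlation (complete pairs): %.3f (n = %d)\n",
            obs$r, obs$n))

# per-country observed correlations on raw scales, as a descriptive table
desc <- do.call(rbind, lapply(split(tab, tab$COUNTRY), function(s) {
  o <- observed_correlation(afb = s$AFB, neb = s$NEB)
  data.frame(country = s$COUNTRY[1],
             mean_afb = mean(s$AFB, na.rm = TRUE),
             mean_neb = mean(s$NEB, na.rm = TRUE),
             r_obs = o$r, n_pairs = o$n)
}))
print(desc, row.names = FALSE)
write.table(desc, "results/descriptives.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

pcs_tab <- read.delim("results/merged.eigenvec")
pcs <- list(vectors = as.matrix(pcs_tab[, -(1:2)]),
            values = rep(NA_real_, ncol(pcs_tab) - 2),
            ids = data.frame(fid = pcs_tab[[1]], iid = pcs_tab[[2]]))
class(pcs) <- "pc_set"
X <- suppressWarnings(build_covariates(tab, pcs, k = 20))
cat("covariate design:", ncol(X), "columns, rank", qr(X)$rank, "\n")

out <- data.frame(tab[, c("FID", "IID")], AFB_Z = afb_z, NEB_Z = neb_z)
write.table(out, "results/phenotypes_analysis.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(IID = rownames(X), X, check.names = FALSE),
            "results/covariates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_gcta_inputs(tab, list(afb = afb_z, neb = neb_z), X, "results/greml")
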