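# gremlite

SNP heritability and genetic correlation of human fertility traits via
GREML, end to end.

## What this is

Two quantitative traits summarize female fertility: **age at first birth
(AFB)**, the tempo of reproduction, and **number of children ever born
(NEB)**, its quantum and the usual proxy for fitness. `gremlite`
estimates how much of the variance in each — and how much of their
well-known negative association — is tagged by common SNPs, using
genomic-relatedness-matrix restricted maximum likelihood (GREML) on
unrelated women from two pooled cohorts.

The package implements the full analysis chain:

* **Synthetic two-cohort data** — genotypes with Balding–Nichols
  between-cohort drift plus an additive bivariate architecture for
  AFB/NEB (targets `h2_afb`, `h2_neb`, `r_g`, `r_e` are configurable;
  defaults are the study-scale scenario `0.15 / 0.10 / -0.62 / -0.35`),
  written as PLINK 1 bed/bim/fam + info/phenotype tables.
* **SNP QC** — imputation info > 0.6, missing rate ≤ 3%, MAF ≥ 1%,
  exact Hardy–Weinberg p ≥ 1e-6; merge two cohorts on the SNP
  intersection with allele reconciliation, then re-QC the pooled panel.
* **Relatedness** — GRM with bias-corrected diagonal and
  pairwise-complete denominators (GCTA binary format read/write), greedy
  pruning to an unrelated set, top-k principal components for
  stratification control.
* **Phenotype prep** — NEB only for women 45+, AFB missing for the
  childless, IVF users excluded; `log(NEB + 1)`; within-country
  Z-standardization; covariate design (intercept, 20 PCs, country,
  birth decade, DZ twinning).
* **GREML core** — univariate and bivariate AI-REML
  (`V = sigma_G^2 A + sigma_e^2 I`; the bivariate model runs on the
  union of observed rows, with the residual covariance identified only
  on the overlap), delta-method SEs, boundary-mixture likelihood-ratio
  tests.
* **Reporting** — genetic correlation
  `r_G = Cov(G)/sqrt(V_G1 V_G2)` and the exact decomposition
  `r_P = sqrt(h2_1) r_G sqrt(h2_2) + sqrt(e2_1) r_E sqrt(e2_2)` with
  delta-method SEs from the full 6×6 sampling covariance.

See `vignettes/greml-fertility-methods.Rmd` for the model, the
estimation choices and what the synthetic data do and do not emulate.

## Worked example

```r
library(gremlite)

cfg <- sim_config(n_per_cohort = c(700, 900), m_snps = 6000,
                  h2_afb = 0.15, h2_neb = 0.10, r_g = -0.62, r_e = -0.35,
                  maf_range = c(0.05, 0.5), seed = 1)
g    <- simulate_genotypes(cfg)
gq   <- qc_filter(g)$genotypes          # info/missingness/MAF/HWE filters
ph   <- simulate_phenotypes(gq, cfg)$phenotypes
grm  <- compute_grm(gq)
tab  <- build_analysis_set(ph)          # 45+ rule, childless rule, IVF
A    <- subset_grm(grm, match(tab$IID, grm$ids$iid))
pcs  <- compute_pcs(A, k = 20)
afb  <- standardize_by_country(tab$AFB, tab$COUNTRY)
neb  <- standardize_by_country(transform_neb(tab$NEB), tab$COUNTRY)
X    <- build_covariates(tab, pcs, k = 20)

fit_univariate(afb, X, A)
#> GREML fit: n=1347  sigma_g2=0.2127  sigma_e2=0.7878  h2=0.213 (SE 0.070)
#>   logL=-672.9553  LRT p=0.00103  converged=TRUE
bf <- fit_bivariate(afb, neb, X, X, A)
decompose_phenotypic_correlation(bf)
#> r(G) = -1.000 (0.555)   r(E) = -0.214 (0.072)
#> r(P) = -0.316 (0.035) = genetic -0.137 (0.058) + residual -0.179 (0.064)
#> genetic share = 0.433 (~40%)
```

The numbers are what the code prints for seed 1. Reading them: AFB
heritability is estimated at 0.21 (truth 0.15, within one SE); the
bivariate fit lands on the PSD boundary (`r(G) = -1`, SE 0.56) — at
this desk scale single-replicate genetic correlations scatter widely
around the simulated truth (-0.62) and boundary estimates are routine.
The acceptance suite averages 20 replicates at larger n to check the
estimator is centred; the decomposition identity (genetic + residual =
overall) holds exactly in every fit.

The same pipeline, staged over files with narrative logging, lives in
`analysis/01_simulate.R` … `analysis/06_report.R` (outputs under
`results/`).

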