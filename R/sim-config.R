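#' Simulation configuration for a two-cohort fertility GWAS sample
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults emulate the study design the package targets: two female cohorts
#' of unequal size (a UK twin-registry cohort and a Dutch population cohort),
#' a common-SNP panel, additive bivariate genetic architecture for age at
#' first birth (AFB) and number of children ever born (NEB) with
#' h2(AFB) = 0.15, h2(NEB) = 0.10 and genetic correlation -0.62, birth years
#' spanning 1919-1989 so that part of the sample has incomplete fertility,
#' and a childless fraction whose AFB is structurally missing.
#'
#' @param n_per_cohort integer vector of length 2; women per cohort.
#' @param m_snps number of biallelic SNPs.
#' @param maf_range ancestral minor-allele-frequency range, drawn uniformly.
#' @param h2_afb,h2_neb target SNP heritabilities of the two latent traits.
#' @param r_g genetic correlation between the AFB and NEB effect sizes.
#' @param r_e residual correlation between the two latent traits. The default
#'   -0.35 makes the model-implied overall phenotypic correlation about
#'   -0.38 under the default heritabilities and \code{r_g}.
#' @param prop_causal fraction of SNPs with non-zero effects.
#' @param fst_between_cohorts Balding-Nichols drift parameter separating the
#'   two cohorts' allele frequencies (0 = one panmictic population).
#' @param childless_prop fraction of women who remain childless (NEB = 0,
#'   AFB missing). Taken as the lower tail of the latent fertility trait.
#' @param birthyear_range calendar-year range of birth years (uniform).
#' @param missing_geno_rate genotype missingness, missing completely at
#'   random, in [0, 0.03].
#' @param seed integer seed; identical config + seed gives byte-identical
#'   output from every generator operation.
#'
#' @return An object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_per_cohort = c(2400L, 4300L),
                       m_snps = 50000L,
                       maf_range = c(0.01, 0.5),
                       h2_afb = 0.15,
                       h2_neb = 0.10,
                       r_g = -0.62,
                       r_e = -0.35,
                       prop_causal = 0.01,
                       fst_between_cohorts = 0.005,
                       childless_prop = 0.15,
                       birthyear_range = c(1919L, 1989L),
                       missing_geno_rate = 0.01,
                       seed = 1L) {
  cfg <- list(
    n_per_cohort = as.integer(n_per_cohort), m_snps = as.integer(m_snps),
    maf_range = as.numeric(maf_range), h2_afb = h2_afb, h2_neb = h2_neb,
    r_g = r_g, r_e = r_e, prop_causal = prop_causal,
    fst_between_cohorts = fst_between_cohorts,
    childless_prop = childless_prop,
    birthyear_range = as.integer(birthyear_range),
    missing_geno_rate = missing_geno_rate, seed = as.integer(seed)
  )
  .chk <- function(ok, field, why) {
    if (!isTRUE(ok)) stop("invalid sim_config field '", field, "': ", why,
                          call. = FALSE)
  }
  .chk(length(cfg$n_per_cohort) == 2L && all(is.finite(cfg$n_per_cohort)) &&
         all(cfg$n_per_cohort >= 1L), "n_per_cohort",
       "need two positive integers")
  .chk(length(cfg$m_snps) == 1L && is.finite(cfg$m_snps) && cfg$m_snps >= 1L,
       "m_snps", "need a positive integer")
  .chk(length(cfg$maf_range) == 2L && all(is.finite(cfg$maf_range)) &&
         cfg$maf_range[1] > 0 && cfg$maf_range[2] <= 0.5 &&
         cfg$maf_range[1] <= cfg$maf_range[2], "maf_range",
       "need an increasing pair in (0, 0.5]")
  for (f in c("h2_afb", "h2_neb")) {
    .chk(is.finite(cfg[[f]]) && cfg[[f]] >= 0 && cfg[[f]] <= 1, f,
         "need a proportion in [0, 1]")
  }
  for (f in c("r_g", "r_e")) {
    .chk(is.finite(cfg[[f]]) && abs(cfg[[f]]) <= 1, f,
         "need a correlation in [-1, 1]")
  }
  .chk(is.finite(cfg$prop_causal) && cfg$prop_causal > 0 &&
         cfg$prop_causal <= 1, "prop_causal", "need a proportion in (0, 1]")
  .chk(is.finite(cfg$fst_between_cohorts) && cfg$fst_between_cohorts >= 0 &&
         cfg$fst_between_cohorts < 1, "fst_between_cohorts",
       "need a non-negative drift parameter < 1")
  .chk(is.finite(cfg$childless_prop) && cfg$childless_prop >= 0 &&
         cfg$childless_prop < 1, "childless_prop",
       "need a proportion in [0, 1)")
  .chk(length(cfg$birthyear_range) == 2L &&
         all(is.finite(cfg$birthyear_range)) &&
         cfg$birthyear_range[1] <= cfg$birthyear_range[2], "birthyear_range",
       "need an increasing pair of calendar years")
  .chk(is.finite(cfg$missing_geno_rate) && cfg$missing_geno_rate >= 0 &&
         cfg$missing_geno_rate <= 0.03, "missing_geno_rate",
       "need a proportion in [0, 0.03]")
  .chk(length(cfg$seed) == 1L && !is.na(cfg$seed), "seed",
       "need a finite integer")
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", sum(x$n_per_cohort), "women in cohorts",
      paste(x$n_per_cohort, collapse = "/"), "|", x$m_snps, "SNPs\n")
  cat(sprintf("  h2(AFB)=%.3g h2(NEB)=%.3g r_g=%.3g r_e=%.3g Fst=%.3g\n",
              x$h2_afb, x$h2_neb, x$r_g, x$r_e, x$fst_between_cohorts))
  invisible(x)
}
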