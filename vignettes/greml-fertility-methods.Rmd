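---
title: "GREML heritability and genetic correlation of fertility traits: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GREML heritability and genetic correlation of fertility traits: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gremlite)
```

## The scientific question

Human fertility has two standard quantitative measures: the *tempo* of
reproduction, age at first birth (AFB, in years), and its *quantum*,
the number of children ever born (NEB, a lifetime count and the usual
proxy for Darwinian fitness). Twin studies have long reported moderate
heritabilities for both, but rest on strong assumptions about shared
environments. `gremlite` implements the molecular alternative: estimate
the additive variance tagged by common SNPs directly from the realized
genomic similarity of *unrelated* women, using
genomic-relatedness-matrix restricted maximum likelihood (GREML), and
quantify how much of the negative AFB–NEB phenotypic association is
genetic.

## Model

For one trait measured on $n$ unrelated individuals,

$$ y = X\beta + g + e, \qquad
   g \sim N(0, \sigma_G^2 A), \quad e \sim N(0, \sigma_e^2 I), $$

where $A$ is the genomic relationship matrix (GRM) estimated from
genome-wide SNPs and $X$ holds fixed covariates. SNP heritability is
$h^2 = \sigma_G^2 / \sigma_P^2$ with
$\sigma_P^2 = \sigma_G^2 + \sigma_e^2$. The bivariate extension stacks
the two traits over the union of their observed rows; the cross-trait
genetic covariance $\mathrm{Cov}(G)$ acts through $A$ between *all*
pairs of individuals, so the model can use women observed for only one
trait (e.g. women under 45, whose NEB is not yet complete, still inform
AFB), while the residual covariance $\mathrm{Cov}(E)$ is only
identifiable on individuals observed for both traits. The genetic
correlation is
$r_G = \mathrm{Cov}(G) / \sqrt{\sigma^2_{G1}\sigma^2_{G2}}$, and the
model-implied phenotypic correlation splits exactly as

$$ r_P \;=\; \underbrace{\sqrt{h^2_1}\, r_G\, \sqrt{h^2_2}}_{\text{genetic part}}
        \;+\; \underbrace{\sqrt{e^2_1}\, r_E\, \sqrt{e^2_2}}_{\text{residual part}},
        \qquad e^2_t = 1 - h^2_t . $$

Both parts are simply $\mathrm{Cov}(G)/\sqrt{\sigma^2_{P1}\sigma^2_{P2}}$
and $\mathrm{Cov}(E)/\sqrt{\sigma^2_{P1}\sigma^2_{P2}}$, so the identity
holds to machine precision; only the square-root form keeps every term a
bounded correlation. Standard errors of all derived quantities come from
first-order (delta-method) propagation of the full 6×6 sampling
covariance of the components — never from independence approximations.

## Estimation choices

**REML optimizer.** One EM-REML warm-up step from
$(\sigma_G^2, \sigma_e^2) = (V_P/2, V_P/2)$, then average-information
(AI) updates with step-halving so the restricted likelihood never
decreases; convergence when the improvement drops below $10^{-8}$, at
most 100 iterations; components floored at $10^{-6} V_P$ with a boundary
flag. When a constrained fit lands on the floor, the exact boundary
solution $\sigma_G^2 = 0$ (closed-form residual model) is substituted if
it has higher likelihood. Fixed effects are profiled out inside REML
(not pre-residualized).

**Eigenbasis for the univariate model.** With a single GRM,
$V = \sigma_G^2 A + \sigma_e^2 I$ diagonalizes in the eigenbasis of
$A$; after one eigendecomposition each AI iteration is $O(np^2)$. The
standalone `reml_loglik()` is a *separate*, dense-Cholesky
implementation of the restricted likelihood, so the optimizer can be
cross-checked against grid searches that do not share its code path.

**Bivariate optimizer.** The six components
$(\sigma^2_{G1}, \sigma^2_{G2}, \sigma^2_{e1}, \sigma^2_{e2},
\mathrm{Cov}(G), \mathrm{Cov}(E))$ are estimated by dense AI-REML. With
the default `constrain = TRUE`, steps are taken in a Cholesky
parameterization of the 2×2 genetic and residual component matrices:
positive semi-definiteness is then automatic and the PSD boundary
($|r_G| = 1$), which small samples hit routinely, becomes an interior
point of the search space instead of a wall to crawl along. Steps use
Levenberg-style damping of the average-information matrix with a
line search on the exact restricted likelihood. Starting values are the
two univariate fits with zero covariances. `constrain = FALSE` runs
plain AI updates in component space.

**Hypothesis tests.** Variance components are tested against the
boundary null with the one-tailed mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ (so $\Lambda = 0$ gives
$p = 0.5$); the genetic covariance, an interior parameter, uses the
ordinary $\chi^2_1$ from a refit with $\mathrm{Cov}(G) = 0$.

## Genotype QC and the GRM

SNPs are removed, in a fixed attribution order (info → missingness →
MAF → HWE), when the imputation info score is ≤ 0.6, the missing rate
exceeds 3%, the minor allele frequency is below 1% (MAF computed from
called genotypes of the sample at hand; exactly 1% is retained), or the
*exact* Hardy–Weinberg test falls below $10^{-6}$. The exact
(Levene–Haldane) test is used rather than the $\chi^2$ approximation
because the approximation is unreliable exactly where the filter
operates, near the MAF floor. Two cohorts are merged on their SNP
intersection with allele orientation reconciled (A1/A2 swaps flip
dosages $x \mapsto 2 - x$; strand-ambiguous A/T and C/G SNPs are
dropped — frequency-based resolution is unsafe at desk scale), and the
merged panel is re-QC'd with the same thresholds, so a SNP can fail on
pooled MAF even after passing per cohort.

The GRM uses pooled post-QC allele frequencies, pairwise-complete SNP
sets with per-pair denominators $M_{jk}$, and the bias-corrected
diagonal estimator
$A_{jj} = 1 + \tfrac{1}{M_j}\sum_i
  \frac{x_{ij}^2-(1+2p_i)x_{ij}+2p_i^2}{2p_i(1-p_i)}$
(the plain squared-deviation diagonal is available behind
`diag_method = "plain"` for oracle tests). Relatedness pruning is
greedy — repeatedly drop the individual in the most pairs above the
cutoff, ties broken towards the later id — with the conventional default
cutoff 0.025 ("unrelated" ≈ nothing closer than second cousins). Note
that per-pair GRM noise has SD $\approx 1/\sqrt{m}$: at the study scale
($m \sim 10^6$) the noise is far below 0.025, but desk-scale panels
($m \sim 10^3$–$10^4$) need a noise-aware cutoff (the analysis scripts
use $0.025 + 4/\sqrt{m}$) or pruning would remove most of the sample for
no biological reason. PCs for stratification control are computed from
the pruned GRM (the order pruning → PCs is a choice; the source design
does not state it), with a deterministic sign convention (largest
loading positive) so downstream regressions are reproducible.

## Phenotype construction

NEB is set missing for women younger than 45 at interview (fertility
incomplete — right-censored cases are excluded, not modelled; survival
treatments are out of scope), AFB is missing for childless women at any
age, and IVF users are removed entirely. NEB is transformed as
$\log(\mathrm{NEB} + 1)$: the offset is forced because childless women
(NEB = 0) *are* retained in the NEB analysis. Both traits are then
Z-standardized within country before pooling, which removes
between-cohort level differences (e.g. the later Dutch mean AFB).
Covariates: intercept, 20 PCs, country, birth decade (reference =
earliest decade; a linear-year coding is available), DZ-twin status
(twinning is itself heritable and only occurs in the twin-registry
cohort). Standardization is computed on the post-exclusion analysis
sample per trait, matching the trait-specific Ns.

## The synthetic-data generator

Because the real cohort data are access-restricted, the package ships a
generator that emulates the study's *structure*: two cohorts of unequal
size, ancestral allele frequencies uniform on the configured MAF range,
Balding–Nichols drift between cohorts (default $F_{st} = 0.005$, enough
to give PC1 a real stratification signal), genotypes as two Bernoulli
draws, missing calls at random, and simulated info scores on
$[0.4, 1]$ so the info filter has work to do (no imputation is
modelled). A causal subset (default 1% of SNPs) receives
bivariate-normal effect pairs with correlation $r_G$; breeding values
on standardized dosages are rescaled so their sample variance equals the
target $h^2$ exactly, and residual pairs carry correlation $r_E$ and
variance $1 - h^2$. Latent traits map to observables: AFB =
cohort mean (25.7 UK / 26.8 NL) + 4 × latent, rounded and clamped to
[15, 44]; NEB = 2.1 + 1.4 × latent, rounded, floored at 0, capped at 9
— a rounded Gaussian rather than a Poisson, deliberately, so the
downstream log/Z transforms act on a skewed count while the additive
latent structure stays exact. The childless fraction (default 15%, a
placeholder — the source reports no childless fraction) is the *lower
tail* of the latent NEB, so censoring tracks the biology instead of
being independent noise. Birth years are uniform on 1919–1989 with
interview year 2010, which makes about a third of the sample younger
than 45 — that is what generates the partial trait overlap the bivariate
model exploits. DZ flags occur only in the twin cohort (rate 0.3 among
its singletons); IVF is flagged at 0.9%.

Defaults for the architecture are the study-scale scenario values:
$h^2(\mathrm{AFB}) = 0.15$, $h^2(\mathrm{NEB}) = 0.10$,
$r_G = -0.62$, and $r_E = -0.35$, the last back-solved so the
model-implied overall phenotypic correlation is about $-0.38$. The
default panel is 2400 + 4300 women by 50 000 SNPs — a desk-scale
stand-in for the ~1M-SNP study panel (a full-size dosage matrix would
not be a desk object); tests and scripts pass smaller sizes explicitly.

**What the generator does *not* emulate** — and hence what passing
tests cannot show about real data: linkage disequilibrium (every SNP is
independent, so causal variants dropped by QC are simply lost rather
than tagged; recovery experiments therefore simulate phenotypes on the
analyzed panel), the X chromosome, family structure beyond the DZ flag,
genotyping batch effects, and any real imputation process behind the
info scores.

## Calibration experiments

The acceptance suite runs the estimator at reduced scale, chosen to keep
the full test run on one CPU in well under half an hour: univariate
recovery with 20 replicates at $n = 2000$, $m = 5000$, true
$h^2 = 0.15$ (mean $\hat h^2$ within 0.03); bivariate recovery with 20
replicates at ~1500/1200 observed per trait with partial overlap, true
$r_G = -0.62$ (mean $\hat r_G$ within 0.15, sign right in ≥ 19/20); SE
calibration over 50 replicates at $n = 800$ (empirical SD of $\hat h^2$
within 30% of the mean reported SE); and size of the boundary-mixture
LRT under $\sigma_G^2 = 0$ over 200 replicates at $n = 500$ (rejection
rate inside the exact binomial 95% band around 5%). Replicates redraw
effects, residuals and censoring on a fixed genotype panel —
conditional-on-genotype resampling, the standard frame for REML
calibration, which also lets the univariate fits share one
eigendecomposition. The bivariate recovery replicates fit the *latent*
trait pair under the study's observability masks (AFB missing for the
childless, NEB missing under 45): the check targets the estimator's
recovery of the architecture, and the observable mapping's
integer rounding would otherwise attenuate the trait-2 genetic signal
and confound the assessment.

A caution about the sign of $\hat r_G$ at desk scale: with $m$
unlinked SNPs the sampling SD of $\hat h^2$ is about $\sqrt{2m}/n$
(\emph{larger} for more markers at fixed $n$, because per-pair
relatedness signal dilutes), which at $n \approx 1200$, $m = 5000$ is
≈ 0.08 — the same order as the true NEB heritability. In the minority
of replicates whose trait-2 genetic variance estimate collapses toward
zero, $\hat r_G = \widehat{\mathrm{Cov}}(G)/\sqrt{\hat\sigma^2_{G1}
\hat\sigma^2_{G2}}$ pins to a PSD boundary of essentially random sign
with delta SEs far above 1; direct-search oracles confirm these
boundary solutions are the genuine constrained MLEs of those
replicates. The constrained $\hat r_G$ distribution at this scale is
therefore a mixture of an interior mode near the truth and small
boundary atoms at $\pm 1$ — which is why the suite's sign-consistency
check can fail for a correctly centred estimator, and why boundary
fits carry an explicit flag and their SEs should always be read
alongside the point estimate.

## Numerical notes and limitations

* GRMs built with pairwise-complete denominators can be very slightly
  indefinite; eigenvalues are clipped at zero where non-negativity is
  part of a contract (PCs), and the bivariate optimizer tolerates it
  through its line search.
* The mean off-diagonal of a sample-frequency GRM is $-1/(n-1)$, not 0;
  tests account for it.
* An identity GRM makes $(\sigma_G^2, \sigma_e^2)$ jointly
  unidentifiable (the likelihood is flat along their sum); the fit
  detects the singular information matrix and flags it.
* Delta-method SEs are first-order: they are accurate when component
  SEs are small relative to the components and degrade for ratios like
  $r_G$ near the PSD boundary or with very noisy variance estimates.
* Sample-size floors ($n \ge 30$ univariate, union $\ge 60$ bivariate)
  are warnings, not errors: tiny instances are needed for exact oracle
  checks, and the hard error is reserved for $n \le \mathrm{rank}(X)+2$.
* Whether "age 45" means age at interview is not stated in the source
  design; age at interview is used. The IVF exclusion is applied to both
  traits.
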