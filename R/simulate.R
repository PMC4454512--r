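#' Simulate two-cohort SNP genotypes
#'
#' Draws ancestral allele frequencies uniformly from \code{maf_range},
#' drifts them into cohort-specific frequencies with a Balding-Nichols
#' beta model governed by \code{fst_between_cohorts}, and samples each
#' genotype as two Bernoulli allele draws. A fraction
#' \code{missing_geno_rate} of calls is deleted completely at random, and
#' each SNP receives a simulated imputation info score in [0.4, 1] so the
#' downstream info filter has something to act on (no imputation is
#' modelled).
#'
#' @param config a \code{\link{sim_config}}.
#' @return A \code{\link{geno_matrix}} with cohort labels "UK" and "NL".
#' @export
simulate_genotypes <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  m <- config$m_snps
  n_c <- config$n_per_cohort
  p_anc <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  fst <- config$fst_between_cohorts
  draw_cohort_freq <- function() {
    if (fst <= 0) return(p_anc)
    a <- p_anc * (1 - fst) / fst
    b <- (1 - p_anc) * (1 - fst) / fst
    pmin(pmax(stats::rbeta(m, a, b), 1e-4), 1 - 1e-4)
  }
  cohorts <- c("UK", "NL")
  Xs <- vector("list", 2L)
  for (k in 1:2) {
    p_k <- draw_cohort_freq()
    Xs[[k]] <- matrix(stats::rbinom(n_c[k] * m, 2L, rep(p_k, each = n_c[k])),
                      nrow = n_c[k], ncol = m)
  }
  X <- rbind(Xs[[1]], Xs[[2]])
  storage.mode(X) <- "double"
  if (config$missing_geno_rate > 0) {
    n_miss <- round(config$missing_geno_rate * length(X))
    if (n_miss > 0) X[sample.int(length(X), n_miss)] <- NA_real_
  }
  alleles <- t(vapply(seq_len(m),
                      function(i) sample(c("A", "C", "G", "T"), 2L),
                      character(2)))
  snps <- data.frame(
    id = sprintf("snp%06d", seq_len(m)),
    chr = 1L,
    pos = seq_len(m) * 1000L,
    a1 = alleles[, 1], a2 = alleles[, 2],
    info = stats::runif(m, 0.4, 1),
    stringsAsFactors = FALSE
  )
  fam <- data.frame(
    fid = sprintf("F%05d", seq_len(sum(n_c))),
    iid = sprintf("I%05d", seq_len(sum(n_c))),
    cohort = rep(cohorts, n_c),
    stringsAsFactors = FALSE
  )
  geno_matrix(X, snps, fam)
}

# standardized dosages: mean-impute missing, centre by 2p, scale by
# sqrt(2p(1-p)) using pooled sample frequencies
standardize_dosages <- function(X) {
  p <- colMeans(X, na.rm = TRUE) / 2
  keep_scale <- pmax(2 * p * (1 - p), .Machine$double.eps)
  W <- sweep(X, 2L, 2 * p, "-")
  W[is.na(W)] <- 0
  sweep(W, 2L, sqrt(keep_scale), "/")
}

#' Simulate AFB and NEB phenotypes on top of simulated genotypes
#'
#' Implements the additive bivariate architecture the downstream GREML
#' analysis assumes: a causal subset of SNPs receives bivariate-normal
#' effect-size pairs with correlation \code{r_g}; breeding values are built
#' on standardized dosages and rescaled so their sample variances equal the
#' target heritabilities; residual pairs are drawn with correlation
#' \code{r_e} and variances \code{1 - h2}. The two latent traits are then
#' mapped to observables: AFB is an affine map (cohort means 25.7 / 26.8,
#' SD 4) rounded to whole years and clamped to [15, 44]; NEB is a rounded
#' Gaussian (mean 2.1, SD 1.4) floored at 0 and capped at 9. The
#' \code{childless_prop} lower tail of the latent NEB gets NEB = 0 and AFB
#' missing; birth years are uniform; the DZ-twin flag only occurs in the
#' twin cohort; a small IVF fraction (0.9%) is flagged.
#'
#' @param genotypes a \code{\link{geno_matrix}} from
#'   \code{\link{simulate_genotypes}}.
#' @param config the same \code{\link{sim_config}}.
#' @return list with \code{phenotypes} (data.frame FID, IID, AFB, NEB,
#'   BIRTHYEAR, COUNTRY, DZ, IVF) and \code{true} (per-SNP effects,
#'   per-individual breeding values, realized h2 and genetic correlation,
#'   latent traits, causal index).
#' @export
simulate_phenotypes <- function(genotypes, config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  stopifnot(inherits(genotypes, "geno_matrix"))
  m <- ncol(genotypes$X)
  n <- nrow(genotypes$X)
  n_causal <- max(1L, round(config$prop_causal * config$m_snps))
  if (n_causal > m) {
    stop("genotype matrix has fewer SNPs (", m, ") than prop_causal ",
         "requires (", n_causal, ")")
  }
  set.seed(config$seed + 1L)
  causal <- sort(sample.int(m, n_causal))

  # bivariate-normal effect pairs, corr r_g (column 1 = AFB, column 2 = NEB)
  z <- matrix(stats::rnorm(n_causal * 2L), ncol = 2L)
  beta <- cbind(z[, 1], config$r_g * z[, 1] +
                  sqrt(max(0, 1 - config$r_g^2)) * z[, 2])
  W <- standardize_dosages(genotypes$X[, causal, drop = FALSE])
  g_raw <- W %*% beta
  h2 <- c(config$h2_afb, config$h2_neb)
  g <- g_raw
  for (t in 1:2) {
    v <- stats::var(g_raw[, t])
    g[, t] <- if (h2[t] > 0 && v > 0) g_raw[, t] * sqrt(h2[t] / v) else 0
  }
  ze <- matrix(stats::rnorm(n * 2L), ncol = 2L)
  ze <- cbind(ze[, 1], config$r_e * ze[, 1] +
                sqrt(max(0, 1 - config$r_e^2)) * ze[, 2])
  e <- sweep(ze, 2L, sqrt(1 - h2), "*")
  latent <- g + e # column 1 = AFB, column 2 = NEB; variances ~ 1

  cohort <- genotypes$fam$cohort
  afb_mean <- ifelse(cohort == cohort[1], 25.7, 26.8)
  afb <- pmin(pmax(round(afb_mean + 4 * latent[, 1]), 15), 44)
  neb <- pmin(pmax(round(2.1 + 1.4 * latent[, 2]), 0), 9)

  n_childless <- round(config$childless_prop * n)
  childless <- if (n_childless > 0) order(latent[, 2])[seq_len(n_childless)]
               else integer(0)
  neb[childless] <- 0L
  afb[childless] <- NA_real_

  birthyear <- sample(seq(config$birthyear_range[1],
                          config$birthyear_range[2]), n, replace = TRUE)
  dz <- ifelse(cohort == cohort[1], stats::rbinom(n, 1L, 0.3), 0L)
  ivf <- stats::rbinom(n, 1L, 0.009)

  beta_full <- matrix(0, m, 2L,
                      dimnames = list(genotypes$snps$id, c("afb", "neb")))
  beta_full[causal, ] <- beta
  realized_h2 <- vapply(1:2, function(t) {
    vy <- stats::var(latent[, t])
    if (vy > 0) stats::var(g[, t]) / vy else 0
  }, numeric(1))
  r_g_real <- if (all(h2 > 0)) stats::cor(g[, 1], g[, 2]) else NA_real_

  list(
    phenotypes = data.frame(
      FID = genotypes$fam$fid, IID = genotypes$fam$iid,
      AFB = afb, NEB = as.integer(neb),
      BIRTHYEAR = as.integer(birthyear), COUNTRY = cohort,
      DZ = as.integer(dz), IVF = as.integer(ivf),
      stringsAsFactors = FALSE
    ),
    true = list(
      beta = beta_full,
      g = structure(g, dimnames = list(genotypes$fam$iid, c("afb", "neb"))),
      latent = latent,
      causal = causal,
      realized_h2 = stats::setNames(realized_h2, c("afb", "neb")),
      realized_r_g = r_g_real
    )
  )
}

#' Write a simulated cohort to disk in analysis-ready formats
#'
#' Emits PLINK 1 bed/bim/fam, a tab-delimited SNP info-score table
#' (SNP, INFO) and a tab-delimited phenotype/covariate table
#' (FID, IID, AFB, NEB, BIRTHYEAR, COUNTRY, DZ, IVF).
#'
#' @param genotypes a \code{\link{geno_matrix}}.
#' @param phenotypes the phenotype data.frame from
#'   \code{\link{simulate_phenotypes}} (or \code{NULL} to skip).
#' @param prefix output path prefix; files \code{<prefix>.bed/.bim/.fam},
#'   \code{<prefix>.info.txt}, \code{<prefix>.pheno.txt} are created.
#' @param overwrite logical; refuse to clobber existing files by default.
#' @return invisibly, the character vector of files written.
#' @export
write_cohort <- function(genotypes, phenotypes = NULL, prefix,
                         overwrite = FALSE) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  files <- paste0(prefix, c(".bed", ".bim", ".fam", ".info.txt"))
  if (!is.null(phenotypes)) {
    stopifnot(identical(phenotypes$IID, genotypes$fam$iid))
    files <- c(files, paste0(prefix, ".pheno.txt"))
  }
  hit <- files[file.exists(files)]
  if (length(hit) && !overwrite) {
    stop("refusing to overwrite existing file(s): ",
         paste(hit, collapse = ", "), " (set overwrite = TRUE)")
  }
  write_plink(genotypes, prefix)
  utils::write.table(
    data.frame(SNP = genotypes$snps$id, INFO = genotypes$snps$info),
    paste0(prefix, ".info.txt"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(phenotypes)) {
    utils::write.table(phenotypes, paste0(prefix, ".pheno.txt"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(files)
}
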