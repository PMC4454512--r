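#' SNP quality-control thresholds
#'
#' Defaults follow the study design the package targets: SNPs are removed
#' with missing rate above 3%, minor allele frequency below 1%, an exact
#' Hardy-Weinberg test p-value below 1e-6, or an imputation info score of
#' 0.6 or less.
#'
#' @param max_missing_rate maximum tolerated per-SNP missing rate
#'   (exclusive: a SNP fails when its missing rate is strictly larger).
#' @param min_maf minimum minor allele frequency (a SNP fails when MAF is
#'   strictly lower, so MAF exactly at the threshold is retained).
#' @param hwe_p_floor SNPs with exact HWE p-value below this fail.
#' @param min_info SNPs with info score <= this fail (the filter keeps
#'   scores strictly larger than 0.6).
#' @return An object of class \code{qc_thresholds}.
#' @export
qc_thresholds <- function(max_missing_rate = 0.03, min_maf = 0.01,
                          hwe_p_floor = 1e-6, min_info = 0.6) {
  th <- list(max_missing_rate = max_missing_rate, min_maf = min_maf,
             hwe_p_floor = hwe_p_floor, min_info = min_info)
  for (f in names(th)) {
    v <- th[[f]]
    if (!is.finite(v) || v <= 0 || v >= 1) {
      stop("qc_thresholds field '", f, "' must lie in (0, 1)", call. = FALSE)
    }
  }
  structure(th, class = "qc_thresholds")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Levene-Haldane exact test: conditions on the observed allele counts and
#' sums the probabilities of all heterozygote counts whose conditional
#' probability does not exceed that of the observed count (the standard
#' SNP-HWE formulation, not mid-p). Monomorphic input returns p = 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return exact p-value in (0, 1].
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("genotype counts must be non-negative")
  }
  if (any(counts != round(counts))) stop("genotype counts must be integers")
  n <- sum(counts)
  if (n == 0) stop("total genotype count must be positive")
  n_rare <- 2 * min(n_AA, n_aa) + n_Aa # copies of the rarer allele
  if (n_rare == 0) return(1.0)         # monomorphic
  # conditional distribution of het count given allele counts; het counts
  # share the parity of n_rare
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  n_common <- 2 * n - n_rare
  # log P(het = h) up to a constant: via log-factorials
  lp <- vapply(hets, function(h) {
    hom_r <- (n_rare - h) / 2
    hom_c <- (n_common - h) / 2
    h * log(2) - lfactorial(h) - lfactorial(hom_r) - lfactorial(hom_c)
  }, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

#' Apply SNP-level quality control
#'
#' Removes SNPs failing, in this fixed attribution order: info score
#' (<= min_info), missing rate (> max), MAF (< min, computed from called
#' genotypes), exact HWE (p < floor). Individuals are never removed. A SNP
#' failing several filters is attributed to the first in the order.
#'
#' @param genotypes a \code{\link{geno_matrix}}.
#' @param thresholds a \code{\link{qc_thresholds}}.
#' @return list with the filtered \code{geno_matrix} and a
#'   \code{qc_report} (per-filter exclusion counts, survivors, per-SNP fail
#'   reason labels).
#' @export
qc_filter <- function(genotypes, thresholds = qc_thresholds()) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  if (!inherits(thresholds, "qc_thresholds")) {
    thresholds <- do.call(qc_thresholds, as.list(thresholds))
  }
  if (ncol(genotypes$X) == 0L) stop("empty genotype matrix")
  st <- snp_stats(genotypes)
  info <- genotypes$snps$info
  # boundary semantics (info = 0.6 fails; missing rate = 3% and MAF = 1%
  # pass) must hold under floating-point rounding of the rates
  eps <- 1e-12
  fail_info <- !is.na(info) & info <= thresholds$min_info + eps
  fail_miss <- st$miss_rate > thresholds$max_missing_rate + eps
  fail_maf <- is.na(st$maf) | st$maf < thresholds$min_maf - eps
  hwe_p <- hwe_p_values(genotypes$X)
  fail_hwe <- hwe_p < thresholds$hwe_p_floor

  reason <- rep(NA_character_, ncol(genotypes$X))
  reason[fail_hwe] <- "hwe"
  reason[fail_maf] <- "maf"
  reason[fail_miss] <- "missingness"
  reason[fail_info] <- "info"
  keep <- is.na(reason)
  report <- structure(list(
    n_input = length(keep),
    n_pass = sum(keep),
    excluded = c(info = sum(reason == "info", na.rm = TRUE),
                 missingness = sum(reason == "missingness", na.rm = TRUE),
                 maf = sum(reason == "maf", na.rm = TRUE),
                 hwe = sum(reason == "hwe", na.rm = TRUE)),
    fail_reason = stats::setNames(reason, genotypes$snps$id),
    thresholds = thresholds
  ), class = "qc_report")
  list(genotypes = subset_geno(genotypes, j = which(keep)),
       report = report)
}

# vectorized exact HWE p-values over the columns of a dosage matrix
hwe_p_values <- function(X) {
  n_aa <- colSums(X == 0, na.rm = TRUE)
  n_het <- colSums(X == 1, na.rm = TRUE)
  n_AA <- colSums(X == 2, na.rm = TRUE)
  vapply(seq_len(ncol(X)), function(j) {
    if (n_AA[j] + n_het[j] + n_aa[j] == 0) return(1.0) # all calls missing
    hwe_test(n_AA[j], n_het[j], n_aa[j])
  }, numeric(1))
}

#' @export
print.qc_report <- function(x, ...) {
  cat("SNP QC:", x$n_input, "in,", x$n_pass, "pass\n")
  cat(sprintf("  excluded: info<=%g: %d | missing>%g: %d | MAF<%g: %d | HWE<%g: %d\n",
              x$thresholds$min_info, x$excluded[["info"]],
              x$thresholds$max_missing_rate, x$excluded[["missingness"]],
              x$thresholds$min_maf, x$excluded[["maf"]],
              x$thresholds$hwe_p_floor, x$excluded[["hwe"]]))
  invisible(x)
}

#' Write a QC report as a delimited summary
#'
#' @param report a \code{qc_report}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(
    metric = c("n_input", "excluded_info", "excluded_missingness",
               "excluded_maf", "excluded_hwe", "n_pass"),
    value = c(report$n_input, report$excluded[["info"]],
              report$excluded[["missingness"]], report$excluded[["maf"]],
              report$excluded[["hwe"]], report$n_pass)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# TRUE for strand-ambiguous allele pairs (A/T or C/G)
is_ambiguous_pair <- function(a1, a2) {
  unname(.COMPLEMENT[a1] == a2)
}

#' Merge two QC'd cohorts and re-apply QC
#'
#' SNP set is the intersection by id and position. Allele orientation is
#' reconciled against the first cohort: a plain A1/A2 swap (or its strand
#' complement) flips the second cohort's dosages x -> 2 - x; strand-
#' ambiguous A/T and C/G SNPs and irreconcilable allele pairs are dropped.
#' The merged matrix is then passed through \code{\link{qc_filter}} again
#' with the same thresholds, so pooled MAF/missingness/HWE are re-checked.
#' The merged info score of a SNP is the minimum of the two cohorts'.
#'
#' @param a,b \code{\link{geno_matrix}} objects, individually QC'd, with
#'   disjoint individual ids.
#' @param thresholds a \code{\link{qc_thresholds}}.
#' @return list with the merged, re-QC'd \code{geno_matrix} and the
#'   \code{qc_report} of the merge-stage filter (with merge bookkeeping in
#'   attributes \code{n_flipped}, \code{n_ambiguous_dropped},
#'   \code{n_mismatch_dropped}, \code{n_intersection}).
#' @export
merge_cohorts <- function(a, b, thresholds = qc_thresholds()) {
  stopifnot(inherits(a, "geno_matrix"), inherits(b, "geno_matrix"))
  if (length(intersect(a$fam$iid, b$fam$iid))) {
    stop("cohorts share individual ids; they must be disjoint")
  }
  key_a <- paste(a$snps$id, a$snps$chr, a$snps$pos)
  key_b <- paste(b$snps$id, b$snps$chr, b$snps$pos)
  common <- intersect(key_a, key_b)
  ia <- match(common, key_a)
  ib <- match(common, key_b)
  a1a <- a$snps$a1[ia]; a2a <- a$snps$a2[ia]
  a1b <- b$snps$a1[ib]; a2b <- b$snps$a2[ib]

  same <- a1a == a1b & a2a == a2b
  swap <- a1a == a2b & a2a == a1b
  flip_strand <- .COMPLEMENT[a1b] == a1a & .COMPLEMENT[a2b] == a2a
  flip_swap <- .COMPLEMENT[a2b] == a1a & .COMPLEMENT[a1b] == a2a
  ambiguous <- is_ambiguous_pair(a1a, a2a) | is_ambiguous_pair(a1b, a2b)
  reconcilable <- (same | swap | flip_strand | flip_swap) & !ambiguous
  needs_flip <- (swap | flip_swap) & reconcilable

  Xa <- a$X[, ia[reconcilable], drop = FALSE]
  Xb <- b$X[, ib[reconcilable], drop = FALSE]
  flip_cols <- needs_flip[reconcilable]
  if (any(flip_cols)) {
    Xb[, flip_cols] <- 2 - Xb[, flip_cols]
  }
  snps <- a$snps[ia[reconcilable], , drop = FALSE]
  snps$info <- pmin(a$snps$info[ia[reconcilable]],
                    b$snps$info[ib[reconcilable]])
  fam <- rbind(a$fam[, c("fid", "iid", "cohort")],
               b$fam[, c("fid", "iid", "cohort")])
  merged <- geno_matrix(rbind(Xa, Xb), snps, fam)
  out <- qc_filter(merged, thresholds)
  attr(out$report, "n_intersection") <- length(common)
  attr(out$report, "n_flipped") <- sum(needs_flip)
  attr(out$report, "n_ambiguous_dropped") <- sum(ambiguous)
  attr(out$report, "n_mismatch_dropped") <-
    sum(!(same | swap | flip_strand | flip_swap) & !ambiguous)
  out
}
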