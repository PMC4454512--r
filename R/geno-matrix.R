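#' Genotype container: additive dosages plus per-SNP metadata
#'
#' A \code{geno_matrix} stores an individuals-by-SNPs matrix of additive
#' dosages counting copies of the A1 allele (0/1/2, \code{NA} = missing),
#' a per-SNP metadata table (id, chromosome, position, A1/A2 alleles,
#' imputation info score) and a per-individual table (FID, IID, cohort).
#'
#' @param X numeric matrix, individuals in rows, SNPs in columns.
#' @param snps data.frame with columns id, chr, pos, a1, a2, info.
#' @param fam data.frame with columns fid, iid, cohort.
#' @return An object of class \code{geno_matrix}.
#' @export
geno_matrix <- function(X, snps, fam) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == nrow(fam), ncol(X) == nrow(snps),
            all(c("id", "chr", "pos", "a1", "a2", "info") %in% names(snps)),
            all(c("fid", "iid") %in% names(fam)))
  if (anyDuplicated(fam$iid)) stop("duplicated individual ids")
  if (anyDuplicated(snps$id)) stop("duplicated SNP ids")
  if (is.null(fam$cohort)) fam$cohort <- "cohort1"
  rownames(X) <- fam$iid
  colnames(X) <- snps$id
  structure(list(X = X, snps = snps, fam = fam), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$X), "individuals x", ncol(x$X), "SNPs;",
      format(100 * mean(is.na(x$X)), digits = 3), "% missing\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$X)

# subset a geno_matrix by individual and/or SNP index
subset_geno <- function(g, i = NULL, j = NULL) {
  if (!is.null(i)) {
    g$X <- g$X[i, , drop = FALSE]
    g$fam <- g$fam[i, , drop = FALSE]
  }
  if (!is.null(j)) {
    g$X <- g$X[, j, drop = FALSE]
    g$snps <- g$snps[j, , drop = FALSE]
  }
  rownames(g$fam) <- NULL
  rownames(g$snps) <- NULL
  g
}

#' Per-SNP summary statistics of a genotype matrix
#'
#' @param g a \code{geno_matrix}.
#' @return data.frame with per-SNP missing rate, A1 allele frequency and
#'   minor allele frequency computed from called genotypes only.
#' @export
snp_stats <- function(g) {
  X <- g$X
  n <- nrow(X)
  n_called <- n - colSums(is.na(X))
  freq <- colMeans(X, na.rm = TRUE) / 2
  freq[n_called == 0L] <- NA_real_
  data.frame(
    id = g$snps$id,
    miss_rate = 1 - n_called / n,
    freq_a1 = freq,
    maf = pmin(freq, 1 - freq),
    n_called = n_called,
    stringsAsFactors = FALSE
  )
}
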