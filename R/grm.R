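#' Compute the genomic relationship matrix (GRM)
#'
#' Off-diagonal entries average, over SNPs called in both individuals, the
#' product of centred dosages scaled by the sample heterozygosity:
#' \deqn{A_{jk} = \frac{1}{M_{jk}} \sum_i
#'   \frac{(x_{ij}-2p_i)(x_{ik}-2p_i)}{2p_i(1-p_i)}.}
#' The diagonal uses the bias-corrected estimator
#' \eqn{A_{jj} = 1 + \frac{1}{M_j}\sum_i
#'   \frac{x_{ij}^2-(1+2p_i)x_{ij}+2p_i^2}{2p_i(1-p_i)}}
#' (the plain squared-deviation diagonal is available via
#' \code{diag_method = "plain"} for cross-checks). Allele frequencies
#' \eqn{p_i} are pooled sample frequencies of the matrix at hand, computed
#' after QC; missing genotypes are handled with pairwise-complete SNP sets
#' and per-pair denominators \eqn{M_{jk}}.
#'
#' @param genotypes a QC'd \code{\link{geno_matrix}} with no monomorphic
#'   SNPs.
#' @param diag_method \code{"corrected"} (default) or \code{"plain"}.
#' @return An object of class \code{grm}: list with symmetric matrix
#'   \code{A}, per-pair SNP-count matrix \code{M} and id table \code{ids}.
#' @export
compute_grm <- function(genotypes, diag_method = c("corrected", "plain")) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  diag_method <- match.arg(diag_method)
  X <- genotypes$X
  n <- nrow(X); m <- ncol(X)
  p <- colMeans(X, na.rm = TRUE) / 2
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("monomorphic or all-missing SNP reached compute_grm; ",
         "QC contract violated")
  }
  het <- 2 * p * (1 - p)
  W <- sweep(X, 2L, 2 * p, "-")
  W <- sweep(W, 2L, sqrt(het), "/")
  has_na <- anyNA(X)
  if (has_na) {
    obs <- !is.na(X)
    W[!obs] <- 0
    storage.mode(obs) <- "double"
    M <- tcrossprod(obs)
  } else {
    M <- matrix(as.numeric(m), n, n)
  }
  if (any(M < 1)) stop("individual pair with no jointly called SNPs")
  A <- tcrossprod(W) / M
  # diagonal
  if (diag_method == "corrected") {
    # per-SNP term (x^2 - (1+2p)x + 2p^2)/(2p(1-p)), 0 where missing
    D <- X * X - sweep(X, 2L, 1 + 2 * p, "*")
    D <- sweep(D, 2L, 2 * p^2, "+")
    D <- sweep(D, 2L, het, "/")
    D[is.na(D)] <- 0
    diag(A) <- 1 + rowSums(D) / diag(M)
  }
  dimnames(A) <- list(genotypes$fam$iid, genotypes$fam$iid)
  dimnames(M) <- dimnames(A)
  structure(list(A = A, M = M,
                 ids = genotypes$fam[, c("fid", "iid")]),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  off <- x$A[upper.tri(x$A)]
  cat("GRM:", nrow(x$A), "individuals; mean diag",
      format(mean(diag(x$A)), digits = 4), "; off-diag SD",
      format(stats::sd(off), digits = 3), "\n")
  invisible(x)
}

#' Greedily prune related individuals from a GRM
#'
#' While any off-diagonal relatedness exceeds \code{cutoff}, the individual
#' involved in the most violating pairs is dropped (ties broken by dropping
#' the one later in id order). The default cutoff 0.025 is the GREML
#' convention for "unrelated" (roughly second cousins or closer removed).
#'
#' @param grm a \code{grm}.
#' @param cutoff positive relatedness threshold.
#' @return integer vector of retained row indices (names = retained iids).
#' @export
prune_related <- function(grm, cutoff = 0.025) {
  stopifnot(inherits(grm, "grm"))
  if (!is.finite(cutoff) || cutoff <= 0) stop("cutoff must be positive")
  A <- grm$A
  diag(A) <- 0
  viol <- A > cutoff
  keep <- rep(TRUE, nrow(A))
  while (TRUE) {
    counts <- rowSums(viol[keep, keep, drop = FALSE])
    if (!any(counts > 0)) break
    worst <- which(counts == max(counts))
    drop_local <- worst[length(worst)] # tie -> larger id order
    keep[which(keep)[drop_local]] <- FALSE
  }
  out <- which(keep)
  names(out) <- grm$ids$iid[out]
  out
}

#' Principal components of a GRM for stratification control
#'
#' Top-k eigenvectors/eigenvalues of the (pruned) GRM, with a deterministic
#' sign convention: each component's largest-magnitude loading is positive.
#'
#' @param grm a \code{grm}, restricted to the retained individuals.
#' @param k number of components (default 20, the standard GREML
#'   stratification control); must be < n.
#' @return An object of class \code{pc_set}: list with \code{vectors}
#'   (n x k, orthonormal), \code{values} (non-increasing, clipped at 0) and
#'   \code{ids}.
#' @export
compute_pcs <- function(grm, k = 20L) {
  stopifnot(inherits(grm, "grm"))
  n <- nrow(grm$A)
  if (k >= n) stop("k must be smaller than the number of individuals")
  eig <- eigen(grm$A, symmetric = TRUE)
  vec <- eig$vectors[, seq_len(k), drop = FALSE]
  val <- pmax(eig$values[seq_len(k)], 0)
  for (j in seq_len(k)) {
    i_max <- which.max(abs(vec[, j]))
    if (vec[i_max, j] < 0) vec[, j] <- -vec[, j]
  }
  colnames(vec) <- paste0("PC", seq_len(k))
  structure(list(vectors = vec, values = val, ids = grm$ids),
            class = "pc_set")
}

#' Write principal components as delimited text (FID, IID, PC1..PCk)
#'
#' @param pcs a \code{pc_set}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_pcs <- function(pcs, path) {
  df <- cbind(pcs$ids, as.data.frame(pcs$vectors))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict a GRM to a subset of individuals
#'
#' @param grm a \code{grm}.
#' @param idx integer row indices to keep (e.g. from
#'   \code{\link{prune_related}}).
#' @return the restricted \code{grm}.
#' @export
subset_grm <- function(grm, idx) {
  structure(list(A = grm$A[idx, idx, drop = FALSE],
                 M = grm$M[idx, idx, drop = FALSE],
                 ids = grm$ids[idx, , drop = FALSE]),
            class = "grm")
}
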