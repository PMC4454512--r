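#' Write a genotype matrix as PLINK 1 binary (bed/bim/fam)
#'
#' SNP-major bed with magic bytes 0x6C 0x1B 0x01; dosages count A1 alleles
#' (bim column 5), using the standard 2-bit codes 00 = A1/A1 (dosage 2),
#' 10 = het, 11 = A2/A2 (dosage 0), 01 = missing, packed 4 genotypes per
#' byte, first sample in the lowest-order bits.
#'
#' @param g a \code{\link{geno_matrix}}.
#' @param prefix output path prefix.
#' @return invisibly, \code{prefix}.
#' @export
write_plink <- function(g, prefix) {
  stopifnot(inherits(g, "geno_matrix"))
  n <- nrow(g$X); m <- ncol(g$X)
  # map dosage -> 2-bit code
  code <- matrix(3L, n, m)                       # dosage 0 -> 11
  code[!is.na(g$X) & g$X == 1] <- 2L             # het      -> 10
  code[!is.na(g$X) & g$X == 2] <- 0L             # A1 hom   -> 00
  code[is.na(g$X)] <- 1L                         # missing  -> 01
  n_pad <- 4L * ceiling(n / 4L)
  if (n_pad > n) code <- rbind(code, matrix(0L, n_pad - n, m))
  # pack: rows 1..4 of each group of 4 into one byte, sample 1 in bits 0-1
  dim(code) <- c(4L, n_pad / 4L * m)
  bytes <- as.raw(code[1, ] + 4L * code[2, ] + 16L * code[3, ] +
                    64L * code[4, ])
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6C, 0x1B, 0x01)), con)
  writeBin(bytes, con)

  bim <- data.frame(g$snps$chr, g$snps$id, 0, g$snps$pos, g$snps$a1,
                    g$snps$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  fam <- data.frame(g$fam$fid, g$fam$iid, 0, 0, 2, -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read PLINK 1 binary (bed/bim/fam) into a genotype matrix
#'
#' @param prefix path prefix of the .bed/.bim/.fam triplet.
#' @param info_file optional path to a tab-delimited per-SNP info-score
#'   table with columns SNP and INFO; SNPs absent from it get info = NA.
#' @return A \code{\link{geno_matrix}}; the cohort column is taken from the
#'   FID prefix only if absent (defaults to a single cohort label).
#' @export
read_plink <- function(prefix, info_file = NULL) {
  bim <- utils::read.table(paste0(prefix, ".bim"), sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("chr", "id", "cm", "pos", "a1",
                                         "a2"))
  fam <- utils::read.table(paste0(prefix, ".fam"),
                           stringsAsFactors = FALSE)[, 1:2]
  names(fam) <- c("fid", "iid")
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3L + m * ceiling(n / 4L))
  if (length(raw) < 3L || raw[1] != as.raw(0x6C) || raw[2] != as.raw(0x1B)) {
    stop("not a PLINK 1 bed file: bad magic bytes")
  }
  if (raw[3] != as.raw(0x01)) stop("only SNP-major bed files are supported")
  payload <- as.integer(raw[-(1:3)])
  if (length(payload) != m * ceiling(n / 4L)) {
    stop("bed payload size does not match bim/fam dimensions")
  }
  # unpack 4 codes per byte
  codes <- rbind(payload %% 4L, (payload %/% 4L) %% 4L,
                 (payload %/% 16L) %% 4L, payload %/% 64L)
  dim(codes) <- c(4L * ceiling(n / 4L), m)
  codes <- codes[seq_len(n), , drop = FALSE]
  X <- matrix(NA_real_, n, m)
  X[codes == 0L] <- 2
  X[codes == 2L] <- 1
  X[codes == 3L] <- 0
  info <- rep(NA_real_, m)
  if (!is.null(info_file)) {
    it <- utils::read.table(info_file, header = TRUE,
                            stringsAsFactors = FALSE)
    info <- it$INFO[match(bim$id, it$SNP)]
  }
  snps <- data.frame(id = bim$id, chr = bim$chr, pos = bim$pos,
                     a1 = bim$a1, a2 = bim$a2, info = info,
                     stringsAsFactors = FALSE)
  fam$cohort <- "cohort1"
  geno_matrix(X, snps, fam)
}

#' Write a GRM in the GCTA binary convention
#'
#' Lower triangle (including the diagonal), row by row, as 4-byte
#' little-endian floats in \code{<prefix>.grm.bin}; per-pair SNP counts in
#' the same order in \code{<prefix>.grm.N.bin}; ids in
#' \code{<prefix>.grm.id}.
#'
#' @param grm a \code{\link{compute_grm}} result.
#' @param prefix output path prefix.
#' @return invisibly, \code{prefix}.
#' @export
write_grm <- function(grm, prefix) {
  stopifnot(inherits(grm, "grm"))
  n <- nrow(grm$A)
  lt <- which(lower.tri(grm$A, diag = TRUE), arr.ind = TRUE)
  ord <- order(lt[, 1], lt[, 2]) # row by row
  vals <- grm$A[lt[ord, , drop = FALSE]]
  cnts <- grm$M[lt[ord, , drop = FALSE]]
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(vals), con, size = 4L, endian = "little")
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(as.numeric(cnts), con, size = 4L, endian = "little")
  close(con)
  utils::write.table(grm$ids, paste0(prefix, ".grm.id"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a GRM written in the GCTA binary convention
#'
#' @param prefix path prefix of the .grm.bin/.grm.N.bin/.grm.id triplet.
#' @return A \code{grm} object (see \code{\link{compute_grm}}).
#' @export
read_grm <- function(prefix) {
  ids <- utils::read.table(paste0(prefix, ".grm.id"),
                           stringsAsFactors = FALSE)
  names(ids) <- c("fid", "iid")
  n <- nrow(ids)
  n_lt <- n * (n + 1L) / 2L
  vals <- readBin(paste0(prefix, ".grm.bin"), "numeric", n = n_lt,
                  size = 4L, endian = "little")
  cnts <- readBin(paste0(prefix, ".grm.N.bin"), "numeric", n = n_lt,
                  size = 4L, endian = "little")
  A <- matrix(0, n, n)
  M <- matrix(0, n, n)
  idx <- which(lower.tri(A, diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  A[idx] <- vals
  M[idx] <- cnts
  A <- A + t(A) - diag(diag(A))
  M <- M + t(M) - diag(diag(M))
  dimnames(A) <- list(ids$iid, ids$iid)
  dimnames(M) <- dimnames(A)
  structure(list(A = A, M = M, ids = ids), class = "grm")
}
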