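# Shared fixture builders. Everything is generated in code; no data files.

# hand-built geno_matrix from a dosage matrix
make_geno <- function(X, info = rep(1, ncol(X)), a1 = NULL, a2 = NULL,
                      cohort = "cohort1", ids = NULL, pos = NULL) {
  n <- nrow(X); m <- ncol(X)
  if (is.null(a1)) a1 <- rep("A", m)
  if (is.null(a2)) a2 <- rep("C", m)
  if (is.null(ids)) ids <- sprintf("s%03d", seq_len(m))
  if (is.null(pos)) pos <- seq_len(m) * 100L
  geno_matrix(
    X,
    data.frame(id = ids, chr = 1L, pos = pos, a1 = a1, a2 = a2,
               info = info, stringsAsFactors = FALSE),
    data.frame(fid = sprintf("f%04d", seq_len(n)),
               iid = sprintf("i%04d", seq_len(n)),
               cohort = rep_len(cohort, n), stringsAsFactors = FALSE)
  )
}

# random polymorphic dosage matrix
random_geno <- function(n, m, seed = 1, maf = c(0.1, 0.5),
                        miss_rate = 0) {
  set.seed(seed)
  p <- runif(m, maf[1], maf[2])
  X <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
  storage.mode(X) <- "double"
  if (miss_rate > 0) X[sample.int(n * m, round(miss_rate * n * m))] <- NA
  make_geno(X)
}

# GRM object from a plain matrix
make_grm <- function(A, M = NULL) {
  n <- nrow(A)
  if (is.null(M)) M <- matrix(100, n, n)
  structure(list(A = A, M = M,
                 ids = data.frame(fid = sprintf("f%04d", 1:n),
                                  iid = sprintf("i%04d", 1:n),
                                  stringsAsFactors = FALSE)),
            class = "grm")
}

# block-diagonal duplicate-pair GRM: n_pairs pairs with A = 1 within pair
block_pair_grm <- function(n_pairs) {
  A <- diag(2 * n_pairs)
  for (k in seq_len(n_pairs)) {
    i <- 2 * k - 1
    A[i, i + 1] <- A[i + 1, i] <- 1
  }
  make_grm(A)
}

# draw y ~ N(Xb, sg*A + se*I)
draw_mvn_pheno <- function(A, sg, se, X = NULL, beta = NULL, seed = 1) {
  set.seed(seed)
  n <- nrow(A)
  ev <- eigen(A, symmetric = TRUE)
  L <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  y <- sqrt(sg) * as.numeric(L %*% rnorm(n)) + rnorm(n, 0, sqrt(se))
  if (!is.null(X) && !is.null(beta)) y <- y + as.numeric(X %*% beta)
  y
}

# independent exact HWE enumeration oracle: closed-form Levene-Haldane
# conditional probability P(het = h | allele counts) summed over all
# configurations as or less probable than the observed one
hwe_enum_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n - nA
  rare <- min(nA, na)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- sapply(hets, function(h) {
    homr <- (rare - h) / 2
    homc <- (2 * n - rare - h) / 2
    lfactorial(n) - lfactorial(homr) - lfactorial(h) - lfactorial(homc) +
      lfactorial(nA) + lfactorial(na) - lfactorial(2 * n) + h * log(2)
  })
  pr <- exp(logp)
  obs <- pr[match(n_Aa, hets)]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# 10-SNP QC fixture with exactly one SNP failing each filter, fates known
# by hand:
#   s1 info 0.6 (boundary) -> info (the filter keeps only info > 0.6)
#   s2 8% missing          -> missingness
#   s3 MAF 0.005           -> maf
#   s4 het depletion       -> hwe
#   s5..s10 clean          -> survive (s6 has MAF exactly 0.01, retained;
#                             s7 has missing rate exactly 3%, retained)
hand_qc_fixture <- function() {
  n <- 200
  set.seed(42)
  clean <- function(p) rbinom(n, 2, p)
  X <- cbind(
    s1 = clean(0.3),
    s2 = { x <- clean(0.3); x[1:16] <- NA; x },
    s3 = c(rep(1, 2), rep(0, n - 2)),              # freq 2/400 = 0.005
    s4 = c(rep(2, 100), rep(0, 100)),              # no hets at freq 0.5
    s5 = clean(0.4),
    s6 = c(rep(1, 4), rep(0, n - 4)),              # freq 4/400 = 0.010
    s7 = { x <- clean(0.25); x[1:6] <- NA; x },    # 6/200 = 3% missing
    s8 = clean(0.15), s9 = clean(0.45), s10 = clean(0.2)
  )
  make_geno(X, info = c(0.6, rep(0.95, 9)), ids = paste0("s", 1:10))
}

# dense double-loop GRM oracle following the estimator definition literally
grm_oracle <- function(X, diag_method = "corrected") {
  n <- nrow(X); m <- ncol(X)
  p <- colMeans(X, na.rm = TRUE) / 2
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      num <- 0; cnt <- 0
      for (i in seq_len(m)) {
        xj <- X[j, i]; xk <- X[k, i]
        if (is.na(xj) || is.na(xk)) next
        cnt <- cnt + 1
        if (j == k && diag_method == "corrected") {
          num <- num + (xj^2 - (1 + 2 * p[i]) * xj + 2 * p[i]^2) /
            (2 * p[i] * (1 - p[i]))
        } else {
          num <- num + (xj - 2 * p[i]) * (xk - 2 * p[i]) /
            (2 * p[i] * (1 - p[i]))
        }
      }
      A[j, k] <- if (j == k && diag_method == "corrected") {
        1 + num / cnt
      } else num / cnt
    }
  }
  A
}
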